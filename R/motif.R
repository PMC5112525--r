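# Promoter extraction, PWM scanning, and TF-target network construction.

#' Read position frequency matrices in JASPAR text format
#'
#' Parses the plain-text JASPAR PFM layout: a `>motif_id name` header
#' followed by four lines `A [ 4 19 0 ... ]` (brackets optional) for
#' A, C, G, T.
#'
#' @param path PFM file (may contain several motifs).
#' @return Named list of motifs, each a list with `motif_id`, `tf_family`
#'   (the name field), and `counts` (4 x L matrix, rows A/C/G/T).
#' @export
readJasparPfm <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (!length(starts)) stop("no JASPAR '>' headers in ", path)
  out <- list()
  for (i in seq_along(starts)) {
    from <- starts[i]
    to <- if (i < length(starts)) starts[i + 1] - 1 else length(lines)
    hdr <- strsplit(sub("^>", "", lines[from]), "\\s+")[[1]]
    id <- hdr[1]
    fam <- if (length(hdr) > 1) paste(hdr[-1], collapse = " ") else id
    rows <- lines[(from + 1):to]
    if (length(rows) != 4)
      stop("motif ", id, ": expected 4 count rows, got ", length(rows))
    parsed <- lapply(rows, function(r) {
      r <- gsub("[][]", " ", r)
      v <- strsplit(trimws(r), "\\s+")[[1]]
      if (v[1] %in% c("A", "C", "G", "T")) v <- v[-1]
      as.numeric(v)
    })
    if (length(unique(lengths(parsed))) != 1)
      stop("motif ", id, ": ragged count rows")
    counts <- do.call(rbind, parsed)
    rownames(counts) <- c("A", "C", "G", "T")
    if (ncol(counts) < 4)
      stop("motif ", id, ": length must be at least 4")
    out[[id]] <- list(motif_id = id, tf_family = fam, counts = counts)
  }
  out
}

#' Convert a count matrix to a log2-odds scoring matrix
#'
#' Column counts are normalised with a pseudocount (`(count +
#' pseudocount/4) / (colsum + pseudocount)`) and scored against the
#' background as `log2(p / background)`.
#'
#' @param counts 4 x L count matrix (rows A/C/G/T).
#' @param pseudocount total pseudocount per column (default 0.8).
#' @param background base probabilities, must sum to 1 (default uniform).
#' @return 4 x L log2-odds matrix.
#' @export
pwmLogOdds <- function(counts, pseudocount = 0.8,
                       background = rep(0.25, 4)) {
  if (abs(sum(background) - 1) > 1e-6) stop("background must sum to 1")
  cs <- colSums(counts)
  p <- sweep(counts + pseudocount / 4, 2, cs + pseudocount, "/")
  log2(p / background)
}

#' Extract promoter sequences upstream of TSSs
#'
#' Strand-aware: plus-strand genes take the `length` bases ending just
#' before the TSS; minus-strand genes take the `length` bases just after
#' the gene end, reverse-complemented. Promoters truncated at chromosome
#' ends keep their actual length and are flagged.
#'
#' @param models a [GeneModelSet-class].
#' @param genome `DNAStringSet` of chromosome sequences.
#' @param geneIds which genes (default: all).
#' @param length promoter span in bp (default 3000).
#' @return `DNAStringSet` named by gene id, with `actual_length` and
#'   `truncated` in `metadata()`.
#' @export
extractPromoters <- function(models, genome, geneIds = NULL, length = 3000) {
  g <- models@genes
  if (is.null(geneIds)) geneIds <- mcols(g)$gene_id
  idx <- match(geneIds, mcols(g)$gene_id)
  if (anyNA(idx))
    stop("unknown gene(s): ", paste(geneIds[is.na(idx)], collapse = ", "))
  seqs <- character(length(idx))
  actual <- integer(length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    ch <- as.character(seqnames(g))[i]
    chromLen <- nchar(as.character(genome[[ch]]))
    if (as.character(strand(g))[i] == "-") {
      tss <- end(g)[i]
      from <- tss + 1; to <- min(tss + length, chromLen)
      if (from > to) { seqs[k] <- ""; actual[k] <- 0L; next }
      s <- subseq(genome[[ch]], from, to)
      seqs[k] <- as.character(reverseComplement(s))
    } else {
      tss <- start(g)[i]
      from <- max(1, tss - length); to <- tss - 1
      if (to < from) { seqs[k] <- ""; actual[k] <- 0L; next }
      seqs[k] <- as.character(subseq(genome[[ch]], from, to))
    }
    actual[k] <- nchar(seqs[k])
  }
  if (any(actual == 0))
    warning("zero-length promoter for: ",
            paste(geneIds[actual == 0], collapse = ", "))
  out <- DNAStringSet(seqs)
  names(out) <- geneIds
  metadata(out)$actual_length <- setNames(actual, geneIds)
  metadata(out)$truncated <- setNames(actual < length, geneIds)
  out
}

.seqToCodes <- function(seq) {
  chars <- strsplit(toupper(as.character(seq)), "")[[1]]
  match(chars, c("A", "C", "G", "T"))  # N and others -> NA
}

#' Scan a sequence with a PWM
#'
#' Scores every offset on both strands with the log2-odds matrix and keeps
#' hits scoring at least `thresholdFraction` of the maximum attainable
#' score. Windows containing N (or any non-ACGT base) are skipped.
#' Overlapping hits are all reported.
#'
#' @param seq a `DNAString`, `DNAStringSet` element, or character sequence.
#' @param pwm a motif from [readJasparPfm()] (or any list with `counts`).
#' @param thresholdFraction fraction of the maximum score (default 0.8).
#' @param pseudocount,background passed to [pwmLogOdds()].
#' @return data.frame with `offset` (1-based start of the hit window on the
#'   given sequence), `strand`, `score`; zero rows when the sequence is
#'   shorter than the motif.
#' @export
scanPwm <- function(seq, pwm, thresholdFraction = 0.8, pseudocount = 0.8,
                    background = rep(0.25, 4)) {
  lom <- pwmLogOdds(pwm$counts, pseudocount, background)
  L <- ncol(lom)
  codes <- .seqToCodes(seq)
  n <- length(codes)
  empty <- data.frame(offset = integer(), strand = character(),
                      score = numeric())
  if (n < L) return(empty)
  maxScore <- sum(apply(lom, 2, max))
  threshold <- thresholdFraction * maxScore
  scoreStrand <- function(cds) {
    nOff <- length(cds) - L + 1
    sc <- numeric(nOff)
    for (j in seq_len(L)) sc <- sc + lom[cbind(cds[j:(j + nOff - 1)], j)]
    sc
  }
  fw <- scoreStrand(codes)
  rcCodes <- rev(5L - codes)          # A<->T, C<->G on the reversed strand
  rv <- scoreStrand(rcCodes)
  hits <- rbind(
    if (any(ok <- !is.na(fw) & fw >= threshold))
      data.frame(offset = which(ok), strand = "+", score = fw[ok]),
    if (any(ok <- !is.na(rv) & rv >= threshold))
      data.frame(offset = n - L + 2L - which(ok), strand = "-",
                 score = rv[ok]))
  if (is.null(hits)) return(empty)
  hits[order(hits$offset, hits$strand), , drop = FALSE]
}

#' Build a TF-target network from promoter scans
#'
#' One edge per (motif, gene, hit). Hit positions are reported relative to
#' the TSS (negative upstream: a hit starting at the promoter's last base
#' is at -motif length ... -1 region start `-(promoter length - offset + 1)`).
#'
#' @param promoters `DNAStringSet` from [extractPromoters()].
#' @param pwms list of motifs from [readJasparPfm()].
#' @param thresholdFraction passed to [scanPwm()].
#' @param pseudocount,background passed to [scanPwm()].
#' @return List with `edges` (data.frame: `tf_family`, `motif_id`,
#'   `target_gene`, `hit_position`, `strand`, `score`) and `summary`
#'   (data.frame: genes with at least one hit per TF family, plus the
#'   total distinct genes with any hit).
#' @export
buildNetwork <- function(promoters, pwms, thresholdFraction = 0.8,
                         pseudocount = 0.8, background = rep(0.25, 4)) {
  edges <- list()
  for (pw in pwms) {
    for (g in names(promoters)) {
      pl <- nchar(as.character(promoters[[g]]))
      if (pl == 0) next
      h <- scanPwm(promoters[[g]], pw, thresholdFraction, pseudocount,
                   background)
      if (!nrow(h)) next
      edges[[length(edges) + 1L]] <- data.frame(
        tf_family = pw$tf_family, motif_id = pw$motif_id, target_gene = g,
        hit_position = h$offset - pl - 1L, strand = h$strand,
        score = h$score, stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges)
    else data.frame(tf_family = character(), motif_id = character(),
                    target_gene = character(), hit_position = integer(),
                    strand = character(), score = numeric())
  fams <- unique(vapply(pwms, `[[`, "", "tf_family"))
  summary <- data.frame(
    tf_family = fams,
    n_genes = vapply(fams, function(f)
      length(unique(edges$target_gene[edges$tf_family == f])), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  list(edges = edges, summary = summary,
       n_genes_with_tfbs = length(unique(edges$target_gene)))
}

#' Write a network as SIF-style TSV plus a detailed hits table
#'
#' @param network output of [buildNetwork()].
#' @param sifPath SIF-style file (`tf_family binds target_gene`).
#' @param hitsPath detailed per-hit TSV.
#' @return `sifPath`, invisibly.
#' @export
writeNetworkTsv <- function(network, sifPath, hitsPath) {
  e <- network$edges
  sif <- unique(data.frame(tf_family = e$tf_family, interaction = "binds",
                           target_gene = e$target_gene))
  write.table(sif, sifPath, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  write.table(e, hitsPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(sifPath)
}
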