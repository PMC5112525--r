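# SNP annotation: genomic-feature classification and coding-effect calls.

.FEATURE_LEVELS <- c("splice_site", "utr5", "utr3", "exon", "intron",
                     "promoter", "intergenic")

# Feature ranges of one gene, tagged with priority (lower wins).
.geneFeatureRanges <- function(models, spliceBp) {
  ids <- mcols(models@genes)$gene_id
  pieces <- list()
  add <- function(gr, feature, priority, gid) {
    if (!length(gr)) return()
    mcols(gr) <- NULL
    mcols(gr)$feature <- feature
    mcols(gr)$priority <- priority
    mcols(gr)$gene_id <- gid
    pieces[[length(pieces) + 1L]] <<- gr
  }
  for (i in seq_along(ids)) {
    gid <- ids[i]
    introns <- models@introns[[gid]]
    if (length(introns) && spliceBp > 0) {
      ok <- width(introns) >= 1
      sp5 <- GenomicRanges::resize(introns[ok], pmin(spliceBp, width(introns[ok])),
                                   fix = "start", ignore.strand = TRUE)
      sp3 <- GenomicRanges::resize(introns[ok], pmin(spliceBp, width(introns[ok])),
                                   fix = "end", ignore.strand = TRUE)
      add(c(sp5, sp3), "splice_site", 1L, gid)
    }
    add(models@utr5[[gid]], "utr5", 2L, gid)
    add(models@utr3[[gid]], "utr3", 3L, gid)
    add(models@exons[[gid]], "exon", 4L, gid)
    add(introns, "intron", 5L, gid)
  }
  if (!length(pieces)) return(GRanges())
  names(pieces) <- NULL
  suppressWarnings(do.call(c, pieces))
}

#' Classify SNPs by genomic feature
#'
#' Exactly one feature per SNP. Within a gene the priority is splice site >
#' 5'/3' UTR > exon > intron; if a SNP hits multiple genes the
#' highest-priority feature wins. `promoter` applies only to SNPs outside
#' all genebodies that lie within `promoterBp` upstream of some TSS
#' (strand-aware); everything else is `intergenic`. Splice sites are the
#' first and last `spliceBp` bases of each intron (default 2, the GT-AG
#' dinucleotides).
#'
#' @param sites `GRanges` of SNP positions.
#' @param models a [GeneModelSet-class].
#' @param promoterBp promoter span upstream of the TSS (default 2000).
#' @param spliceBp splice-site span inside each intron end (default 2).
#' @return data.frame with `chrom`, `pos`, `feature` (factor over the seven
#'   classes) and `gene_id` (`NA` for intergenic).
#' @export
classifyFeatures <- function(sites, models, promoterBp = 2000, spliceBp = 2) {
  n <- length(sites)
  feature <- rep("intergenic", n)
  gene <- rep(NA_character_, n)
  feat <- .geneFeatureRanges(models, spliceBp)
  if (length(feat)) {
    ov <- findOverlaps(sites, feat, ignore.strand = TRUE)
    if (length(ov)) {
      df <- data.frame(q = queryHits(ov),
                       priority = mcols(feat)$priority[subjectHits(ov)],
                       feature = mcols(feat)$feature[subjectHits(ov)],
                       gene_id = mcols(feat)$gene_id[subjectHits(ov)])
      df <- df[order(df$q, df$priority), ]
      df <- df[!duplicated(df$q), ]
      feature[df$q] <- df$feature
      gene[df$q] <- df$gene_id
    }
  }
  # promoter: outside all genebodies, within promoterBp upstream of a TSS
  inBody <- unique(queryHits(findOverlaps(sites, models@genes,
                                          ignore.strand = TRUE)))
  prom <- GenomicRanges::trim(
    GenomicRanges::flank(models@genes, promoterBp, start = TRUE))
  pov <- findOverlaps(sites, prom, ignore.strand = TRUE)
  cand <- setdiff(unique(queryHits(pov)), inBody)
  cand <- cand[feature[cand] == "intergenic"]
  if (length(cand)) {
    first <- match(cand, queryHits(pov))
    feature[cand] <- "promoter"
    gene[cand] <- mcols(models@genes)$gene_id[subjectHits(pov)[first]]
  }
  data.frame(chrom = as.character(seqnames(sites)), pos = start(sites),
             feature = factor(feature, levels = .FEATURE_LEVELS),
             gene_id = gene, stringsAsFactors = FALSE)
}

# CDS ranges of a gene in transcript (5'->3') order.
.cdsInTxOrder <- function(models, gid) {
  cd <- models@cds[[gid]]
  st <- as.character(strand(models@genes))[
    match(gid, mcols(models@genes)$gene_id)]
  cd <- cd[order(start(cd))]
  if (st == "-") cd <- rev(cd)
  list(cds = cd, strand = st)
}

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Classify the coding effect of CDS SNPs
#'
#' For each SNP inside a CDS, splices the reference codon out of the CDS in
#' transcript orientation (reverse-complementing on the minus strand),
#' substitutes the alternate allele, and compares amino acids under the
#' standard nuclear codon table: same residue = synonymous, different =
#' nonsynonymous, non-stop to stop = stop gain, stop to non-stop = stop
#' loss. Genes flagged `codingOk = FALSE` (CDS not a multiple of 3) are
#' skipped with effect `none`.
#'
#' @param sites `GRanges` of SNP positions with `ref`/`alt` metadata
#'   columns (plus-strand alleles, as in VCF).
#' @param models a [GeneModelSet-class].
#' @param genome `DNAStringSet` of chromosome sequences.
#' @return data.frame with `chrom`, `pos`, `gene_id`, `codon_pos`,
#'   `ref_codon`, `alt_codon`, `ref_aa`, `alt_aa`, `effect` (synonymous /
#'   nonsynonymous / stop_gain / stop_loss / none). One row per (SNP, gene)
#'   CDS hit.
#' @export
codingEffects <- function(sites, models, genome) {
  cdsAll <- unlist(models@cds)
  if (!length(cdsAll))
    return(data.frame(chrom = character(), pos = integer(),
                      gene_id = character(), effect = character()))
  gids <- rep(names(models@cds), lengths(models@cds))
  ov <- findOverlaps(sites, cdsAll, ignore.strand = TRUE)
  rows <- list()
  chromSeqs <- genome
  codonTable <- GENETIC_CODE
  seen <- character()
  for (k in seq_along(ov)) {
    si <- queryHits(ov)[k]
    gid <- gids[subjectHits(ov)[k]]
    key <- paste(si, gid)
    if (key %in% seen) next   # one row per (SNP, gene)
    seen <- c(seen, key)
    okGene <- mcols(models@genes)$codingOk[
      match(gid, mcols(models@genes)$gene_id)]
    pos <- start(sites)[si]
    ch <- as.character(seqnames(sites))[si]
    ref <- mcols(sites)$ref[si]; alt <- mcols(sites)$alt[si]
    genomeBase <- as.character(subseq(chromSeqs[[ch]], pos, pos))
    if (genomeBase != ref)
      stop(sprintf("reference mismatch at %s:%d (VCF ref %s, genome %s)",
                   ch, pos, ref, genomeBase))
    if (!isTRUE(okGene)) {
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch, pos = pos, gene_id = gid, codon_pos = NA_integer_,
        ref_codon = NA_character_, alt_codon = NA_character_,
        ref_aa = NA_character_, alt_aa = NA_character_, effect = "none",
        stringsAsFactors = FALSE)
      next
    }
    tx <- .cdsInTxOrder(models, gid)
    cd <- tx$cds
    w <- width(cd)
    cum <- cumsum(c(0, w))
    seg <- which(start(cd) <= pos & end(cd) >= pos)
    offset <- if (tx$strand == "+")
      cum[seg] + (pos - start(cd)[seg] + 1L)
    else
      cum[seg] + (end(cd)[seg] - pos + 1L)
    codonIdx <- ceiling(offset / 3)
    posInCodon <- offset - (codonIdx - 1L) * 3L
    # genomic positions of the codon's three bases, in tx order
    txPos <- ((codonIdx - 1L) * 3L + 1L):((codonIdx) * 3L)
    genPos <- vapply(txPos, function(o) {
      s <- max(which(cum < o))  # segment containing tx offset o
      within <- o - cum[s]
      as.integer(if (tx$strand == "+") start(cd)[s] + within - 1
                 else end(cd)[s] - within + 1)
    }, integer(1))
    refCodon <- vapply(genPos, function(p)
      as.character(subseq(chromSeqs[[ch]], p, p)), "")
    if (tx$strand == "-") refCodon <- unname(.COMPLEMENT[refCodon])
    altBase <- if (tx$strand == "-") unname(.COMPLEMENT[alt]) else alt
    altCodon <- refCodon
    altCodon[posInCodon] <- altBase
    refC <- paste(refCodon, collapse = "")
    altC <- paste(altCodon, collapse = "")
    refAa <- codonTable[[refC]]
    altAa <- codonTable[[altC]]
    effect <- if (refAa == "*" && altAa != "*") "stop_loss"
      else if (refAa != "*" && altAa == "*") "stop_gain"
      else if (refAa == altAa) "synonymous"
      else "nonsynonymous"
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = ch, pos = pos, gene_id = gid, codon_pos = posInCodon,
      ref_codon = refC, alt_codon = altC, ref_aa = refAa, alt_aa = altAa,
      effect = effect, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(chrom = character(), pos = integer(),
                      gene_id = character(), effect = character()))
  do.call(rbind, rows)
}

#' Annotate SNPs with feature class and coding effect
#'
#' Combines [classifyFeatures()] with [codingEffects()]: coding effects are
#' attached to SNPs classified `exon` that fall in the representative CDS.
#'
#' @inheritParams classifyFeatures
#' @param genome `DNAStringSet` of chromosome sequences.
#' @return data.frame: one row per SNP with `feature`, `gene_id`, `effect`
#'   (`none` outside CDS).
#' @export
annotateSnps <- function(sites, models, genome, promoterBp = 2000,
                         spliceBp = 2) {
  ann <- classifyFeatures(sites, models, promoterBp, spliceBp)
  ann$effect <- "none"
  eff <- codingEffects(sites, models, genome)
  if (nrow(eff)) {
    key <- paste(ann$chrom, ann$pos, ann$gene_id)
    ekey <- paste(eff$chrom, eff$pos, eff$gene_id)
    hit <- match(key, ekey)
    ok <- !is.na(hit) & ann$feature == "exon"
    ann$effect[ok] <- eff$effect[hit[ok]]
  }
  ann
}

#' Summarise an annotation table
#'
#' Per-feature counts and percentages, coding-effect counts, and the
#' nonsynonymous/synonymous ratio. Stop-gain and stop-loss variants are
#' excluded from both sides of the ratio.
#'
#' @param annotations data.frame from [annotateSnps()] (needs `feature` and
#'   `effect`).
#' @return List with `feature_counts`, `feature_percent`, `effect_counts`,
#'   `nonsyn_syn_ratio` (`NA` when there are no synonymous SNPs).
#' @export
annotationSummary <- function(annotations) {
  if (!nrow(annotations)) stop("empty annotation table")
  fc <- table(factor(annotations$feature, levels = .FEATURE_LEVELS))
  ec <- table(factor(annotations$effect,
                     levels = c("synonymous", "nonsynonymous",
                                "stop_gain", "stop_loss", "none")))
  ratio <- if (ec["synonymous"] == 0) NA_real_
           else unname(ec["nonsynonymous"] / ec["synonymous"])
  list(feature_counts = fc,
       feature_percent = 100 * fc / sum(fc),
       effect_counts = ec,
       nonsyn_syn_ratio = as.numeric(ratio))
}

#' Summary statistics from pre-tabulated SNP counts
#'
#' The count-level arithmetic of [annotationSummary()], for use when only a
#' tabulation is available (e.g. published supplementary tables): shares of
#' a total and the nonsynonymous/synonymous ratio with stop variants
#' excluded from both numerator and denominator.
#'
#' @param counts named numeric vector of counts.
#' @param total denominator for the shares (defaults to `sum(counts)`).
#' @return List with `percent` (named, same order as `counts`) and, when
#'   `counts` contains `nonsynonymous` and `synonymous` entries,
#'   `nonsyn_syn_ratio`.
#' @export
snpDistributionSummary <- function(counts, total = sum(counts)) {
  if (total <= 0) stop("total must be positive")
  out <- list(percent = 100 * counts / total)
  if (all(c("nonsynonymous", "synonymous") %in% names(counts))) {
    out$nonsyn_syn_ratio <- if (counts["synonymous"] == 0) NA_real_
      else unname(counts["nonsynonymous"] / counts["synonymous"])
  }
  out
}
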