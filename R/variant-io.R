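# Readers/writers for the standard formats all stages share.
# Coordinates are 1-based inclusive everywhere except BED output
# (0-based half-open).

#' Read multi-sample genotypes from a VCF
#'
#' Keeps biallelic SNPs only: multiallelic sites and indels are skipped and
#' counted (reported via `message()` and stored in
#' `metadata(variantSites(x))`). `./.` becomes missing; the phase separator
#' (`|` vs `/`) is ignored.
#'
#' @param path VCF file (plain text or gzipped).
#' @return A [GenotypeMatrix-class].
#' @export
readVcfGenotypes <- function(path) {
  hdr <- readLines(path, n = 2000L)
  body <- grep("^##", hdr, invert = TRUE)
  if (!length(body) || !startsWith(hdr[body[1]], "#CHROM"))
    stop("malformed VCF header: expected #CHROM line at line ",
         if (length(body)) body[1] else length(hdr) + 1L, " of ", path)
  cols <- strsplit(hdr[body[1]], "\t")[[1]]
  if (length(cols) < 10)
    stop("VCF has an empty sample list (line ", body[1], " of ", path, ")")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  fmt <- v@gt[, "FORMAT"]
  if (!all(grepl("(^|:)GT(:|$)", fmt)))
    stop("VCF record without a GT field in ", path)
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  multi <- grepl(",", alt, fixed = TRUE)
  indel <- !multi & (nchar(ref) != 1L | nchar(alt) != 1L)
  keep <- !multi & !indel
  nSkip <- c(multiallelic = sum(multi), indel = sum(indel))
  if (sum(nSkip) > 0)
    message("readVcfGenotypes: skipped ", nSkip["multiallelic"],
            " multiallelic site(s) and ", nSkip["indel"], " indel(s)")
  gtRaw <- v@gt[keep, -1, drop = FALSE]
  gt <- gsub("\\|", "/", sub(":.*", "", gtRaw))
  calls <- matrix(NA_integer_, nrow = ncol(gtRaw), ncol = nrow(gtRaw),
                  dimnames = list(colnames(gtRaw), NULL))
  code <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
  calls[] <- t(matrix(code[gt], nrow = nrow(gtRaw)))
  sites <- GRanges(fix[keep, "CHROM"],
                   IRanges(as.integer(fix[keep, "POS"]), width = 1),
                   ref = unname(ref[keep]), alt = unname(alt[keep]))
  o <- order(as.character(seqnames(sites)), start(sites))
  sites <- sites[o]
  calls <- calls[, o, drop = FALSE]
  # contig lengths from the header, when present
  contig <- grep("^##contig=", hdr, value = TRUE)
  ids <- sub(".*<ID=([^,>]+).*", "\\1", contig)
  lens <- suppressWarnings(as.integer(
    ifelse(grepl("length=", contig),
           sub(".*length=([0-9]+).*", "\\1", contig), NA)))
  known <- !is.na(lens) & ids %in% seqlevels(sites)
  if (any(known))
    seqlengths(sites)[ids[known]] <- lens[known]
  metadata(sites)$skipped <- nSkip
  GenotypeMatrix(calls, sites)
}

#' Write a GenotypeMatrix as minimal VCFv4.2
#'
#' Emits CHROM/POS/ID/REF/ALT/QUAL/FILTER/INFO/FORMAT(GT) with a diploid GT
#' per sample. The header carries contig lengths when the sites have
#' seqlengths, and no date line, so output is byte-reproducible.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeVcfGenotypes <- function(gm, path) {
  sites <- variantSites(gm)
  calls <- genotypeCalls(gm)
  hdr <- c("##fileformat=VCFv4.2",
           "##source=pedtrace")
  sl <- seqlengths(sites)
  for (ch in seqlevels(sites))
    hdr <- c(hdr, sprintf("##contig=<ID=%s%s>", ch,
                          if (!is.na(sl[ch])) sprintf(",length=%d", sl[ch]) else ""))
  hdr <- c(hdr, '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", rownames(calls)), collapse = "\t"))
  gtStr <- c("0/0", "0/1", "1/1")
  body <- vapply(seq_along(sites), function(j) {
    g <- calls[, j]
    gt <- ifelse(is.na(g), "./.", gtStr[g + 1L])
    paste(c(as.character(seqnames(sites))[j], start(sites)[j], ".",
            mcols(sites)$ref[j], mcols(sites)$alt[j], ".", "PASS", ".",
            "GT", gt), collapse = "\t")
  }, "")
  writeLines(c(hdr, body), path)
  invisible(path)
}

# ---- gene models -----------------------------------------------------------

# Strand-aware pieces of an exon set outside the CDS span, split into the
# 5' and 3' sides.
.utrsFromExons <- function(exons, cdsRange, strand) {
  if (!length(cdsRange)) return(list(utr5 = exons[0], utr3 = exons[0]))
  cdsStart <- min(start(cdsRange)); cdsEnd <- max(end(cdsRange))
  left <- GenomicRanges::restrict(exons, end = cdsStart - 1L)
  right <- GenomicRanges::restrict(exons, start = cdsEnd + 1L)
  if (strand == "+") list(utr5 = left, utr3 = right)
  else list(utr5 = right, utr3 = left)
}

.buildModelSet <- function(geneGr, exonsL, cdsL) {
  ids <- mcols(geneGr)$gene_id
  utr5 <- vector("list", length(ids)); utr3 <- utr5; introns <- utr5
  codingOk <- logical(length(ids)); tss <- integer(length(ids))
  for (i in seq_along(ids)) {
    st <- as.character(strand(geneGr))[i]
    ex <- sort(exonsL[[i]])
    cd <- sort(cdsL[[i]])
    u <- .utrsFromExons(ex, cd, st)
    utr5[[i]] <- u$utr5; utr3[[i]] <- u$utr3
    span <- range(ex)
    introns[[i]] <- GenomicRanges::setdiff(span, ex)
    codingOk[i] <- length(cd) > 0 && sum(width(cd)) %% 3L == 0L
    tss[i] <- if (st == "-") end(geneGr)[i] else start(geneGr)[i]
  }
  mcols(geneGr)$tss <- tss
  mcols(geneGr)$codingOk <- codingOk
  names(exonsL) <- ids; names(cdsL) <- ids
  names(utr5) <- ids; names(utr3) <- ids; names(introns) <- ids
  new("GeneModelSet", genes = geneGr,
      exons = GRangesList(exonsL), cds = GRangesList(cdsL),
      utr5 = GRangesList(utr5), utr3 = GRangesList(utr3),
      introns = GRangesList(introns))
}

#' Read gene models from GFF3
#'
#' Parses gene/mRNA/exon/CDS (and UTR) features and keeps one representative
#' transcript per gene: the one with the longest total CDS (ties broken by
#' order of appearance). Genes whose CDS length is not divisible by 3 are
#' flagged `codingOk = FALSE` rather than rejected; they are skipped by
#' coding-effect classification.
#'
#' @param path GFF3 file.
#' @return A [GeneModelSet-class].
#' @export
readGeneModels <- function(path) {
  gff <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gff$type)
  genes <- gff[type == "gene"]
  if (!length(genes)) stop("no gene features in ", path)
  txs <- gff[type %in% c("mRNA", "transcript")]
  parentOf <- function(gr) vapply(gr$Parent, function(p)
    if (length(p)) p[[1]] else NA_character_, "")
  txParent <- parentOf(txs)
  sub <- gff[type %in% c("exon", "CDS")]
  subParent <- parentOf(sub)
  geneIds <- genes$ID
  exonsL <- vector("list", length(genes)); cdsL <- exonsL
  for (i in seq_along(genes)) {
    mytx <- txs[txParent == geneIds[i]]
    if (!length(mytx)) {  # features attached directly to the gene
      ex <- sub[subParent == geneIds[i] & as.character(sub$type) == "exon"]
      cd <- sub[subParent == geneIds[i] & as.character(sub$type) == "CDS"]
    } else {
      cdsLen <- vapply(mytx$ID, function(tid)
        sum(width(sub[subParent == tid & as.character(sub$type) == "CDS"])),
        numeric(1))
      best <- mytx$ID[which.max(cdsLen)]
      ex <- sub[subParent == best & as.character(sub$type) == "exon"]
      cd <- sub[subParent == best & as.character(sub$type) == "CDS"]
    }
    if (!length(ex)) ex <- granges(genes[i])
    exonsL[[i]] <- granges(sort(ex))
    cdsL[[i]] <- granges(sort(cd))
  }
  geneGr <- granges(genes)
  mcols(geneGr)$gene_id <- geneIds
  .buildModelSet(geneGr, exonsL, cdsL)
}

#' Build gene models programmatically
#'
#' Convenience constructor for fixtures and simulations: supply gene spans
#' with strand plus per-gene exon and CDS intervals; UTRs and introns are
#' derived.
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `strand`,
#'   `start`, `end`.
#' @param exons named list (by gene id) of [IRanges::IRanges] exon intervals.
#' @param cds named list (by gene id) of CDS intervals (may be empty for
#'   non-coding genes).
#' @return A [GeneModelSet-class].
#' @export
makeGeneModels <- function(genes, exons, cds) {
  geneGr <- GRanges(genes$chrom, IRanges(genes$start, genes$end),
                    strand = genes$strand, gene_id = genes$gene_id)
  exonsL <- lapply(genes$gene_id, function(g)
    GRanges(genes$chrom[genes$gene_id == g],
            exons[[g]], strand = genes$strand[genes$gene_id == g]))
  cdsL <- lapply(genes$gene_id, function(g) {
    ir <- cds[[g]]
    if (is.null(ir) || !length(ir)) return(GRanges())
    GRanges(genes$chrom[genes$gene_id == g], ir,
            strand = genes$strand[genes$gene_id == g])
  })
  .buildModelSet(geneGr, exonsL, cdsL)
}

#' Write gene models as GFF3
#'
#' Emits gene, mRNA, exon, CDS, five_prime_UTR and three_prime_UTR features
#' with ID/Parent attributes, so models round-trip through
#' [readGeneModels()].
#'
#' @param models a [GeneModelSet-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeGeneModelsGff3 <- function(models, path) {
  rows <- character()
  fmt <- function(chrom, type, s, e, strand, attrs)
    sprintf("%s\tpedtrace\t%s\t%d\t%d\t.\t%s\t.\t%s",
            chrom, type, s, e, strand, attrs)
  g <- models@genes
  for (i in seq_along(g)) {
    id <- mcols(g)$gene_id[i]
    ch <- as.character(seqnames(g))[i]; st <- as.character(strand(g))[i]
    tid <- paste0(id, ".1")
    rows <- c(rows,
              fmt(ch, "gene", start(g)[i], end(g)[i], st,
                  sprintf("ID=%s;Name=%s", id, id)),
              fmt(ch, "mRNA", start(g)[i], end(g)[i], st,
                  sprintf("ID=%s;Parent=%s", tid, id)))
    feat <- function(gr, type) {
      if (!length(gr)) return(character())
      vapply(seq_along(gr), function(j)
        fmt(ch, type, start(gr)[j], end(gr)[j], st,
            sprintf("Parent=%s", tid)), "")
    }
    rows <- c(rows,
              feat(models@exons[[id]], "exon"),
              feat(models@cds[[id]], "CDS"),
              feat(models@utr5[[id]], "five_prime_UTR"),
              feat(models@utr3[[id]], "three_prime_UTR"))
  }
  writeLines(c("##gff-version 3", rows), path)
  invisible(path)
}

#' Genes overlapping a set of positions
#'
#' Point query against the gene-span index.
#'
#' @param models a [GeneModelSet-class].
#' @param gr query `GRanges` (typically width-1 SNP positions).
#' @return A data.frame with columns `query` (index into `gr`) and
#'   `gene_id`; zero rows when nothing overlaps.
#' @export
genesAt <- function(models, gr) {
  ov <- findOverlaps(gr, models@genes, ignore.strand = TRUE)
  data.frame(query = queryHits(ov),
             gene_id = mcols(models@genes)$gene_id[subjectHits(ov)],
             stringsAsFactors = FALSE)
}
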