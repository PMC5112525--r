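# Specific inherited alleles: sites where the offspring matches a
# donor-side parent and differs from the recurrent parent, and their
# assignment to genes.

#' Trace specifically inherited alleles
#'
#' A site qualifies when offspring, recurrent parent, and at least one donor
#' are all homozygous and non-missing, the offspring differs from the
#' recurrent parent, and the offspring equals that donor. Heterozygous sites
#' are excluded: on inbred lines they are ambiguous for origin. All donors
#' matching the offspring call are recorded (grandparents frequently share
#' alleles, so matching is reported per-donor, not collapsed).
#'
#' @param gm a [GenotypeMatrix-class].
#' @param offspring,recurrent sample ids.
#' @param donors character vector of donor-side sample ids, disjoint from
#'   `offspring` and `recurrent`.
#' @return `GRanges` of qualifying sites with metadata columns `ref`, `alt`,
#'   `offspring_call`, `recurrent_call`, and `matching_donors`
#'   (a `CharacterList`).
#' @export
traceSpecificAlleles <- function(gm, offspring, recurrent, donors) {
  ids <- sampleIds(gm)
  all_ids <- c(offspring, recurrent, donors)
  if (!all(all_ids %in% ids))
    stop("unknown sample(s): ",
         paste(setdiff(all_ids, ids), collapse = ", "))
  if (length(intersect(donors, c(offspring, recurrent))))
    stop("donors must be disjoint from offspring and recurrent parent")
  calls <- genotypeCalls(gm)
  go <- calls[offspring, ]; gr <- calls[recurrent, ]
  hom <- function(v) !is.na(v) & v != 1L
  base <- hom(go) & hom(gr) & go != gr
  donorCalls <- calls[donors, , drop = FALSE]
  matchMat <- t(apply(donorCalls, 1, function(gd) hom(gd) & gd == go))
  if (length(donors) == 1) matchMat <- matrix(matchMat, nrow = 1)
  anyMatch <- base & colSums(matchMat) > 0
  idx <- which(anyMatch)
  sites <- variantSites(gm)[idx]
  md <- lapply(idx, function(j) donors[matchMat[, j]])
  mcols(sites)$offspring_call <- go[idx]
  mcols(sites)$recurrent_call <- gr[idx]
  mcols(sites)$matching_donors <- CharacterList(md)
  sites
}

#' Assign traced alleles to genes
#'
#' A SNP hits a gene's genebody when it lies within the gene span
#' (inclusive), and its promoter when it lies within `promoterBp` upstream
#' of the TSS, strand-aware and exclusive of the gene's own body. A SNP may
#' hit multiple genes.
#'
#' @param records `GRanges` from [traceSpecificAlleles()] (any site
#'   `GRanges` works).
#' @param models a [GeneModelSet-class].
#' @param promoterBp upstream promoter span (default 2000).
#' @return List with `hits` (data.frame: `record`, `chrom`, `pos`,
#'   `gene_id`, `location` in genebody/promoter) and `genes` (per-gene
#'   summary: `gene_id`, `n_snps`, `locations`).
#' @export
assignToGenes <- function(records, models, promoterBp = 2000) {
  genes <- models@genes
  bodyOv <- findOverlaps(records, genes, ignore.strand = TRUE)
  prom <- GenomicRanges::flank(genes, promoterBp, start = TRUE)
  prom <- GenomicRanges::trim(prom)
  promOv <- findOverlaps(records, prom, ignore.strand = TRUE)
  # promoter hits exclude positions inside that same gene's body
  inBody <- paste(queryHits(bodyOv), subjectHits(bodyOv))
  promKeep <- !(paste(queryHits(promOv), subjectHits(promOv)) %in% inBody)
  nb <- length(bodyOv); np <- sum(promKeep)
  hits <- rbind(
    data.frame(record = queryHits(bodyOv),
               gene_id = mcols(genes)$gene_id[subjectHits(bodyOv)],
               location = rep("genebody", nb), stringsAsFactors = FALSE),
    data.frame(record = queryHits(promOv)[promKeep],
               gene_id = mcols(genes)$gene_id[subjectHits(promOv)[promKeep]],
               location = rep("promoter", np), stringsAsFactors = FALSE))
  hits <- hits[order(hits$record, hits$gene_id), , drop = FALSE]
  if (nrow(hits)) {
    hits$chrom <- as.character(seqnames(records))[hits$record]
    hits$pos <- start(records)[hits$record]
    hits <- hits[, c("record", "chrom", "pos", "gene_id", "location")]
    genesSummary <- do.call(rbind, lapply(split(hits, hits$gene_id),
      function(d) data.frame(gene_id = d$gene_id[1],
                             n_snps = length(unique(d$record)),
                             locations = paste(sort(unique(d$location)),
                                               collapse = ","),
                             stringsAsFactors = FALSE)))
    rownames(genesSummary) <- NULL
  } else {
    genesSummary <- data.frame(gene_id = character(), n_snps = integer(),
                               locations = character())
  }
  list(hits = hits, genes = genesSummary)
}

#' Concordance of traced alleles with a block mosaic
#'
#' Fraction of traced sites that lie inside a block whose origin is among
#' the site's matching donors. Works against either a called mosaic
#' (`GRanges` with an `origin` column from [callBlocks()]) or simulation
#' truth (a [TruthMosaic-class]; a site is concordant when either homolog's
#' origin matches).
#'
#' @param records `GRanges` from [traceSpecificAlleles()].
#' @param mosaic `GRanges` with `origin`, or a [TruthMosaic-class].
#' @return List with `concordance` (overall fraction, `NA` when there are
#'   no records) and `by_chrom` (named per-chromosome fractions).
#' @export
concordanceWithMosaic <- function(records, mosaic) {
  if (is(mosaic, "TruthMosaic")) {
    ranges <- truthOriginRanges(mosaic)
    originSets <- as.list(mcols(ranges)$origins)
  } else {
    ranges <- mosaic
    originSets <- as.list(mcols(mosaic)$origin)
  }
  if (!length(records))
    return(list(concordance = NA_real_, by_chrom = numeric()))
  ov <- findOverlaps(records, ranges)
  conc <- logical(length(records))
  donors <- as.list(mcols(records)$matching_donors)
  for (k in seq_along(ov)) {
    q <- queryHits(ov)[k]
    conc[q] <- conc[q] ||
      any(donors[[q]] %in% originSets[[subjectHits(ov)[k]]])
  }
  ch <- as.character(seqnames(records))
  list(concordance = mean(conc),
       by_chrom = vapply(split(conc, ch), mean, numeric(1)))
}

#' Write traced alleles as TSV
#'
#' @param records `GRanges` from [traceSpecificAlleles()].
#' @param path output file.
#' @param params optional named list written as `# key=value` comments.
#' @return `path`, invisibly.
#' @export
writeTraceTsv <- function(records, path, params = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(params))
    writeLines(sprintf("# %s=%s", k, params[[k]]), con)
  df <- data.frame(
    chrom = as.character(seqnames(records)), pos = start(records),
    ref = mcols(records)$ref, alt = mcols(records)$alt,
    offspring_call = mcols(records)$offspring_call,
    recurrent_call = mcols(records)$recurrent_call,
    matching_donors = vapply(as.list(mcols(records)$matching_donors),
                             paste, "", collapse = ","))
  writeLines(paste(colnames(df), collapse = "\t"), con)
  if (nrow(df))
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  invisible(path)
}
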