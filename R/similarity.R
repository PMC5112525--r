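# Pairwise genetic similarity (1 - pi) between inbred lines.

# Per-pair (diff, valid) site masks under a het policy.
# "exclude": only sites where both calls are homozygous; difference is
#   hom-ref vs hom-alt.
# "half": all sites where both calls are non-missing; het vs hom counts as
#   half a difference, het vs het as none.
.pairDiff <- function(gi, gj, hetPolicy) {
  if (hetPolicy == "exclude") {
    valid <- !is.na(gi) & !is.na(gj) & gi != 1L & gj != 1L
    diff <- numeric(length(gi))
    diff[valid] <- as.numeric(gi[valid] != gj[valid])
  } else {
    valid <- !is.na(gi) & !is.na(gj)
    diff <- numeric(length(gi))
    diff[valid] <- abs(gi[valid] - gj[valid]) / 2
  }
  list(diff = diff, valid = valid)
}

#' Pairwise genetic similarity matrix (1 - pi)
#'
#' For each sample pair, pi is the fraction of compared sites at which the
#' two genotypes differ; the similarity index is 1 - pi (Nei-Li on inbred
#' lines). Missing calls are excluded pairwise. Pairs with fewer than
#' `minSites` comparable sites are reported as `NA` with a warning.
#'
#' @param gm a [GenotypeMatrix-class] with at least two samples.
#' @param hetPolicy `"exclude"` (default; sites heterozygous in either
#'   member are dropped from that pair's comparison) or `"half"`
#'   (heterozygous-vs-homozygous counts as half a difference).
#' @param minSites minimum comparable sites per pair (default 100).
#' @return A [SimilarityMatrix-class].
#' @examples
#' sim <- runPedigree(defaultPedigreeSpec(seed = 1, chromLengthBp = 2e5))
#' pairwiseSimilarity(sim@genotypes, minSites = 10)
#' @export
pairwiseSimilarity <- function(gm, hetPolicy = c("exclude", "half"),
                               minSites = 100) {
  hetPolicy <- match.arg(hetPolicy)
  calls <- genotypeCalls(gm)
  ids <- sampleIds(gm)
  if (length(ids) < 2) stop("at least two samples required")
  n <- length(ids)
  vals <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  ncmp <- matrix(0L, n, n, dimnames = list(ids, ids))
  diag(vals) <- 1
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    pd <- .pairDiff(calls[i, ], calls[j, ], hetPolicy)
    nv <- sum(pd$valid)
    ncmp[i, j] <- ncmp[j, i] <- nv
    if (nv == 0) {
      warning("no comparable sites for pair ", ids[i], "-", ids[j])
    } else if (nv >= minSites) {
      vals[i, j] <- vals[j, i] <- 1 - sum(pd$diff) / nv
    }
  }
  und <- sum(is.na(vals[upper.tri(vals)]) & ncmp[upper.tri(ncmp)] > 0)
  if (und > 0)
    warning(und, " pair(s) had fewer than ", minSites,
            " comparable sites; reported as NA")
  new("SimilarityMatrix", values = vals, nCompared = ncmp,
      hetPolicy = hetPolicy)
}

#' Write a similarity matrix as a labelled square TSV
#'
#' @param sm a [SimilarityMatrix-class].
#' @param path output file.
#' @param params optional named list recorded as `# key=value` header
#'   comments.
#' @return `path`, invisibly.
#' @export
writeSimilarityTsv <- function(sm, path, params = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(params))
    writeLines(sprintf("# %s=%s", k, params[[k]]), con)
  v <- similarityValues(sm)
  writeLines(paste(c("sample", colnames(v)), collapse = "\t"), con)
  for (i in seq_len(nrow(v)))
    writeLines(paste(c(rownames(v)[i], format(v[i, ], digits = 10)),
                     collapse = "\t"), con)
  invisible(path)
}
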