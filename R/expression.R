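# Differential-expression filtering and integration with traced genes.
# This module consumes p-values (the upstream testing tool is out of its
# scope); the fold-change/p-value filter is the computation.

#' Call differentially expressed genes between two conditions
#'
#' A gene is up-regulated when `(fpkmA + pseudocount) / (fpkmB +
#' pseudocount) > fcThreshold` and `p < pThreshold`, and down-regulated when
#' the reciprocal fold change exceeds the threshold at the same p cutoff.
#' Both inequalities are strict: a fold change of exactly `fcThreshold` is
#' not a DEG.
#'
#' @param geneId character vector of gene ids.
#' @param fpkmA,fpkmB FPKM values in the two conditions (A vs B; "up" means
#'   higher in A).
#' @param pValue per-gene p-values for the contrast; missing values are an
#'   error — this module filters, it does not test.
#' @param fcThreshold fold-change threshold (default 2).
#' @param pThreshold p-value threshold (default 0.05).
#' @param pseudocount added to both FPKM values before the ratio
#'   (default 0.1).
#' @return List of class `DegSet`: `up` and `down` gene-id vectors
#'   (disjoint), plus the thresholds used.
#' @export
callDegs <- function(geneId, fpkmA, fpkmB, pValue, fcThreshold = 2,
                     pThreshold = 0.05, pseudocount = 0.1) {
  if (anyNA(pValue))
    stop("missing p-values: supply a p-value for every gene")
  if (any(fpkmA < 0) || any(fpkmB < 0)) stop("FPKM must be non-negative")
  fc <- (fpkmA + pseudocount) / (fpkmB + pseudocount)
  sig <- pValue < pThreshold
  up <- geneId[sig & fc > fcThreshold]
  down <- geneId[sig & (1 / fc) > fcThreshold]
  structure(list(up = up, down = down, fcThreshold = fcThreshold,
                 pThreshold = pThreshold, pseudocount = pseudocount),
            class = "DegSet")
}

#' @export
print.DegSet <- function(x, ...) {
  cat("DegSet:", length(x$up), "up,", length(x$down), "down (FC >",
      x$fcThreshold, ", p <", x$pThreshold, ")\n")
  invisible(x)
}

#' Union of DEG sets over several contrasts
#'
#' @param ... `DegSet` objects.
#' @return A `DegSet` whose `up`/`down` are the unions; a gene both up in
#'   one contrast and down in another stays in both lists.
#' @export
unionDegs <- function(...) {
  sets <- list(...)
  structure(list(up = unique(unlist(lapply(sets, `[[`, "up"))),
                 down = unique(unlist(lapply(sets, `[[`, "down"))),
                 fcThreshold = sets[[1]]$fcThreshold,
                 pThreshold = sets[[1]]$pThreshold,
                 pseudocount = sets[[1]]$pseudocount),
            class = "DegSet")
}

# Venn region counts for 2 or 3 named sets.
.vennCounts <- function(sets) {
  n <- length(sets)
  ids <- unique(unlist(sets))
  member <- vapply(sets, function(s) ids %in% s, logical(length(ids)))
  if (length(ids) == 1) member <- matrix(member, nrow = 1)
  pattern <- apply(member, 1, function(v) paste(as.integer(v), collapse = ""))
  tab <- table(pattern)
  all_patterns <- apply(expand.grid(rep(list(0:1), n))[-1, , drop = FALSE],
                        1, paste, collapse = "")
  out <- setNames(integer(length(all_patterns)), all_patterns)
  out[names(tab)] <- as.integer(tab)
  names(out) <- vapply(names(out), function(p) {
    inc <- as.logical(as.integer(strsplit(p, "")[[1]]))
    paste(names(sets)[inc], collapse = "&")
  }, "")
  out
}

#' Venn overlaps between DEG sets
#'
#' Counts every exclusive Venn region of the up and down lists separately,
#' and the "common DEGs" total for a pair of sets: the genes up in both
#' plus the genes down in both.
#'
#' @param degSets named list of 2 or 3 `DegSet` objects.
#' @return List with `up` and `down` exclusive-region counts, `union_up`,
#'   `union_down`, and (for two sets) `common_total`.
#' @export
degOverlaps <- function(degSets) {
  if (length(degSets) < 2) stop("need at least two DEG sets")
  if (is.null(names(degSets)))
    names(degSets) <- paste0("set", seq_along(degSets))
  ups <- lapply(degSets, `[[`, "up")
  downs <- lapply(degSets, `[[`, "down")
  out <- list(up = .vennCounts(ups), down = .vennCounts(downs),
              union_up = length(unique(unlist(ups))),
              union_down = length(unique(unlist(downs))))
  if (length(degSets) == 2) {
    out$common_total <- length(intersect(ups[[1]], ups[[2]])) +
      length(intersect(downs[[1]], downs[[2]]))
  }
  out
}

#' Drought/watered log2 expression ratio
#'
#' `log2((fpkmDrought + pseudocount) / (fpkmWatered + pseudocount))`;
#' symmetric around 0, and 0 when both values are 0.
#'
#' @param fpkmDrought,fpkmWatered FPKM values (vectorised).
#' @param pseudocount default 0.1.
#' @return Numeric vector of log2 ratios.
#' @export
log2StressRatio <- function(fpkmDrought, fpkmWatered, pseudocount = 0.1) {
  log2((fpkmDrought + pseudocount) / (fpkmWatered + pseudocount))
}

#' Intersect DEGs with genes carrying specific inherited alleles
#'
#' @param degSet a `DegSet` (e.g. the union over contrasts).
#' @param tracedGenes data.frame from [assignToGenes()]`$genes` (needs
#'   `gene_id`, `locations`).
#' @return data.frame of genes in both sets with `direction`
#'   (up/down), `n_snps` and `locations` provenance.
#' @export
intersectWithTracedGenes <- function(degSet, tracedGenes) {
  degs <- data.frame(
    gene_id = c(degSet$up, degSet$down),
    direction = c(rep("up", length(degSet$up)),
                  rep("down", length(degSet$down))),
    stringsAsFactors = FALSE)
  out <- merge(degs, tracedGenes, by = "gene_id")
  out[order(out$gene_id), , drop = FALSE]
}

#' Simulate a toy expression table with planted DEGs
#'
#' Emulates FPKM observations for one variety over well-watered and drought
#' conditions at three time points, with a chosen fraction of genes planted
#' as drought-responsive (shifted by a log-uniform fold change above the
#' filter threshold) and per-contrast p-values drawn small for planted
#' genes and large otherwise. The p-values are synthetic placeholders for
#' an upstream test, which this package deliberately does not perform.
#'
#' @param geneIds character vector of gene ids.
#' @param degFraction fraction of genes planted as DEGs (default 0.2).
#' @param seed integer seed.
#' @return List with `fpkm` (long data.frame: `gene_id`, `condition`,
#'   `time_point`, `fpkm`), `pvalues` (per gene and contrast), `contrasts`
#'   (the three contrast definitions), and `truth` (`up`/`down` planted
#'   sets, for the drought-vs-watered contrast at T1).
#' @export
simulateExpression <- function(geneIds, degFraction = 0.2, seed = 1L) {
  set.seed(seed)
  n <- length(geneIds)
  base <- rlnorm(n, meanlog = 2, sdlog = 1)
  nDeg <- round(degFraction * n)
  degIdx <- sample.int(n, nDeg)
  dirUp <- rbinom(nDeg, 1, 0.5) == 1
  fold <- 2^runif(nDeg, 1.4, 2.6)      # fold change 2.6x - 6x
  conds <- expand.grid(condition = c("well_watered", "drought"),
                       time_point = c("T1", "T2", "T3"),
                       stringsAsFactors = FALSE)
  fpkm <- do.call(rbind, lapply(seq_len(nrow(conds)), function(i) {
    mult <- rep(1, n)
    if (conds$condition[i] == "drought") {
      mult[degIdx[dirUp]] <- fold[dirUp]
      mult[degIdx[!dirUp]] <- 1 / fold[!dirUp]
    }
    noise <- rlnorm(n, 0, 0.05)
    data.frame(gene_id = geneIds, condition = conds$condition[i],
               time_point = conds$time_point[i],
               fpkm = base * mult * noise, stringsAsFactors = FALSE)
  }))
  contrasts <- data.frame(
    label = c("D_T1_vs_WW_T1", "D_T2_vs_D_T1", "D_T3_vs_D_T2"),
    a_condition = c("drought", "drought", "drought"),
    a_time = c("T1", "T2", "T3"),
    b_condition = c("well_watered", "drought", "drought"),
    b_time = c("T1", "T1", "T2"), stringsAsFactors = FALSE)
  pvalues <- do.call(rbind, lapply(contrasts$label, function(lb) {
    p <- runif(n, 0.2, 1)
    if (lb == "D_T1_vs_WW_T1") p[degIdx] <- runif(nDeg, 0, 0.01)
    data.frame(gene_id = geneIds, contrast = lb, p_value = p,
               stringsAsFactors = FALSE)
  }))
  list(fpkm = fpkm, pvalues = pvalues, contrasts = contrasts,
       truth = list(up = sort(geneIds[degIdx[dirUp]]),
                    down = sort(geneIds[degIdx[!dirUp]])))
}

#' Apply the DEG filter to one contrast of an expression table
#'
#' @param expr output of [simulateExpression()] or a list with the same
#'   `fpkm`/`pvalues`/`contrasts` layout.
#' @param label which contrast.
#' @param ... passed to [callDegs()].
#' @return A `DegSet`.
#' @export
degsForContrast <- function(expr, label, ...) {
  co <- expr$contrasts[expr$contrasts$label == label, ]
  if (!nrow(co)) stop("unknown contrast: ", label)
  a <- expr$fpkm[expr$fpkm$condition == co$a_condition &
                   expr$fpkm$time_point == co$a_time, ]
  b <- expr$fpkm[expr$fpkm$condition == co$b_condition &
                   expr$fpkm$time_point == co$b_time, ]
  p <- expr$pvalues[expr$pvalues$contrast == label, ]
  ord <- a$gene_id
  callDegs(ord, a$fpkm[match(ord, a$gene_id)],
           b$fpkm[match(ord, b$gene_id)],
           p$p_value[match(ord, p$gene_id)], ...)
}
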