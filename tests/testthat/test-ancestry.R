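# Window diversity, the diversity-decreased level, bimodal thresholding,
# block calling and contribution fractions.

test_that("diversity-decreased level follows its definition", {
  # d_arv = 0.4, d_pair = 0.1 -> decrease = 0.75; d_pair == d_arv -> 0;
  # d_pair = 0 -> 1. Construct a 4-sample window achieving these.
  sites <- GRanges("chr1", IRanges(seq(10, 100, by = 10), width = 1),
                   ref = "A", alt = "T")
  # descendant identical to ancestor A; B differs everywhere
  calls <- rbind(desc = rep(0L, 10), A = rep(0L, 10), B = rep(2L, 10))
  gm <- GenotypeMatrix(calls, sites)
  w <- GRanges("chr1", IRanges(1, 200))
  metadata(w)$stepBp <- 200
  prof <- windowDiversity(gm, w, "desc", c("A", "B"), minSnps = 1)
  # pairs: desc-A (0), desc-B (1), A-B (1) -> dArv = 2/3
  expect_equal(prof@dArv, 2 / 3)
  expect_equal(unname(prof@decrease[1, "A"]), 1)          # Dpair = 0
  expect_equal(unname(prof@decrease[1, "B"]), (2/3 - 1) / (2/3))
  # direct formula case
  expect_equal((0.4 - 0.1) / 0.4, 0.75)
  expect_equal((0.4 - 0.4) / 0.4, 0)
})

test_that("per-window values equal a brute-force recount on random
           fixtures", {
  gm <- randomGenotypeMatrix(nSamples = 4, nSites = 300, seed = 7,
                             nChrom = 2, chromLen = 5e4)
  w <- makeWindows(setNames(c(5e4, 5e4), c("chr1", "chr2")),
                   windowBp = 1e4, stepBp = 5e3)
  ids <- sampleIds(gm)
  prof <- windowDiversity(gm, w, ids[1], ids[2:4], minSnps = 1)
  # Dpair against each ancestor
  for (a in ids[2:4]) {
    o <- oracleWindowDiversity(gm, w, ids[1], a)
    expect_equal(unname(prof@dPair[, a]), unname(o["d", ]),
                 tolerance = 1e-12)
    expect_equal(unname(prof@nSnps[, a]), unname(o["n", ]))
  }
  # Darv: mean of all C(4,2) pairwise diversities
  pairs <- combn(ids, 2)
  dmat <- sapply(seq_len(ncol(pairs)), function(k)
    oracleWindowDiversity(gm, w, pairs[1, k], pairs[2, k])["d", ])
  expect_equal(prof@dArv, rowMeans(dmat, na.rm = TRUE), tolerance = 1e-12)
})

test_that("windows with zero usable SNPs are uninformative, never NaN", {
  sites <- GRanges("chr1", IRanges(c(10, 20), width = 1),
                   ref = "A", alt = "T")
  calls <- rbind(d = c(0L, 0L), a = c(0L, 2L), b = c(1L, NA))
  gm <- GenotypeMatrix(calls, sites)
  w <- makeWindows(c(chr1 = 300), windowBp = 100, stepBp = 100)
  prof <- windowDiversity(gm, w, "d", c("a", "b"), minSnps = 1)
  expect_false(any(is.nan(prof@decrease)))
  expect_true(all(is.na(prof@decrease[2:3, ])))  # empty windows
})

test_that("EM thresholding separates a clear two-component mixture", {
  set.seed(99)
  vals <- c(rnorm(500, 0.10, 0.02), rnorm(500, 0.85, 0.05))
  fit <- bimodalThreshold(vals)
  expect_false(fit$unimodal)
  expect_gt(fit$threshold, 0.3)
  expect_lt(fit$threshold, 0.6)
  expect_true(all(fit$weights > 0.4 & fit$weights < 0.6))
  expect_equal(fit$means, c(0.10, 0.85), tolerance = 0.02)
  # misassignment below 1%: the threshold cleanly splits the components
  truth <- rep(c(FALSE, TRUE), each = 500)
  expect_lt(mean((vals > fit$threshold) != truth), 0.01)
})

test_that("EM agrees with an independent mixture fit (mclust)", {
  skip_if_not_installed("mclust")
  suppressPackageStartupMessages(library(mclust))
  set.seed(123)
  vals <- c(rnorm(400, 0.2, 0.05), rnorm(600, 0.8, 0.08))
  fit <- bimodalThreshold(vals)
  mc <- Mclust(vals, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(sort(fit$means), sort(as.numeric(mc$parameters$mean)),
               tolerance = 0.02)
})

test_that("degenerate and deterministic thresholding behaviour", {
  expect_error(bimodalThreshold(rep(0.5, 10)), "insufficient windows")
  fitFlat <- bimodalThreshold(rep(0.5, 100))
  expect_true(fitFlat$unimodal)
  expect_equal(fitFlat$threshold, 0.5)
  set.seed(7); vals <- rnorm(200, 0.4, 0.01)  # unimodal cloud
  fitUni <- bimodalThreshold(vals)
  expect_true(fitUni$unimodal)
  expect_identical(bimodalThreshold(vals), bimodalThreshold(vals))
})

test_that("uniform-origin windows yield one chromosome-spanning block", {
  # descendant is an exact copy of ancestor s1: every window favours s1
  gm0 <- randomGenotypeMatrix(nSamples = 3, nSites = 400, seed = 13,
                              hetRate = 0, missingRate = 0,
                              nChrom = 2, chromLen = 1e5)
  calls <- rbind(genotypeCalls(gm0), desc = genotypeCalls(gm0)["s1", ])
  gm <- GenotypeMatrix(calls, variantSites(gm0))
  w <- makeWindows(c(chr1 = 1e5, chr2 = 1e5), windowBp = 2e4, stepBp = 5e3)
  prof <- windowDiversity(gm, w, "desc", c("s1", "s2"), minSnps = 3)
  thr <- list(s1 = list(threshold = 0.5), s2 = list(threshold = 0.5))
  blocks <- callBlocks(prof, thr)
  expect_equal(length(blocks), 2)
  expect_true(all(mcols(blocks)$origin == "s1"))
  expect_equal(sum(width(blocks)), 2e5)
  cf <- contributionFractions(blocks, c(chr1 = 1e5, chr2 = 1e5))
  expect_equal(unname(cf$fractions["s1"]), 1)
  expect_equal(cf$unassigned_bp, 0)
})

test_that("uncertain runs between blocks split at the midpoint; terminal
           runs attach to the single adjacent block", {
  # hand-built profile: chromosome of 12 step-tiles, window == step
  w <- makeWindows(c(chr1 = 1200), windowBp = 100, stepBp = 100)
  dec <- matrix(NA_real_, length(w), 2, dimnames = list(NULL, c("A", "B")))
  lab <- c("A", "A", "A", "A", NA, NA, NA, NA, "B", "B", "B", "B")
  dec[lab == "A" & !is.na(lab), "A"] <- 0.9
  dec[lab == "B" & !is.na(lab), "B"] <- 0.9
  prof <- new("DiversityProfile", windows = w, descendant = "d",
              ancestors = c("A", "B"), dPair = dec * 0, dArv = rep(0.5, 12),
              decrease = dec, nSnps = matrix(100L, 12, 2,
                dimnames = list(NULL, c("A", "B"))), minSnps = 1L)
  thr <- list(A = list(threshold = 0.5), B = list(threshold = 0.5))
  blocks <- callBlocks(prof, thr)
  expect_equal(length(blocks), 2)
  # 4-tile uncertain run [401, 800]: midpoint 600
  expect_equal(end(blocks)[1], 600)
  expect_equal(start(blocks)[2], 601)
  expect_equal(mcols(blocks)$origin, c("A", "B"))
  # terminal uncertain run attaches to its single neighbour
  lab2 <- dec; lab2[1:3, ] <- NA  # head tiles uncertain
  prof2 <- prof; prof2@decrease <- lab2
  blocks2 <- callBlocks(prof2, thr)
  expect_equal(start(blocks2)[1], 1)
})

test_that("an entirely uncertain chromosome is reported unassigned", {
  w <- makeWindows(c(chr1 = 500), windowBp = 100, stepBp = 100)
  dec <- matrix(NA_real_, 5, 1, dimnames = list(NULL, "A"))
  prof <- new("DiversityProfile", windows = w, descendant = "d",
              ancestors = "A", dPair = dec, dArv = rep(NA_real_, 5),
              decrease = dec,
              nSnps = matrix(0L, 5, 1, dimnames = list(NULL, "A")),
              minSnps = 1L)
  expect_warning(blocks <- callBlocks(prof, list(A = list(threshold = 0.5))),
                 "entirely uncertain")
  expect_length(blocks, 0)
  expect_error(contributionFractions(blocks, c(chr1 = 500)), "assigned")
})

test_that("a single simulated crossover is recovered within one window", {
  # doubled-haploid descendant built from one F1 gamete with exactly one
  # crossover, so the true breakpoint is known to the base pair
  spec <- PedigreeSpec(
    founders = c("A", "B"),
    crosses = data.frame(mother = "A", father = "B", child = "hyb",
                         selfing = 0L),
    genome = data.frame(chrom = "chr1", length_bp = 2e6,
                        length_morgans = 1),
    snpDensity = 1e-3, seed = 17L)
  fs <- simulateFounders(spec)
  hyb <- crossIndividuals(founderIndividual(fs, spec, "A"),
                          founderIndividual(fs, spec, "B"), 1, 2, id = "hyb")
  g <- NULL
  for (s in 1:50) {
    cand <- simulateMeiosis(hyb, s + 300)
    if (length(cand$crossovers$chr1) == 1 &&
        nrow(cand$segs$chr1) == 2) { g <- cand; break }
  }
  expect_false(is.null(g))
  breakTrue <- g$segs$chr1$end[1]
  calls <- rbind(A = fs@alleles["A", ] * 2L, B = fs@alleles["B", ] * 2L,
                 desc = g$alleles * 2L)
  gm <- GenotypeMatrix(calls, fs@sites)
  w <- makeWindows(spec@genome, windowBp = 1e5, stepBp = 1e4)
  prof <- windowDiversity(gm, w, "desc", c("A", "B"), minSnps = 5)
  blocks <- callBlocks(prof, list(A = list(threshold = 0.5),
                                  B = list(threshold = 0.5)))
  expect_equal(mcols(blocks)$origin,
               g$segs$chr1$origin)
  breakEst <- end(blocks)[1]
  expect_lt(abs(breakEst - breakTrue), 1e5 + 1)  # within one window
})

test_that("block-origin recovery and contribution errors on the default
           pedigree stay within tolerance", {
  accs <- c(); errs <- c()
  for (s in 1:3) {
    sim <- runPedigree(tinySpec(seed = s + 70, chromLengthBp = 2e6))
    spec <- sim@spec
    gmP <- subsetSamples(sim@genotypes,
                         c("grandparentA", "grandparentB", "recurrent",
                           "donor", "offspring"))
    w <- makeWindows(spec@genome)
    prof <- windowDiversity(gmP, w, "offspring",
                            c("grandparentA", "grandparentB", "recurrent"))
    thr <- ancestryThresholds(prof)
    blocks <- callBlocks(prof, thr)
    accs <- c(accs, mosaicAccuracy(blocks, sim@mosaics[["offspring"]]))
    cf <- contributionFractions(blocks, spec@genome)
    tc <- truthContributions(sim@mosaics[["offspring"]])
    est <- cf$fractions[names(tc)]
    est[is.na(est)] <- 0
    errs <- c(errs, max(abs(est - tc)))
  }
  expect_true(all(accs >= 0.95))
  expect_true(all(errs <= 0.05))
})

test_that("contribution fractions over the assigned genome sum to one", {
  sim <- runPedigree(tinySpec(seed = 33))
  gmP <- subsetSamples(sim@genotypes,
                       c("grandparentA", "grandparentB", "recurrent",
                         "donor", "offspring"))
  w <- makeWindows(sim@spec@genome, windowBp = 5e4, stepBp = 1e4)
  prof <- windowDiversity(gmP, w, "offspring",
                          c("grandparentA", "grandparentB", "recurrent"))
  blocks <- callBlocks(prof, ancestryThresholds(prof, minWindows = 10))
  cf <- contributionFractions(blocks, sim@spec@genome)
  expect_equal(sum(cf$fractions), 1, tolerance = 1e-9)
  expect_equal(cf$assigned_bp + cf$unassigned_bp,
               sum(sim@spec@genome$length_bp))
})
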