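# Simulator: founder generation, meiosis model, pedigree truth bookkeeping.

test_that("founder site counts follow the density model and are shared", {
  spec <- PedigreeSpec(
    founders = c("A", "B"), crosses = data.frame(
      mother = character(), father = character(), child = character(),
      selfing = integer()),
    genome = data.frame(chrom = "chr1", length_bp = 1e6,
                        length_morgans = 1),
    snpDensity = 1e-3, seed = 11L)
  fs <- simulateFounders(spec)
  n <- length(fs@sites)
  # Poisson(1000): 3 SD band
  expect_gt(n, 1000 - 3 * sqrt(1000))
  expect_lt(n, 1000 + 3 * sqrt(1000))
  expect_true(all(diff(start(fs@sites)) > 0))
  expect_identical(dim(fs@alleles), c(2L, n))
})

test_that("polymorphism rate 0 makes all founders identical, and the seed
           contract gives bit-identical output", {
  spec <- tinySpec(seed = 4, polymorphismRate = 0)
  fs <- simulateFounders(spec)
  expect_true(all(fs@alleles == fs@alleles[rep(1, nrow(fs@alleles)), ]))
  spec2 <- tinySpec(seed = 4)
  expect_identical(simulateFounders(spec2), simulateFounders(spec2))
  sim1 <- runPedigree(spec2)
  sim2 <- runPedigree(spec2)
  expect_identical(genotypeCalls(sim1@genotypes),
                   genotypeCalls(sim2@genotypes))
  expect_identical(sim1@mosaics, sim2@mosaics)
})

test_that("configuration errors are caught", {
  expect_error(defaultPedigreeSpec(snpDensity = 0), "snpDensity")
  expect_error(defaultPedigreeSpec(nChrom = 0), "chromosome")
  badCrosses <- data.frame(mother = "nobody", father = "recurrent",
                           child = "x", selfing = 0L)
  expect_error(PedigreeSpec(
    founders = "recurrent", crosses = badCrosses,
    genome = data.frame(chrom = "chr1", length_bp = 1e5,
                        length_morgans = 1)), "not defined")
})

test_that("meiosis crossover counts match the Haldane expectation", {
  spec <- PedigreeSpec(
    founders = c("A", "B"),
    crosses = data.frame(mother = "A", father = "B", child = "F1",
                         selfing = 0L),
    genome = data.frame(chrom = "chr1", length_bp = 1e5,
                        length_morgans = 2),
    snpDensity = 5e-4, seed = 21L)
  fs <- simulateFounders(spec)
  f1 <- crossIndividuals(founderIndividual(fs, spec, "A"),
                         founderIndividual(fs, spec, "B"), 1, 2, id = "F1")
  nxo <- vapply(seq_len(1000), function(s)
    length(simulateMeiosis(f1, s + 100)$crossovers$chr1), 1L)
  se <- sqrt(2 / 1000)  # Poisson(2) mean over 1000 meioses
  expect_lt(abs(mean(nxo) - 2), 3 * se)
})

test_that("zero genetic length gives an intact parental haplotype and a
           homozygous parent transmits its haplotype regardless", {
  spec <- PedigreeSpec(
    founders = c("A", "B"),
    crosses = data.frame(mother = "A", father = "B", child = "F1",
                         selfing = 0L),
    genome = data.frame(chrom = "chr1", length_bp = 2e5,
                        length_morgans = 0),
    snpDensity = 1e-3, seed = 3L)
  fs <- simulateFounders(spec)
  f1 <- crossIndividuals(founderIndividual(fs, spec, "A"),
                         founderIndividual(fs, spec, "B"), 5, 6, id = "F1")
  g <- simulateMeiosis(f1, 7)
  expect_true(identical(g$alleles, f1$haps[[1]]$alleles) ||
                identical(g$alleles, f1$haps[[2]]$alleles))
  expect_length(g$crossovers$chr1, 0)
  # homozygous parent: gamete == its haplotype even with crossovers
  specR <- PedigreeSpec(
    founders = c("A", "B"),
    crosses = data.frame(mother = "A", father = "B", child = "F1",
                         selfing = 0L),
    genome = data.frame(chrom = "chr1", length_bp = 2e5,
                        length_morgans = 3),
    snpDensity = 1e-3, seed = 3L)
  fsR <- simulateFounders(specR)
  a <- founderIndividual(fsR, specR, "A")
  gA <- simulateMeiosis(a, 8)
  expect_identical(gA$alleles, a$haps[[1]]$alleles)
})

test_that("BC1 recurrent-parent genome fraction averages 75%", {
  fracs <- vapply(1:200, function(s) {
    spec <- PedigreeSpec(
      founders = c("donor", "recurrent"),
      crosses = data.frame(
        mother = c("donor", "f1"), father = c("recurrent", "recurrent"),
        child = c("f1", "bc1"), selfing = c(0L, 0L)),
      genome = data.frame(chrom = c("chr1", "chr2"),
                          length_bp = c(1e5, 1e5),
                          length_morgans = c(1, 1)),
      snpDensity = 1e-4, seed = s)
    sim <- runPedigree(spec)
    unname(truthContributions(sim@mosaics[["bc1"]])["recurrent"])
  }, 1)
  # theoretical SD of the BC1 fraction is large on a 2-chromosome genome;
  # use the empirical SE
  se <- sd(fracs) / sqrt(length(fracs))
  expect_lt(abs(mean(fracs) - 0.75), 3 * se)
})

test_that("selfing halves residual heterozygosity per generation", {
  hetAt <- function(nSelf) {
    vapply(1:40, function(s) {
      spec <- PedigreeSpec(
        founders = c("A", "B"),
        crosses = data.frame(mother = "A", father = "B", child = "L",
                             selfing = as.integer(nSelf)),
        genome = data.frame(chrom = "chr1", length_bp = 5e5,
                            length_morgans = 1),
        snpDensity = 2e-4, seed = s + 500)
      unname(hetRate(runPedigree(spec)@genotypes)["L"])
    }, 1)
  }
  h0 <- mean(hetAt(0)); h2 <- mean(hetAt(2)); h4 <- mean(hetAt(4))
  # F1 het ~= polymorphism rate (0.5); each selfing halves it in expectation
  expect_gt(h0, h2)
  expect_gt(h2, h4)
  expect_lt(abs(h2 / h0 - 0.25), 0.08)
  expect_lt(abs(h4 / h0 - 0.0625), 0.04)
})

test_that("truth mosaics tile chromosomes exactly and contributions sum
           to 1", {
  sim <- runPedigree(tinySpec(seed = 9))
  for (m in sim@mosaics) {
    expect_true(validObject(m))  # validity enforces exact tiling
    expect_equal(sum(truthContributions(m)), 1, tolerance = 1e-9)
  }
  tc <- truthContributions(sim@mosaics[["offspring"]])
  expect_true(all(names(tc) %in% sim@spec@founders))
})

test_that("truth BED output is 0-based half-open and round-trips widths", {
  sim <- runPedigree(tinySpec(seed = 2))
  path <- withr::local_tempfile(fileext = ".bed")
  writeTruthBed(sim@mosaics[["offspring"]], path)
  bed <- read.delim(path, header = FALSE)
  expect_true(all(bed$V3 > bed$V2))
  expect_equal(sum(bed$V3 - bed$V2),
               2 * sum(sim@spec@genome$length_bp))
  expect_true(all(bed$V5 %in% 1:2))
})
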