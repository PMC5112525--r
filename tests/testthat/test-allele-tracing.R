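# Specific inherited alleles and their gene assignment.

.traceFixture <- function() {
  sites <- GRanges("chr1", IRanges(seq(100, 1200, by = 100), width = 1),
                   ref = "A", alt = "T")
  n <- length(sites)
  # recurrent all hom-ref; offspring matches donorA at 5 planted sites
  off <- rep(0L, n); rec <- rep(0L, n)
  dA <- rep(0L, n); dB <- rep(0L, n)
  planted <- c(2, 4, 6, 8, 10)
  off[planted] <- 2L; dA[planted] <- 2L
  dB[4] <- 2L                      # shares one planted allele
  off[11] <- 1L; dA[11] <- 2L      # het offspring: excluded
  off[12] <- 2L; dA[12] <- NA      # donor missing, no other match
  calls <- rbind(off = off, rec = rec, donorA = dA, donorB = dB)
  list(gm = GenotypeMatrix(calls, sites), planted = planted)
}

test_that("planted donor-specific sites are traced with their donors", {
  fx <- .traceFixture()
  rec <- traceSpecificAlleles(fx$gm, "off", "rec", c("donorA", "donorB"))
  expect_equal(start(rec), 100 * fx$planted)
  donors <- as.list(mcols(rec)$matching_donors)
  expect_true(all(vapply(donors, function(d) "donorA" %in% d, TRUE)))
  expect_setequal(donors[[which(fx$planted == 4)]], c("donorA", "donorB"))
  # every traced site is polymorphic offspring vs recurrent by construction
  expect_true(all(mcols(rec)$offspring_call != mcols(rec)$recurrent_call))
})

test_that("offspring identical to recurrent yields no traced sites, and
           monomorphic sites are excluded", {
  sites <- GRanges("chr1", IRanges(c(10, 20, 30), width = 1),
                   ref = "A", alt = "T")
  calls <- rbind(off = c(0L, 2L, 2L), rec = c(0L, 2L, 2L),
                 d = c(2L, 2L, 0L))
  gm <- GenotypeMatrix(calls, sites)
  expect_length(traceSpecificAlleles(gm, "off", "rec", "d"), 0)
  expect_error(traceSpecificAlleles(gm, "off", "rec", "rec"), "disjoint")
})

test_that("gene assignment distinguishes genebody from promoter and
           matches a brute-force interval scan", {
  fx <- toyModelFixture()
  g <- geneRanges(fx$models)
  # gPlus: span 3001-3800, TSS 3001; SNP at TSS-500 => promoter
  sites <- GRanges("chrM", IRanges(c(2501, 3400, 900, 5500, 5290), width = 1),
                   ref = "A", alt = "T")
  asg <- assignToGenes(sites, fx$models, promoterBp = 2000)
  hit <- function(i) asg$hits[asg$hits$record == i, ]
  expect_equal(hit(1)$gene_id, "gPlus")
  expect_equal(hit(1)$location, "promoter")
  expect_equal(hit(2)$location, "genebody")     # intron position
  expect_equal(nrow(hit(3)), 0)                 # far upstream intergenic
  expect_equal(hit(4)$gene_id, "gMinus")        # minus-strand promoter
  expect_equal(hit(4)$location, "promoter")
  expect_equal(hit(5)$location, "genebody")
  # brute-force check on random positions
  set.seed(31)
  pos <- sample.int(fx$chromLen, 400)
  rnd <- GRanges("chrM", IRanges(pos, width = 1), ref = "A", alt = "T")
  asgR <- assignToGenes(rnd, fx$models, promoterBp = 2000)
  for (k in seq_along(rnd)) {
    expected <- character()
    for (i in seq_along(g)) {
      gid <- mcols(g)$gene_id[i]
      st <- as.character(strand(g))[i]
      tss <- if (st == "-") end(g)[i] else start(g)[i]
      if (pos[k] >= start(g)[i] && pos[k] <= end(g)[i])
        expected <- c(expected, paste(gid, "genebody"))
      else if (st == "+" && pos[k] < tss && pos[k] >= tss - 2000)
        expected <- c(expected, paste(gid, "promoter"))
      else if (st == "-" && pos[k] > tss && pos[k] <= tss + 2000)
        expected <- c(expected, paste(gid, "promoter"))
    }
    got <- paste(asgR$hits$gene_id[asgR$hits$record == k],
                 asgR$hits$location[asgR$hits$record == k])
    expect_setequal(got, expected)
  }
})

test_that("gene-level summary grows monotonically with promoter span", {
  fx <- toyModelFixture()
  set.seed(12)
  pos <- sort(sample.int(fx$chromLen, 250))
  sites <- GRanges("chrM", IRanges(pos, width = 1), ref = "A", alt = "T")
  counts <- vapply(c(0, 500, 1000, 2000, 3000), function(pb)
    sum(assignToGenes(sites, fx$models, promoterBp = pb)$genes$n_snps),
    1)
  expect_true(all(diff(counts) >= 0))
})

test_that("concordance against truth and called mosaics behaves at the
           boundaries", {
  # empty records: not applicable
  empty <- GRanges()
  mcols(empty)$matching_donors <- CharacterList()
  blocks <- GRanges("chr1", IRanges(1, 1000), origin = "rec")
  expect_true(is.na(concordanceWithMosaic(empty, blocks)$concordance))
  # all blocks from the recurrent parent: concordance 0
  sites <- GRanges("chr1", IRanges(c(100, 200), width = 1),
                   ref = "A", alt = "T")
  mcols(sites)$matching_donors <- CharacterList(list("d", "d"))
  expect_equal(concordanceWithMosaic(sites, blocks)$concordance, 0)
  # matching origin: concordance 1
  blocksD <- GRanges("chr1", IRanges(1, 1000), origin = "d")
  expect_equal(concordanceWithMosaic(sites, blocksD)$concordance, 1)
})

test_that("simulated traced alleles are concordant with truth blocks", {
  conc <- vapply(1:5, function(s) {
    sim <- runPedigree(tinySpec(seed = s + 90, chromLengthBp = 1e6))
    tr <- traceSpecificAlleles(sim@genotypes, "offspring", "recurrent",
                               c("donor", "grandparentA", "grandparentB"))
    concordanceWithMosaic(tr, sim@mosaics[["offspring"]])$concordance
  }, 1)
  # replicates whose offspring carries no donor content have no traced
  # sites (concordance not applicable); the rest must be concordant
  expect_gte(sum(!is.na(conc)), 2)
  expect_true(all(conc[!is.na(conc)] >= 0.95))
})
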