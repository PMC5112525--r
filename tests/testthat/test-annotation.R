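# Feature classification and coding-effect calls.

test_that("splice sites, promoters and intergenic positions classify by
           definition", {
  fx <- toyModelFixture()
  # gPlus intron: 3301..3500
  sites <- GRanges("chrM", IRanges(c(3301, 3302, 3400, 3500, 3499,
                                     2900, 100), width = 1),
                   ref = "A", alt = "T")
  ann <- classifyFeatures(sites, fx$models)
  expect_equal(as.character(ann$feature),
               c("splice_site", "splice_site", "intron", "splice_site",
                 "splice_site", "promoter", "intergenic"))
  expect_equal(ann$gene_id[1], "gPlus")
  expect_true(is.na(ann$gene_id[7]))
})

test_that("classification equals brute-force re-derivation on random
           fixtures", {
  fx <- toyModelFixture()
  set.seed(77)
  pos <- sample.int(fx$chromLen, 500)
  sites <- GRanges("chrM", IRanges(pos, width = 1), ref = "A", alt = "T")
  ann <- classifyFeatures(sites, fx$models)
  for (k in seq_along(pos)) {
    o <- oracleClassify(pos[k], fx$models)
    expect_equal(as.character(ann$feature[k]), o$feature,
                 info = paste("pos", pos[k]))
    if (!is.na(ann$gene_id[k]) || !is.na(o$gene))
      expect_equal(ann$gene_id[k], o$gene, info = paste("pos", pos[k]))
  }
})

test_that("canonical codon-table cases classify correctly", {
  # single-exon plus-strand gene whose CDS we control base by base
  cdsSeq <- paste0("ATG", "GGA", "TGG", "TTC", "AAA", "TAA")  # 6 codons
  genomeSeq <- paste0(strrep("C", 100), cdsSeq, strrep("C", 100))
  genome <- DNAStringSet(c(chrT = genomeSeq))
  genes <- data.frame(gene_id = "g", chrom = "chrT", strand = "+",
                      start = 101L, end = 118L)
  models <- makeGeneModels(genes, exons = list(g = IRanges(101, 118)),
                           cds = list(g = IRanges(101, 118)))
  mk <- function(pos, ref, alt)
    GRanges("chrT", IRanges(pos, width = 1), ref = ref, alt = alt)
  # GGA -> GGG at codon position 3: synonymous (Gly -> Gly)
  eff <- codingEffects(mk(106, "A", "G"), models, genome)
  expect_equal(eff$effect, "synonymous")
  expect_equal(eff$ref_codon, "GGA"); expect_equal(eff$alt_codon, "GGG")
  # TGG -> TGA: stop gain (Trp -> *)
  eff <- codingEffects(mk(109, "G", "A"), models, genome)
  expect_equal(eff$effect, "stop_gain")
  # TAA -> CAA at the annotated stop: stop loss
  eff <- codingEffects(mk(116, "T", "C"), models, genome)
  expect_equal(eff$effect, "stop_loss")
  # TTC -> TTA: nonsynonymous (Phe -> Leu)
  eff <- codingEffects(mk(112, "C", "A"), models, genome)
  expect_equal(eff$effect, "nonsynonymous")
  # reference mismatch against the genome is an error naming the site
  expect_error(codingEffects(mk(106, "T", "G"), models, genome),
               "chrT:106")
})

test_that("coding effects match the whole-protein translation oracle on
           both strands", {
  fx <- toyModelFixture()
  for (gid in c("gPlus", "gMinus")) {
    cd <- sort(fx$models@cds[[gid]])
    cdsPos <- unlist(lapply(seq_along(cd), function(k)
      start(cd)[k]:end(cd)[k]))
    set.seed(5)
    testPos <- sample(cdsPos, 60)
    for (pos in testPos) {
      refBase <- as.character(subseq(fx$genome[["chrM"]], pos, pos))
      altBase <- sample(setdiff(c("A", "C", "G", "T"), refBase), 1)
      site <- GRanges("chrM", IRanges(pos, width = 1),
                      ref = refBase, alt = altBase)
      eff <- codingEffects(site, fx$models, fx$genome)
      eff <- eff[eff$gene_id == gid, ]
      o <- oracleCodingEffect("chrM", pos, refBase, altBase, fx$models,
                              fx$genome, gid)
      expect_equal(eff$effect, o,
                   info = sprintf("%s pos %d %s>%s", gid, pos, refBase,
                                  altBase))
    }
  }
})

test_that("summary percentages and the Nonsyn/Syn ratio follow hand
           counts, excluding stop variants from the ratio", {
  ann <- data.frame(
    feature = c(rep("intergenic", 6), rep("promoter", 2), "intron",
                "exon"),
    effect = c(rep("none", 6), rep("none", 2), "none", "synonymous"))
  s <- annotationSummary(ann)
  expect_equal(unname(s$feature_percent["intergenic"]), 60)
  expect_equal(sum(s$feature_percent), 100)
  ann2 <- data.frame(
    feature = rep("exon", 10),
    effect = c(rep("nonsynonymous", 4), rep("synonymous", 4),
               "stop_gain", "stop_loss"))
  expect_equal(annotationSummary(ann2)$nonsyn_syn_ratio, 1)
  ann3 <- data.frame(feature = "exon", effect = "synonymous")
  expect_equal(annotationSummary(ann3)$nonsyn_syn_ratio, 0)
  ann4 <- data.frame(feature = "exon", effect = "nonsynonymous")
  expect_true(is.na(annotationSummary(ann4)$nonsyn_syn_ratio))
})

test_that("count-level summary reproduces share and ratio arithmetic", {
  s <- snpDistributionSummary(
    c(nonsynonymous = 69097, synonymous = 109121, stop_gain = 3843,
      stop_loss = 883))
  expect_equal(round(s$nonsyn_syn_ratio, 2), 0.63)
  s2 <- snpDistributionSummary(c(chr4 = 112536, chr3 = 45581),
                               total = 1085144)
  expect_equal(round(unname(s2$percent["chr4"]), 2), 10.37)
  expect_equal(round(unname(s2$percent["chr3"]), 2), 4.20)
})

test_that("feature percentages from an annotated random fixture sum to
           100 and effects appear only in CDS exons", {
  fx <- toyModelFixture()
  set.seed(19)
  pos <- sort(sample.int(fx$chromLen, 300))
  refs <- vapply(pos, function(p)
    as.character(subseq(fx$genome[["chrM"]], p, p)), "")
  alts <- vapply(refs, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1), "")
  sites <- GRanges("chrM", IRanges(pos, width = 1), ref = refs, alt = alts)
  ann <- annotateSnps(sites, fx$models, fx$genome)
  s <- annotationSummary(ann)
  expect_equal(sum(s$feature_percent), 100, tolerance = 1e-9)
  expect_true(all(ann$feature[ann$effect != "none"] == "exon"))
})
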