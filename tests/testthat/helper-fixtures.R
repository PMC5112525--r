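# Fixtures built in code and independent brute-force oracles.
# The oracles deliberately use naive per-site / per-offset loops so they
# share no code path with the package implementations they check.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(Biostrings)
})

# Random genotype matrix over a small genome.
randomGenotypeMatrix <- function(nSamples = 6, nSites = 100, seed = 1,
                                 missingRate = 0.05, hetRate = 0.2,
                                 nChrom = 2, chromLen = 1e5) {
  set.seed(seed)
  chroms <- paste0("chr", seq_len(nChrom))
  perChrom <- sort(rep(chroms, length.out = nSites))
  pos <- unlist(lapply(split(seq_len(nSites), perChrom), function(i)
    sort(sample.int(chromLen, length(i)))))
  sites <- GRanges(factor(perChrom, levels = chroms),
                   IRanges(unname(pos), width = 1),
                   ref = "A", alt = "T")
  seqlengths(sites) <- setNames(rep(chromLen, nChrom), chroms)
  calls <- matrix(sample(c(0L, 1L, 2L), nSamples * nSites, replace = TRUE,
                         prob = c((1 - hetRate) / 2, hetRate,
                                  (1 - hetRate) / 2)),
                  nrow = nSamples,
                  dimnames = list(paste0("s", seq_len(nSamples)), NULL))
  calls[sample(length(calls), round(missingRate * length(calls)))] <- NA
  GenotypeMatrix(calls, sites)
}

# Brute-force pairwise similarity: per-site loop.
oracleSimilarity <- function(calls, i, j, policy = "exclude") {
  ndiff <- 0; nvalid <- 0
  for (k in seq_len(ncol(calls))) {
    a <- calls[i, k]; b <- calls[j, k]
    if (is.na(a) || is.na(b)) next
    if (policy == "exclude") {
      if (a == 1 || b == 1) next
      nvalid <- nvalid + 1
      if (a != b) ndiff <- ndiff + 1
    } else {
      nvalid <- nvalid + 1
      ndiff <- ndiff + abs(a - b) / 2
    }
  }
  list(pi = if (nvalid > 0) unname(ndiff / nvalid) else NA_real_,
       n = nvalid)
}

# Brute-force per-window diversity for one pair.
oracleWindowDiversity <- function(gm, windows, s1, s2, policy = "exclude") {
  calls <- genotypeCalls(gm)
  sites <- variantSites(gm)
  sapply(seq_along(windows), function(w) {
    inWin <- as.character(seqnames(sites)) ==
      as.character(seqnames(windows))[w] &
      start(sites) >= start(windows)[w] & start(sites) <= end(windows)[w]
    idx <- which(inWin)
    if (!length(idx)) return(c(d = NA, n = 0))
    sub <- calls[, idx, drop = FALSE]
    o <- oracleSimilarity(sub, match(s1, rownames(sub)),
                          match(s2, rownames(sub)), policy)
    c(d = o$pi, n = o$n)
  })
}

# A deterministic two-gene fixture (one per strand) with a hand-written
# genome, used for gene-model, annotation and promoter tests.
#
# chrM layout (length 6000):
#   genePlus  (+): span 3001..3800
#     exon1 3001..3300, exon2 3501..3800
#     CDS   3101..3300 + 3501..3700  (400 bp, %3 != 0 would be bad -> 399?)
# We pick CDS widths summing to a multiple of 3 below.
toyModelFixture <- function(seed = 42) {
  set.seed(seed)
  chromLen <- 6000
  genome <- DNAStringSet(c(
    chrM = paste(sample(c("A", "C", "G", "T"), chromLen, replace = TRUE),
                 collapse = "")))
  genes <- data.frame(
    gene_id = c("gPlus", "gMinus"),
    chrom = "chrM",
    strand = c("+", "-"),
    start = c(3001L, 4501L),
    end = c(3800L, 5300L), stringsAsFactors = FALSE)
  exons <- list(
    gPlus = IRanges(c(3001, 3501), c(3300, 3800)),
    gMinus = IRanges(c(4501, 5001), c(4800, 5300)))
  cds <- list(
    gPlus = IRanges(c(3101, 3501), c(3300, 3700)),   # 200 + 200 = 400
    gMinus = IRanges(c(4601, 5001), c(4800, 5200)))  # 200 + 200 = 400
  # make CDS lengths multiples of 3: trim 1 bp from the 3' end
  cds$gPlus <- IRanges(c(3101, 3501), c(3300, 3699))    # 200+199 = 399
  cds$gMinus <- IRanges(c(4602, 5001), c(4800, 5200))   # 199+200 = 399
  models <- makeGeneModels(genes, exons, cds)
  list(models = models, genome = genome, chromLen = chromLen)
}

# Brute-force feature classification of a single position.
oracleClassify <- function(pos, models, promoterBp = 2000, spliceBp = 2) {
  g <- models@genes
  best <- list(priority = 99, feature = "intergenic", gene = NA_character_)
  inAnyBody <- FALSE
  for (i in seq_along(g)) {
    gid <- mcols(g)$gene_id[i]
    if (pos >= start(g)[i] && pos <= end(g)[i]) inAnyBody <- TRUE
    hit <- function(gr) length(gr) > 0 &&
      any(pos >= start(gr) & pos <= end(gr))
    introns <- models@introns[[gid]]
    splice <- FALSE
    if (length(introns)) for (k in seq_along(introns)) {
      s <- start(introns)[k]; e <- end(introns)[k]
      if ((pos >= s && pos <= min(s + spliceBp - 1, e)) ||
          (pos <= e && pos >= max(e - spliceBp + 1, s))) splice <- TRUE
    }
    cand <- if (splice) c(1, "splice_site")
      else if (hit(models@utr5[[gid]])) c(2, "utr5")
      else if (hit(models@utr3[[gid]])) c(3, "utr3")
      else if (hit(models@exons[[gid]])) c(4, "exon")
      else if (hit(introns)) c(5, "intron")
      else NULL
    if (!is.null(cand) && as.numeric(cand[1]) < best$priority)
      best <- list(priority = as.numeric(cand[1]), feature = cand[2],
                   gene = gid)
  }
  if (best$feature != "intergenic") return(best[c("feature", "gene")])
  if (!inAnyBody) for (i in seq_along(g)) {
    st <- as.character(strand(g))[i]
    tss <- if (st == "-") end(g)[i] else start(g)[i]
    inProm <- if (st == "-") pos > tss && pos <= tss + promoterBp
      else pos < tss && pos >= tss - promoterBp
    if (inProm)
      return(list(feature = "promoter", gene = mcols(g)$gene_id[i]))
  }
  list(feature = "intergenic", gene = NA_character_)
}

# Whole-protein translation oracle for coding effects: build the full ref
# and alt CDS sequences, translate both, and diff.
oracleCodingEffect <- function(chrom, pos, ref, alt, models, genome, gid) {
  g <- models@genes
  i <- match(gid, mcols(g)$gene_id)
  st <- as.character(strand(g))[i]
  cd <- sort(models@cds[[gid]])
  refSeq <- paste(vapply(seq_along(cd), function(k)
    as.character(subseq(genome[[chrom]], start(cd)[k], end(cd)[k])), ""),
    collapse = "")
  offsetInCds <- 0L
  found <- FALSE
  for (k in seq_along(cd)) {
    if (pos >= start(cd)[k] && pos <= end(cd)[k]) {
      offsetInCds <- offsetInCds + (pos - start(cd)[k] + 1L)
      found <- TRUE
      break
    }
    offsetInCds <- offsetInCds + width(cd)[k]
  }
  if (!found) return("none")
  altSeq <- refSeq
  substr(altSeq, offsetInCds, offsetInCds) <- alt
  toProt <- function(s) {
    d <- DNAString(s)
    if (st == "-") d <- reverseComplement(d)
    as.character(translate(d, if.fuzzy.codon = "X"))
  }
  pr <- toProt(refSeq); pa <- toProt(altSeq)
  dif <- which(strsplit(pr, "")[[1]] != strsplit(pa, "")[[1]])
  if (!length(dif)) return("synonymous")
  aaR <- substr(pr, dif[1], dif[1]); aaA <- substr(pa, dif[1], dif[1])
  if (aaR == "*" && aaA != "*") "stop_loss"
  else if (aaR != "*" && aaA == "*") "stop_gain"
  else "nonsynonymous"
}

# Exhaustive PWM scan oracle: score every offset on both strands from the
# raw counts, naively.
oracleScan <- function(seq, counts, thresholdFraction = 0.8,
                       pseudocount = 0.8, background = rep(0.25, 4)) {
  p <- sweep(counts + pseudocount / 4, 2, colSums(counts) + pseudocount, "/")
  lo <- log2(p / background)
  bases <- c("A", "C", "G", "T")
  maxScore <- sum(apply(lo, 2, max))
  thr <- thresholdFraction * maxScore
  s <- toupper(as.character(seq))
  n <- nchar(s); L <- ncol(counts)
  hits <- NULL
  if (n >= L) for (off in 1:(n - L + 1)) {
    win <- substr(s, off, off + L - 1)
    chars <- strsplit(win, "")[[1]]
    for (strand in c("+", "-")) {
      use <- if (strand == "+") chars
        else rev(c(A = "T", C = "G", G = "C", T = "A", N = "N")[chars])
      if (any(!use %in% bases)) next
      sc <- sum(vapply(seq_len(L), function(j)
        lo[match(use[j], bases), j], 1))
      if (sc >= thr)
        hits <- rbind(hits, data.frame(offset = off, strand = strand,
                                       score = sc))
    }
  }
  if (is.null(hits))
    return(data.frame(offset = integer(), strand = character(),
                      score = numeric()))
  hits[order(hits$offset, hits$strand), ]
}

# Small pedigree spec for fast tests.
tinySpec <- function(seed = 1, chromLengthBp = 5e5, ...)
  defaultPedigreeSpec(seed = seed, chromLengthBp = chromLengthBp, ...)
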