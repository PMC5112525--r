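#' GenotypeMatrix: multi-sample biallelic SNP genotypes
#'
#' Samples-by-sites genotype calls over biallelic SNPs. Calls are coded as
#' integers: 0 = homozygous reference, 1 = heterozygous, 2 = homozygous
#' alternate, `NA` = missing. Sites are a [GenomicRanges::GRanges] of width-1
#' positions (1-based, as in VCF), sorted by (chrom, pos), with metadata
#' columns `ref` and `alt` (single bases).
#'
#' @slot calls integer matrix, samples x sites; rownames are sample ids.
#' @slot sites `GRanges` of SNP positions with `ref`/`alt` metadata columns.
#' @export
setClass("GenotypeMatrix", slots = c(calls = "matrix", sites = "GRanges"))

setValidity("GenotypeMatrix", function(object) {
  msg <- character()
  if (!is.integer(object@calls) && !all(is.na(object@calls)))
    msg <- c(msg, "calls must be an integer matrix")
  if (ncol(object@calls) != length(object@sites))
    msg <- c(msg, "ncol(calls) must equal length(sites)")
  if (is.null(rownames(object@calls)) && nrow(object@calls) > 0)
    msg <- c(msg, "calls must have sample ids as rownames")
  bad <- object@calls[!is.na(object@calls)]
  if (length(bad) && !all(bad %in% 0:2))
    msg <- c(msg, "calls must be in {0, 1, 2, NA}")
  if (length(object@sites)) {
    if (!all(width(object@sites) == 1L))
      msg <- c(msg, "sites must be width-1 positions")
    if (!all(c("ref", "alt") %in% names(mcols(object@sites))))
      msg <- c(msg, "sites need 'ref' and 'alt' metadata columns")
    key <- paste(as.character(seqnames(object@sites)), start(object@sites))
    if (anyDuplicated(key))
      msg <- c(msg, "duplicate (chrom, pos) sites")
    o <- order(as.character(seqnames(object@sites)), start(object@sites))
    if (!identical(o, seq_along(object@sites)))
      msg <- c(msg, "sites must be sorted by (chrom, pos)")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeMatrix
#'
#' @param calls integer matrix (samples x sites, rownames = sample ids) with
#'   values 0/1/2/NA.
#' @param sites `GRanges` of width-1 SNP positions with `ref` and `alt`
#'   metadata columns, sorted by (chrom, pos).
#' @return A [GenotypeMatrix-class] object.
#' @examples
#' sites <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(100, 200), width = 1),
#'                                 ref = "A", alt = "T")
#' calls <- matrix(c(0L, 2L, 2L, 0L), nrow = 2,
#'                 dimnames = list(c("s1", "s2"), NULL))
#' gm <- GenotypeMatrix(calls, sites)
#' @export
GenotypeMatrix <- function(calls, sites) {
  storage.mode(calls) <- "integer"
  new("GenotypeMatrix", calls = calls, sites = sites)
}

#' @describeIn GenotypeMatrix-class sample identifiers
#' @param x a `GenotypeMatrix`
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @export
setMethod("sampleIds", "GenotypeMatrix", function(x) rownames(x@calls))

#' @describeIn GenotypeMatrix-class SNP positions as a `GRanges`
#' @export
setGeneric("variantSites", function(x) standardGeneric("variantSites"))
#' @export
setMethod("variantSites", "GenotypeMatrix", function(x) x@sites)

#' @describeIn GenotypeMatrix-class the integer call matrix
#' @export
setGeneric("genotypeCalls", function(x) standardGeneric("genotypeCalls"))
#' @export
setMethod("genotypeCalls", "GenotypeMatrix", function(x) x@calls)

setMethod("show", "GenotypeMatrix", function(object) {
  cat("GenotypeMatrix:", nrow(object@calls), "samples x",
      length(object@sites), "sites on",
      length(unique(as.character(seqnames(object@sites)))), "chromosome(s)\n")
  if (nrow(object@calls))
    cat("  samples:", paste(head(rownames(object@calls), 6), collapse = ", "),
        if (nrow(object@calls) > 6) "...", "\n")
})

#' Subset a GenotypeMatrix by sample
#'
#' @param x a `GenotypeMatrix`
#' @param samples character vector of sample ids to keep (order preserved).
#' @return A `GenotypeMatrix` restricted to `samples`.
#' @export
subsetSamples <- function(x, samples) {
  missing <- setdiff(samples, sampleIds(x))
  if (length(missing))
    stop("unknown sample(s): ", paste(missing, collapse = ", "))
  GenotypeMatrix(x@calls[samples, , drop = FALSE], x@sites)
}

#' PedigreeSpec: configuration of a simulated breeding program
#'
#' Describes founders, crosses (with selfing generations), the genome
#' (physical and genetic lengths), SNP density, inter-founder polymorphism
#' rate, optional missing-call rate, and the global seed. Crosses are applied
#' in order; each row's `child` is produced from `mother` x `father` followed
#' by `selfing` generations of self-pollination.
#'
#' @slot founders character vector of founder line ids.
#' @slot crosses data.frame with columns `mother`, `father`, `child`,
#'   `selfing` (non-negative integer).
#' @slot genome data.frame with columns `chrom`, `length_bp`, `length_morgans`.
#' @slot snpDensity expected SNP sites per bp (e.g. 1e-3 = 1 per kb).
#' @slot polymorphismRate probability that two founders differ at a site
#'   (in \[0, 0.5\]).
#' @slot missingRate per-call missing-data probability.
#' @slot seed integer global seed; all per-meiosis substreams derive from it.
#' @export
setClass("PedigreeSpec", slots = c(
  founders = "character", crosses = "data.frame", genome = "data.frame",
  snpDensity = "numeric", polymorphismRate = "numeric",
  missingRate = "numeric", seed = "integer"))

setValidity("PedigreeSpec", function(object) {
  msg <- character()
  g <- object@genome
  if (!all(c("chrom", "length_bp", "length_morgans") %in% names(g)))
    msg <- c(msg, "genome needs chrom, length_bp, length_morgans")
  else {
    if (nrow(g) < 1) msg <- c(msg, "at least one chromosome required")
    if (any(g$length_bp <= 0)) msg <- c(msg, "length_bp must be positive")
    if (any(g$length_morgans < 0)) msg <- c(msg, "length_morgans must be >= 0")
  }
  if (length(object@snpDensity) != 1 || object@snpDensity <= 0)
    msg <- c(msg, "snpDensity must be a single positive number")
  if (object@polymorphismRate < 0 || object@polymorphismRate > 0.5)
    msg <- c(msg, "polymorphismRate must be in [0, 0.5]")
  if (object@missingRate < 0 || object@missingRate >= 1)
    msg <- c(msg, "missingRate must be in [0, 1)")
  cr <- object@crosses
  if (nrow(cr)) {
    if (!all(c("mother", "father", "child", "selfing") %in% names(cr)))
      msg <- c(msg, "crosses needs mother, father, child, selfing")
    else {
      known <- object@founders
      for (i in seq_len(nrow(cr))) {
        if (!all(c(cr$mother[i], cr$father[i]) %in% known))
          msg <- c(msg, sprintf(
            "cross %d: parent(s) of '%s' not defined before use", i, cr$child[i]))
        if (cr$child[i] %in% known)
          msg <- c(msg, sprintf("line '%s' defined twice", cr$child[i]))
        known <- c(known, cr$child[i])
      }
      if (any(cr$selfing < 0)) msg <- c(msg, "selfing must be >= 0")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a PedigreeSpec
#'
#' @param founders character vector of founder ids.
#' @param crosses data.frame (`mother`, `father`, `child`, `selfing`);
#'   rows are applied in order, so parents must be founders or earlier
#'   children.
#' @param genome data.frame (`chrom`, `length_bp`, `length_morgans`).
#' @param snpDensity expected SNP sites per bp.
#' @param polymorphismRate per-site probability that two founders carry
#'   different alleles (default 0.5, the maximum under a symmetric
#'   biallelic model).
#' @param missingRate probability a genotype call is emitted as missing.
#' @param seed integer seed.
#' @return A [PedigreeSpec-class].
#' @export
PedigreeSpec <- function(founders, crosses, genome, snpDensity = 1e-3,
                         polymorphismRate = 0.5, missingRate = 0,
                         seed = 1L) {
  crosses$selfing <- as.integer(crosses$selfing)
  new("PedigreeSpec", founders = founders, crosses = crosses,
      genome = genome, snpDensity = snpDensity,
      polymorphismRate = polymorphismRate, missingRate = missingRate,
      seed = as.integer(seed))
}

setMethod("show", "PedigreeSpec", function(object) {
  cat("PedigreeSpec:", length(object@founders), "founders,",
      nrow(object@crosses), "crosses,", nrow(object@genome),
      "chromosome(s),", format(sum(object@genome$length_bp), big.mark = ","),
      "bp\n")
})

#' FounderSet: homozygous founder haplotypes over shared SNP positions
#'
#' Founders are fully homozygous (inbred lines), so one haplotype per founder
#' suffices. All founders share the same site positions.
#'
#' @slot sites `GRanges` of SNP positions (width 1) with `ref`/`alt`.
#' @slot alleles integer matrix founders x sites with values 0 (ref) / 1 (alt).
#' @export
setClass("FounderSet", slots = c(sites = "GRanges", alleles = "matrix"))

setValidity("FounderSet", function(object) {
  msg <- character()
  if (ncol(object@alleles) != length(object@sites))
    msg <- c(msg, "ncol(alleles) must equal length(sites)")
  a <- object@alleles
  if (length(a) && !all(a %in% 0:1)) msg <- c(msg, "alleles must be 0/1")
  if (length(msg)) msg else TRUE
})

setMethod("show", "FounderSet", function(object) {
  cat("FounderSet:", nrow(object@alleles), "founders x",
      length(object@sites), "sites\n")
})

#' TruthMosaic: true ancestor-of-origin segments of a simulated line
#'
#' One `GRanges` per homologous chromosome copy, each with an `origin`
#' metadata column naming the founder the segment descends from. Segments
#' tile every chromosome exactly.
#'
#' @slot lineId the line the mosaic describes.
#' @slot haplotypes `GRangesList` of length 2 (one per homolog).
#' @export
setClass("TruthMosaic",
         slots = c(lineId = "character", haplotypes = "GRangesList"))

setValidity("TruthMosaic", function(object) {
  if (length(object@haplotypes) != 2)
    return("haplotypes must have length 2")
  for (h in seq_len(2)) {
    gr <- object@haplotypes[[h]]
    if (!"origin" %in% names(mcols(gr)))
      return("each haplotype needs an 'origin' column")
    sl <- seqlengths(gr)
    for (ch in seqlevels(gr)) {
      seg <- gr[as.character(seqnames(gr)) == ch]
      seg <- seg[order(start(seg))]
      if (!length(seg)) return(sprintf("chromosome %s has no segments", ch))
      if (start(seg)[1] != 1) return("segments must start at 1")
      if (!is.na(sl[ch]) && end(seg)[length(seg)] != sl[ch])
        return("segments must end at the chromosome length")
      if (length(seg) > 1 &&
          any(start(seg)[-1] != end(seg)[-length(seg)] + 1L))
        return("segments must tile without gaps or overlaps")
    }
  }
  TRUE
})

setMethod("show", "TruthMosaic", function(object) {
  segs <- sum(vapply(object@haplotypes, length, 1L))
  cat("TruthMosaic for", object@lineId, ":", segs,
      "segments over 2 haplotypes\n")
})

#' PedigreeSim: simulated pedigree genotypes plus block truth
#'
#' @slot spec the [PedigreeSpec-class] used.
#' @slot genotypes a [GenotypeMatrix-class] over all lines.
#' @slot mosaics named list of [TruthMosaic-class], one per line.
#' @export
setClass("PedigreeSim", slots = c(
  spec = "PedigreeSpec", genotypes = "GenotypeMatrix", mosaics = "list"))

setMethod("show", "PedigreeSim", function(object) {
  cat("PedigreeSim:", nrow(object@genotypes@calls), "lines,",
      length(object@genotypes@sites), "SNP sites\n")
})

#' SimilarityMatrix: pairwise genetic similarity (1 - pi)
#'
#' @slot values symmetric matrix of similarity indexes in \[0, 1\]
#'   (`NA` where fewer than `minSites` sites were comparable).
#' @slot nCompared per-pair count of sites entering the comparison.
#' @slot hetPolicy how heterozygous calls were handled.
#' @export
setClass("SimilarityMatrix", slots = c(
  values = "matrix", nCompared = "matrix", hetPolicy = "character"))

setValidity("SimilarityMatrix", function(object) {
  v <- object@values
  msg <- character()
  if (nrow(v) != ncol(v) || !identical(rownames(v), colnames(v)))
    msg <- c(msg, "values must be square with matching dimnames")
  if (any(!is.na(v) & (v < 0 | v > 1)))
    msg <- c(msg, "similarities must lie in [0, 1]")
  if (any(!is.na(diag(v)) & diag(v) != 1))
    msg <- c(msg, "diagonal must be 1")
  if (any(abs(v - t(v)) > 1e-12, na.rm = TRUE))
    msg <- c(msg, "values must be symmetric")
  if (length(msg)) msg else TRUE
})

#' @describeIn SimilarityMatrix-class similarity values
#' @param x a `SimilarityMatrix`
#' @export
setGeneric("similarityValues", function(x) standardGeneric("similarityValues"))
#' @export
setMethod("similarityValues", "SimilarityMatrix", function(x) x@values)

#' @describeIn SimilarityMatrix-class per-pair compared-site counts
#' @export
setGeneric("sitesCompared", function(x) standardGeneric("sitesCompared"))
#' @export
setMethod("sitesCompared", "SimilarityMatrix", function(x) x@nCompared)

setMethod("show", "SimilarityMatrix", function(object) {
  cat("SimilarityMatrix (1 - pi),", nrow(object@values), "samples,",
      "het policy:", object@hetPolicy, "\n")
  print(round(object@values, 3))
})

#' DiversityProfile: per-window Dpair/Darv and diversity-decreased level
#'
#' For a descendant and a set of candidate ancestors, holds per window the
#' pairwise diversity Dpair between descendant and each ancestor, the
#' all-sample average diversity Darv, and the diversity-decreased level
#' (Darv - Dpair) / Darv, which approaches 1 inside blocks inherited from
#' that ancestor.
#'
#' @slot windows `GRanges` of the sliding windows.
#' @slot descendant the focal line.
#' @slot ancestors candidate ancestor ids (columns of the matrices).
#' @slot dPair windows x ancestors matrix of pairwise diversities.
#' @slot dArv per-window average diversity over all unordered sample pairs.
#' @slot decrease windows x ancestors matrix of diversity-decreased levels
#'   (`NA` where uninformative).
#' @slot nSnps windows x ancestors matrix of informative site counts.
#' @slot minSnps minimum informative sites for a window to count.
#' @export
setClass("DiversityProfile", slots = c(
  windows = "GRanges", descendant = "character", ancestors = "character",
  dPair = "matrix", dArv = "numeric", decrease = "matrix",
  nSnps = "matrix", minSnps = "integer"))

setValidity("DiversityProfile", function(object) {
  nw <- length(object@windows); na <- length(object@ancestors)
  msg <- character()
  if (!all(dim(object@dPair) == c(nw, na))) msg <- c(msg, "dPair dims")
  if (!all(dim(object@decrease) == c(nw, na))) msg <- c(msg, "decrease dims")
  if (length(object@dArv) != nw) msg <- c(msg, "dArv length")
  if (any(!is.na(object@dPair) & (object@dPair < 0 | object@dPair > 1)))
    msg <- c(msg, "dPair must lie in [0, 1]")
  if (any(!is.na(object@decrease) & object@decrease > 1 + 1e-12))
    msg <- c(msg, "decrease cannot exceed 1")
  if (length(msg)) msg else TRUE
})

setMethod("show", "DiversityProfile", function(object) {
  cat("DiversityProfile:", length(object@windows), "windows,",
      "descendant", object@descendant, "vs",
      paste(object@ancestors, collapse = ", "), "\n")
  inf <- colSums(!is.na(object@decrease))
  cat("  informative windows per ancestor:",
      paste(sprintf("%s=%d", object@ancestors, inf), collapse = ", "), "\n")
})

#' GeneModelSet: indexed gene models from a GFF3 annotation
#'
#' One representative transcript per gene (the longest total CDS). The TSS is
#' the strand-aware 5' end of the gene span. `codingOk` is FALSE for genes
#' whose CDS length is not divisible by 3; such genes are never assigned a
#' coding effect.
#'
#' @slot genes `GRanges` of gene spans with `gene_id`, `tss`, `codingOk`.
#' @slot exons,cds,utr5,utr3,introns `GRangesList` keyed by gene id.
#' @export
setClass("GeneModelSet", slots = c(
  genes = "GRanges", exons = "GRangesList", cds = "GRangesList",
  utr5 = "GRangesList", utr3 = "GRangesList", introns = "GRangesList"))

setMethod("show", "GeneModelSet", function(object) {
  cat("GeneModelSet:", length(object@genes), "genes on",
      length(unique(as.character(seqnames(object@genes)))),
      "chromosome(s);", sum(!mcols(object@genes)$codingOk),
      "flagged non-annotatable for coding effect\n")
})

#' @describeIn GeneModelSet-class gene spans as a `GRanges`
#' @param x a `GeneModelSet`
#' @export
setGeneric("geneRanges", function(x) standardGeneric("geneRanges"))
#' @export
setMethod("geneRanges", "GeneModelSet", function(x) x@genes)
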