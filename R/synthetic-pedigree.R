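# Backcross pedigree simulator with exact ancestor-of-origin truth.
#
# Meiosis follows the Haldane model: crossover count per chromosome is
# Poisson(genetic length in Morgans), crossover positions are uniform, and
# there is no interference. Founders are fully homozygous inbred lines.

# Deterministic per-event substream: one global seed plus an event counter,
# so adding later lines never reshuffles earlier ones.
.substreamSeed <- function(seed, counter) {
  s <- (as.double(seed) %% 2147483647) * 69621 + as.double(counter) * 7919 + 1
  as.integer(s %% 2147483647)
}

#' Simulate homozygous founder haplotypes
#'
#' SNP site counts per chromosome are Poisson with mean
#' `length_bp * snpDensity`; positions are uniform without replacement and
#' shared across founders. Each founder's allele at a site is an independent
#' Bernoulli(q) draw with q chosen so that any two founders differ with
#' probability `polymorphismRate` (q solves 2q(1-q) = rate).
#'
#' @param spec a [PedigreeSpec-class].
#' @param genome optional `DNAStringSet` of reference chromosome sequences
#'   (names matching `spec@genome$chrom`); if supplied, the reference allele
#'   at each site is the genome base and the alternate is a random other
#'   base. Otherwise ref/alt are synthesized as A/T.
#' @return A [FounderSet-class].
#' @examples
#' spec <- defaultPedigreeSpec(seed = 7, chromLengthBp = 1e5)
#' fs <- simulateFounders(spec)
#' @export
simulateFounders <- function(spec, genome = NULL) {
  validObject(spec)
  set.seed(.substreamSeed(spec@seed, 0L))
  p <- spec@polymorphismRate
  q <- (1 - sqrt(1 - 2 * p)) / 2
  chroms <- spec@genome$chrom
  posList <- lapply(seq_along(chroms), function(i) {
    L <- spec@genome$length_bp[i]
    n <- min(rpois(1, L * spec@snpDensity), L)
    sort(sample.int(L, n))
  })
  sites <- GRanges(
    factor(rep(chroms, lengths(posList)), levels = chroms),
    IRanges(unlist(posList), width = 1))
  seqlengths(sites) <- setNames(spec@genome$length_bp, chroms)
  n <- length(sites)
  if (is.null(genome)) {
    ref <- rep("A", n); alt <- rep("T", n)
  } else {
    ref <- character(n)
    for (ch in chroms) {
      idx <- which(as.character(seqnames(sites)) == ch)
      if (length(idx))
        ref[idx] <- strsplit(as.character(subseq(
          genome[[ch]], 1, spec@genome$length_bp[match(ch, chroms)])),
          "")[[1]][start(sites)[idx]]
    }
    bases <- c("A", "C", "G", "T")
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), "")
  }
  mcols(sites)$ref <- unname(ref)
  mcols(sites)$alt <- unname(alt)
  alleles <- matrix(rbinom(length(spec@founders) * n, 1L, q),
                    nrow = length(spec@founders),
                    dimnames = list(spec@founders, NULL))
  storage.mode(alleles) <- "integer"
  new("FounderSet", sites = sites, alleles = alleles)
}

# Site bookkeeping shared by all individuals of one simulation.
.siteContext <- function(founders, spec) {
  sites <- founders@sites
  ch <- as.character(seqnames(sites))
  list(
    chroms = spec@genome$chrom,
    lengths = setNames(spec@genome$length_bp, spec@genome$chrom),
    morgans = setNames(spec@genome$length_morgans, spec@genome$chrom),
    idx = split(seq_along(sites), factor(ch, levels = spec@genome$chrom)),
    pos = split(start(sites), factor(ch, levels = spec@genome$chrom)))
}

#' Build an individual from a homozygous founder
#'
#' @param founders a [FounderSet-class].
#' @param spec the [PedigreeSpec-class] the founders were simulated under.
#' @param founderId which founder.
#' @return An individual: a list with `id` and two haplotypes, each holding a
#'   genome-wide allele vector and per-chromosome origin segments.
#' @export
founderIndividual <- function(founders, spec, founderId) {
  if (!founderId %in% rownames(founders@alleles))
    stop("unknown founder: ", founderId)
  ctx <- .siteContext(founders, spec)
  segs <- lapply(ctx$chroms, function(ch)
    data.frame(start = 1, end = unname(ctx$lengths[ch]), origin = founderId,
               stringsAsFactors = FALSE))
  names(segs) <- ctx$chroms
  hap <- list(alleles = founders@alleles[founderId, ], segs = segs)
  structure(list(id = founderId, haps = list(hap, hap), ctx = ctx),
            class = "pedtraceIndividual")
}

# Clip origin segments to [s, e] (1-based inclusive).
.clipSegs <- function(segs, s, e) {
  keep <- segs$end >= s & segs$start <= e
  out <- segs[keep, , drop = FALSE]
  out$start <- pmax(out$start, s)
  out$end <- pmin(out$end, e)
  out
}

.mergeSegs <- function(segs) {
  if (nrow(segs) <= 1) return(segs)
  keep <- c(TRUE, segs$origin[-1] != segs$origin[-nrow(segs)])
  grp <- cumsum(keep)
  data.frame(start = tapply(segs$start, grp, min),
             end = tapply(segs$end, grp, max),
             origin = segs$origin[keep], stringsAsFactors = FALSE,
             row.names = NULL)
}

# One chromosome's meiosis: Haldane crossovers, alternating mosaic.
.meioseChrom <- function(h1, h2, idx, pos, Lbp, morgans) {
  if (morgans < 0) stop("genetic length must be non-negative")
  nxo <- rpois(1, morgans)
  xo <- sort(runif(nxo, 0, Lbp))
  startHap <- sample.int(2L, 1L)
  a1 <- h1$alleles[idx]; a2 <- h2$alleles[idx]
  k <- findInterval(pos, xo)
  phase <- ((startHap - 1L + k) %% 2L) + 1L
  alleles <- ifelse(phase == 1L, a1, a2)
  cuts <- unique(floor(xo))
  cuts <- cuts[cuts >= 1 & cuts < Lbp]
  starts <- c(1, cuts + 1)
  ends <- c(cuts, Lbp)
  pieceHap <- ((startHap - 1L + findInterval(starts, xo)) %% 2L) + 1L
  pieces <- lapply(seq_along(starts), function(j)
    .clipSegs(if (pieceHap[j] == 1L) h1$segs0 else h2$segs0,
              starts[j], ends[j]))
  segs <- .mergeSegs(do.call(rbind, pieces))
  list(alleles = alleles, segs = segs, crossovers = xo)
}

#' Simulate one meiosis of an individual
#'
#' Crossover counts per chromosome are Poisson in the chromosome's genetic
#' length (Morgans), positions uniform, no interference (Haldane). The gamete
#' is the alternating mosaic of the two parental haplotypes, starting from a
#' haplotype chosen with probability 1/2.
#'
#' @param individual an individual from [founderIndividual()] or
#'   [crossIndividuals()].
#' @param seed integer seed for this meiosis.
#' @return A gamete: list with `alleles` (genome-wide vector), `segs`
#'   (per-chromosome origin segments) and `crossovers` (per-chromosome
#'   crossover positions in bp).
#' @export
simulateMeiosis <- function(individual, seed) {
  ctx <- individual$ctx
  set.seed(seed)
  out <- list(alleles = integer(length(individual$haps[[1]]$alleles)),
              segs = list(), crossovers = list())
  h1 <- individual$haps[[1]]; h2 <- individual$haps[[2]]
  for (ch in ctx$chroms) {
    m <- .meioseChrom(
      list(alleles = h1$alleles, segs0 = h1$segs[[ch]]),
      list(alleles = h2$alleles, segs0 = h2$segs[[ch]]),
      ctx$idx[[ch]], ctx$pos[[ch]], unname(ctx$lengths[ch]),
      unname(ctx$morgans[ch]))
    out$alleles[ctx$idx[[ch]]] <- m$alleles
    out$segs[[ch]] <- m$segs
    out$crossovers[[ch]] <- m$crossovers
  }
  out
}

.gameteToHap <- function(g) list(alleles = g$alleles, segs = g$segs)

#' Cross two individuals
#'
#' Performs two independent meioses (one per parent) and combines the
#' gametes into an offspring individual.
#'
#' @param mother,father individuals.
#' @param seedMother,seedFather seeds for the two meioses.
#' @param id offspring id.
#' @return The offspring individual.
#' @export
crossIndividuals <- function(mother, father, seedMother, seedFather,
                             id = "offspring") {
  gm <- simulateMeiosis(mother, seedMother)
  gf <- simulateMeiosis(father, seedFather)
  structure(list(id = id, haps = list(.gameteToHap(gm), .gameteToHap(gf)),
                 ctx = mother$ctx),
            class = "pedtraceIndividual")
}

.individualCalls <- function(ind)
  ind$haps[[1]]$alleles + ind$haps[[2]]$alleles

.individualMosaic <- function(ind, lengths) {
  chroms <- names(ind$haps[[1]]$segs)
  haps <- lapply(ind$haps, function(h) {
    nseg <- vapply(h$segs, nrow, 1L)
    gr <- GRanges(
      factor(rep(chroms, nseg), levels = chroms),
      IRanges(unlist(lapply(h$segs, `[[`, "start")),
              unlist(lapply(h$segs, `[[`, "end"))),
      origin = unlist(lapply(h$segs, `[[`, "origin")))
    seqlengths(gr) <- lengths[chroms]
    gr
  })
  new("TruthMosaic", lineId = ind$id,
      haplotypes = GRangesList(haps[[1]], haps[[2]]))
}

#' Run a full pedigree simulation
#'
#' Simulates founders (unless supplied), applies every cross of the spec in
#' order (two independent meioses per cross, then the stated number of
#' selfing generations), and records the exact ancestor-of-origin mosaic of
#' every line from crossover bookkeeping.
#'
#' @param spec a [PedigreeSpec-class].
#' @param founders optional pre-simulated [FounderSet-class].
#' @param genome optional reference `DNAStringSet` passed to
#'   [simulateFounders()].
#' @return A [PedigreeSim-class] holding the genotype matrix over all lines
#'   and one [TruthMosaic-class] per line.
#' @examples
#' sim <- runPedigree(defaultPedigreeSpec(seed = 3, chromLengthBp = 2e5))
#' sim
#' @export
runPedigree <- function(spec, founders = NULL, genome = NULL) {
  validObject(spec)
  if (is.null(founders)) founders <- simulateFounders(spec, genome)
  ctx <- .siteContext(founders, spec)
  lengths <- ctx$lengths
  inds <- list()
  for (f in spec@founders)
    inds[[f]] <- founderIndividual(founders, spec, f)
  counter <- 0L
  nextSeed <- function() {
    counter <<- counter + 1L
    .substreamSeed(spec@seed, counter)
  }
  cr <- spec@crosses
  for (i in seq_len(nrow(cr))) {
    mo <- inds[[cr$mother[i]]]; fa <- inds[[cr$father[i]]]
    if (is.null(mo) || is.null(fa))
      stop("cross ", i, ": parents of '", cr$child[i],
           "' not available; crosses must be ordered parent-first")
    child <- crossIndividuals(mo, fa, nextSeed(), nextSeed(),
                              id = cr$child[i])
    for (s in seq_len(cr$selfing[i]))
      child <- crossIndividuals(child, child, nextSeed(), nextSeed(),
                                id = cr$child[i])
    inds[[cr$child[i]]] <- child
  }
  lines <- names(inds)
  calls <- t(vapply(inds, .individualCalls,
                    integer(length(founders@sites))))
  rownames(calls) <- lines
  if (spec@missingRate > 0) {
    set.seed(.substreamSeed(spec@seed, 999983L))
    miss <- matrix(runif(length(calls)) < spec@missingRate, nrow = nrow(calls))
    calls[miss] <- NA_integer_
  }
  gm <- GenotypeMatrix(calls, founders@sites)
  mosaics <- lapply(inds, .individualMosaic, lengths = lengths)
  new("PedigreeSim", spec = spec, genotypes = gm, mosaics = mosaics)
}

#' Default simulated breeding program
#'
#' Three founders: two grandparents crossed to an F1 that is selfed three
#' generations into a donor line; the donor is crossed to a recurrent
#' parent, backcrossed once into the recurrent parent (BC1), and selfed two
#' generations into the offspring line. This mirrors a donor-into-elite
#' introgression program: the offspring is expected to carry about 75% of
#' the recurrent-parent genome.
#'
#' @param seed integer seed.
#' @param nChrom number of chromosomes.
#' @param chromLengthBp physical length of each chromosome.
#' @param chromMorgans genetic length of each chromosome (Morgans).
#' @param snpDensity SNP sites per bp.
#' @param polymorphismRate inter-founder polymorphism rate.
#' @param missingRate per-call missing probability.
#' @return A [PedigreeSpec-class].
#' @export
defaultPedigreeSpec <- function(seed = 1L, nChrom = 2, chromLengthBp = 1e7,
                                chromMorgans = 1, snpDensity = 1e-3,
                                polymorphismRate = 0.5, missingRate = 0) {
  if (nChrom < 1) stop("at least one chromosome required")
  genome <- data.frame(
    chrom = paste0("chr", seq_len(nChrom)),
    length_bp = rep(chromLengthBp, nChrom),
    length_morgans = rep(chromMorgans, nChrom))
  crosses <- data.frame(
    mother = c("grandparentA", "donor", "bc1f1"),
    father = c("grandparentB", "recurrent", "recurrent"),
    child = c("donor", "bc1f1", "offspring"),
    selfing = c(3L, 0L, 2L),
    stringsAsFactors = FALSE)
  PedigreeSpec(founders = c("grandparentA", "grandparentB", "recurrent"),
               crosses = crosses, genome = genome, snpDensity = snpDensity,
               polymorphismRate = polymorphismRate,
               missingRate = missingRate, seed = seed)
}

#' Genome contribution fractions from simulation truth
#'
#' @param mosaic a [TruthMosaic-class].
#' @return Named numeric vector: fraction of the diploid genome descending
#'   from each founder (sums to 1).
#' @export
truthContributions <- function(mosaic) {
  segs <- c(mosaic@haplotypes[[1]], mosaic@haplotypes[[2]])
  bp <- tapply(as.numeric(width(segs)), mcols(segs)$origin, sum)
  out <- as.numeric(bp) / sum(as.numeric(bp))
  setNames(out, names(bp))
}

#' Flatten a truth mosaic to intervals with origin sets
#'
#' Disjoins the two haplotype mosaics into non-overlapping intervals, each
#' annotated with the set of origins present on the two homologs (one origin
#' where the line is homozygous by descent, two where heterozygous).
#'
#' @param mosaic a [TruthMosaic-class].
#' @return `GRanges` with an `origins` `CharacterList` column.
#' @export
truthOriginRanges <- function(mosaic) {
  h1 <- mosaic@haplotypes[[1]]; h2 <- mosaic@haplotypes[[2]]
  pieces <- disjoin(c(granges(h1), granges(h2)))
  # disjoint pieces hit exactly one segment per haplotype
  ov1 <- findOverlaps(pieces, h1)
  ov2 <- findOverlaps(pieces, h2)
  org1 <- mcols(h1)$origin[subjectHits(ov1)[match(seq_along(pieces),
                                                 queryHits(ov1))]]
  org2 <- mcols(h2)$origin[subjectHits(ov2)[match(seq_along(pieces),
                                                 queryHits(ov2))]]
  orig <- mapply(function(a, b) unique(c(a, b)), org1, org2,
                 SIMPLIFY = FALSE)
  mcols(pieces)$origins <- CharacterList(orig)
  pieces
}

#' Per-sample heterozygosity rate
#'
#' @param gm a [GenotypeMatrix-class].
#' @return Named numeric: fraction of non-missing calls that are
#'   heterozygous, per sample.
#' @export
hetRate <- function(gm) {
  calls <- genotypeCalls(gm)
  apply(calls, 1, function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) return(NA_real_)
    mean(v == 1L)
  })
}

#' Write a truth mosaic as BED
#'
#' Four columns (chrom, start, end, origin) plus a fifth giving the
#' haplotype index (1 or 2). BED coordinates are 0-based half-open.
#'
#' @param mosaic a [TruthMosaic-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeTruthBed <- function(mosaic, path) {
  rows <- do.call(rbind, lapply(1:2, function(h) {
    gr <- mosaic@haplotypes[[h]]
    data.frame(chrom = as.character(seqnames(gr)), start = start(gr) - 1L,
               end = end(gr), origin = mcols(gr)$origin, hap = h,
               stringsAsFactors = FALSE)
  }))
  rows <- rows[order(rows$chrom, rows$start, rows$hap), ]
  write.table(rows, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
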