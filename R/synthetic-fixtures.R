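# Synthetic reference data: random genomes, gene models and promoters with
# planted motifs, so annotation and motif stages are testable without
# external data.

#' Simulate a random reference genome
#'
#' @param chromLengths named integer vector of chromosome lengths.
#' @param seed integer seed.
#' @param gc GC content (default 0.44, rice-like).
#' @return A `DNAStringSet`.
#' @export
simulateGenome <- function(chromLengths, seed = 1L, gc = 0.44) {
  set.seed(seed)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- vapply(chromLengths, function(L)
    paste(sample(names(p), L, replace = TRUE, prob = p), collapse = ""), "")
  out <- DNAStringSet(seqs)
  names(out) <- names(chromLengths)
  out
}

#' Simulate gene models on a genome
#'
#' Places non-overlapping multi-exon protein-coding genes on both strands.
#' Each gene has 1-3 exons, a CDS whose length is a multiple of 3, and
#' short UTRs at both ends.
#'
#' @param genome `DNAStringSet` (only lengths are used).
#' @param nGenes total genes to place.
#' @param seed integer seed.
#' @param meanExonBp,meanIntronBp rough exon/intron sizes.
#' @return A [GeneModelSet-class].
#' @export
simulateGeneModels <- function(genome, nGenes = 20, seed = 1L,
                               meanExonBp = 300, meanIntronBp = 200) {
  set.seed(seed)
  chroms <- names(genome)
  lens <- vapply(seq_along(genome), function(i) length(genome[[i]]), 1L)
  names(lens) <- chroms
  perChrom <- table(factor(sample(chroms, nGenes, replace = TRUE),
                           levels = chroms))
  genesDf <- NULL; exons <- list(); cds <- list()
  gi <- 0
  for (ch in chroms) {
    n <- perChrom[[ch]]
    if (n == 0) next
    # place genes in evenly spaced slots, leaving room for promoters
    slotW <- floor(lens[ch] / max(n, 1))
    for (k in seq_len(n)) {
      gi <- gi + 1
      gid <- sprintf("GENE%04d", gi)
      nEx <- sample(1:3, 1)
      exW <- pmax(30L, as.integer(round(rnorm(nEx, meanExonBp, 50))))
      inW <- if (nEx > 1)
        pmax(40L, as.integer(round(rnorm(nEx - 1, meanIntronBp, 40))))
      else integer(0)
      span <- sum(exW) + sum(inW)
      slotStart <- (k - 1) * slotW + 1
      margin <- slotW - span - 3600   # room for a 3 kb promoter + slack
      if (margin < 1) { gi <- gi - 1; next }
      gStart <- slotStart + 3500 + sample.int(max(1, margin - 200), 1)
      exStarts <- gStart + cumsum(c(0L, head(exW, -1) + inW))
      exIr <- IRanges(exStarts, width = exW)
      gEnd <- max(end(exIr))
      # CDS: trim UTRs off the ends, keep length a multiple of 3
      utrLeft <- min(30L, exW[1] - 10L)
      utrRight <- min(30L, exW[nEx] - 10L)
      cdsStart <- gStart + utrLeft
      cdsEnd <- gEnd - utrRight
      cdsIr <- IRanges::restrict(exIr, start = cdsStart, end = cdsEnd)
      extra <- sum(width(cdsIr)) %% 3L
      if (extra > 0)  # shave the 3' end to a codon boundary
        cdsIr <- IRanges::restrict(cdsIr, end = max(end(cdsIr)) - extra)
      st <- sample(c("+", "-"), 1)
      genesDf <- rbind(genesDf, data.frame(
        gene_id = gid, chrom = ch, strand = st, start = gStart, end = gEnd,
        stringsAsFactors = FALSE))
      exons[[gid]] <- exIr
      cds[[gid]] <- cdsIr
    }
  }
  if (is.null(genesDf)) stop("genome too small to place any gene")
  makeGeneModels(genesDf, exons, cds)
}

#' Plant a motif consensus into promoter sequences
#'
#' Replaces a stretch of each selected promoter with the consensus of a
#' count matrix, so scans have a known truth.
#'
#' @param promoters `DNAStringSet`.
#' @param pwm motif (list with `counts`).
#' @param genes which promoter names receive the consensus.
#' @param at 1-based offset of the planted consensus (default: centred).
#' @return The modified `DNAStringSet`.
#' @export
plantMotif <- function(promoters, pwm, genes, at = NULL) {
  cons <- paste(rownames(pwm$counts)[apply(pwm$counts, 2, which.max)],
                collapse = "")
  L <- nchar(cons)
  for (g in genes) {
    s <- as.character(promoters[[g]])
    if (nchar(s) < L) next
    pos <- if (is.null(at)) max(1, floor((nchar(s) - L) / 2)) else at
    substr(s, pos, pos + L - 1) <- cons
    promoters[[g]] <- DNAString(s)
  }
  promoters
}

#' Toy JASPAR-format PWM set
#'
#' Three sharply informative toy motifs named after the drought-associated
#' TF families (ERF, WRKY, bHLH). Returns the path to the PFM file shipped
#' with the package.
#'
#' @return File path.
#' @export
toyPwmFile <- function() {
  system.file("extdata", "toy_motifs.pfm", package = "pedtrace",
              mustWork = TRUE)
}
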