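# Ancestor-of-origin reconstruction: per-window Dpair/Darv, the
# diversity-decreased level (Darv - Dpair)/Darv, bimodal thresholding by a
# two-component Gaussian mixture, haplotype-block calling with
# uncertain-region apportionment, and contribution fractions.

#' Sliding-window grid over a genome
#'
#' Windows start every `stepBp` from 0 and span `windowBp` (clipped at the
#' chromosome end), so windows overlap whenever `stepBp < windowBp`.
#'
#' @param genome data.frame with `chrom` and `length_bp` (a
#'   `PedigreeSpec@genome` works), or a named vector of chromosome lengths.
#' @param windowBp window span (default 100 kb).
#' @param stepBp step between window starts (default 10 kb).
#' @return `GRanges` of windows (1-based inclusive coordinates).
#' @export
makeWindows <- function(genome, windowBp = 1e5, stepBp = 1e4) {
  if (is.data.frame(genome))
    genome <- setNames(genome$length_bp, genome$chrom)
  if (windowBp < stepBp) stop("windowBp must be >= stepBp")
  startsL <- lapply(names(genome), function(ch) {
    L <- genome[[ch]]
    starts <- seq(0, max(0, L - 1), by = stepBp)
    starts[starts < L]
  })
  ch <- rep(names(genome), lengths(startsL))
  starts <- unlist(startsL)
  ends <- pmin(starts + windowBp, genome[ch])
  out <- GRanges(factor(ch, levels = names(genome)),
                 IRanges(starts + 1, ends))
  seqlengths(out) <- genome[seqlevels(out)]
  metadata(out)$windowBp <- windowBp
  metadata(out)$stepBp <- stepBp
  out
}

#' Per-window diversity profile for a descendant against candidate ancestors
#'
#' Within each window, `Dpair` is the fraction of compared sites at which
#' the descendant and one candidate ancestor differ (same counting rules as
#' [pairwiseSimilarity()]); `Darv` is the mean of the pairwise diversities
#' over all unordered sample pairs in `gm`; and the diversity-decreased
#' level is `(Darv - Dpair) / Darv`, computed where `Darv > 0`. Windows with
#' fewer than `minSnps` compared sites for an ancestor are uninformative
#' (`NA`) for that ancestor.
#'
#' @param gm a [GenotypeMatrix-class]; all its samples enter `Darv`, so pass
#'   the panel you mean to average over.
#' @param windows window grid from [makeWindows()].
#' @param descendant focal sample id.
#' @param ancestors candidate ancestor ids.
#' @param hetPolicy see [pairwiseSimilarity()].
#' @param minSnps minimum compared sites per window (default 10).
#' @return A [DiversityProfile-class].
#' @export
windowDiversity <- function(gm, windows, descendant, ancestors,
                            hetPolicy = c("exclude", "half"), minSnps = 10) {
  hetPolicy <- match.arg(hetPolicy)
  ids <- sampleIds(gm)
  if (!descendant %in% ids) stop("descendant not in genotype matrix")
  if (!all(ancestors %in% ids)) stop("ancestor(s) missing from matrix")
  if (descendant %in% ancestors)
    stop("the descendant cannot be one of its own candidate ancestors")
  calls <- genotypeCalls(gm)
  sites <- variantSites(gm)
  nw <- length(windows)
  ov <- findOverlaps(sites, windows)
  qh <- queryHits(ov); sh <- subjectHits(ov)

  windowCounts <- function(i, j) {
    pd <- .pairDiff(calls[i, ], calls[j, ], hetPolicy)
    nd <- numeric(nw); nv <- numeric(nw)
    agg <- rowsum(cbind(pd$diff[qh], as.numeric(pd$valid[qh])), sh)
    at <- as.integer(rownames(agg))
    nd[at] <- agg[, 1]; nv[at] <- agg[, 2]
    list(nd = nd, nv = nv)
  }

  # Darv: mean per-pair diversity over all unordered pairs with data.
  n <- length(ids)
  sumD <- numeric(nw); nPairs <- numeric(nw)
  pairStore <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    wc <- windowCounts(i, j)
    ok <- wc$nv > 0
    sumD[ok] <- sumD[ok] + wc$nd[ok] / wc$nv[ok]
    nPairs <- nPairs + ok
    pairStore[[paste(ids[i], ids[j], sep = "\r")]] <- wc
  }
  dArv <- ifelse(nPairs > 0, sumD / nPairs, NA_real_)

  dPair <- matrix(NA_real_, nw, length(ancestors),
                  dimnames = list(NULL, ancestors))
  nSnps <- matrix(0L, nw, length(ancestors),
                  dimnames = list(NULL, ancestors))
  for (a in ancestors) {
    key <- if (match(descendant, ids) < match(a, ids))
      paste(descendant, a, sep = "\r") else paste(a, descendant, sep = "\r")
    wc <- pairStore[[key]]
    ok <- wc$nv > 0
    dPair[ok, a] <- wc$nd[ok] / wc$nv[ok]
    nSnps[, a] <- as.integer(wc$nv)
  }
  decrease <- (dArv - dPair) / dArv
  decrease[is.na(dArv) | dArv == 0] <- NA_real_
  decrease[nSnps < minSnps] <- NA_real_
  new("DiversityProfile", windows = windows, descendant = descendant,
      ancestors = ancestors, dPair = dPair, dArv = dArv,
      decrease = decrease, nSnps = nSnps, minSnps = as.integer(minSnps))
}

# ---- bimodal thresholding --------------------------------------------------

#' Threshold a bimodal distribution of diversity-decreased levels
#'
#' Fits a two-component Gaussian mixture by EM (deterministic
#' quantile-based initialisation: component means start at the 10% and 90%
#' quantiles) and returns the decision boundary between the components —
#' the point between the two means where the posterior responsibilities are
#' equal. When the fit looks unimodal (component means closer than `delta`,
#' or either weight below `minWeight`), the fixed `fallback` threshold is
#' returned and flagged.
#'
#' @param values numeric vector of diversity-decreased levels (NAs dropped).
#' @param minWindows minimum number of values required (default 50).
#' @param delta minimum separation of component means (default 0.1).
#' @param minWeight minimum component weight (default 0.05).
#' @param fallback threshold used when the distribution is unimodal
#'   (default 0.5).
#' @param maxIter,tol EM iteration controls.
#' @return List with `threshold`, `means`, `sds`, `weights`, `unimodal`
#'   (logical), and `n`.
#' @export
bimodalThreshold <- function(values, minWindows = 50, delta = 0.1,
                             minWeight = 0.05, fallback = 0.5,
                             maxIter = 500, tol = 1e-8) {
  x <- values[!is.na(values)]
  if (length(x) < minWindows)
    stop("insufficient windows: ", length(x), " < ", minWindows)
  mu <- as.numeric(quantile(x, c(0.1, 0.9)))
  s <- rep(max(sd(x) / 2, 1e-4), 2)
  w <- c(0.5, 0.5)
  if (mu[1] == mu[2]) {
    return(list(threshold = fallback, means = mu, sds = s, weights = w,
                unimodal = TRUE, n = length(x)))
  }
  ll0 <- -Inf
  for (it in seq_len(maxIter)) {
    d1 <- w[1] * dnorm(x, mu[1], s[1])
    d2 <- w[2] * dnorm(x, mu[2], s[2])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    r <- d1 / tot
    w <- c(mean(r), 1 - mean(r))
    if (w[1] > 0) mu[1] <- sum(r * x) / sum(r)
    if (w[2] > 0) mu[2] <- sum((1 - r) * x) / sum(1 - r)
    s[1] <- sqrt(max(sum(r * (x - mu[1])^2) / max(sum(r), 1e-12), 1e-8))
    s[2] <- sqrt(max(sum((1 - r) * (x - mu[2])^2) /
                       max(sum(1 - r), 1e-12), 1e-8))
    ll <- sum(log(tot))
    if (is.finite(ll) && abs(ll - ll0) < tol) break
    ll0 <- ll
  }
  if (mu[1] > mu[2]) {  # keep component 1 = lower mode
    mu <- rev(mu); s <- rev(s); w <- rev(w)
  }
  unimodal <- (mu[2] - mu[1]) < delta || min(w) < minWeight
  if (unimodal) {
    threshold <- fallback
  } else {
    f <- function(t) log(w[1]) + dnorm(t, mu[1], s[1], log = TRUE) -
      log(w[2]) - dnorm(t, mu[2], s[2], log = TRUE)
    lo <- mu[1]; hi <- mu[2]
    if (f(lo) > 0 && f(hi) < 0) {
      threshold <- uniroot(f, c(lo, hi), tol = 1e-10)$root
    } else {
      threshold <- (mu[1] + mu[2]) / 2
    }
  }
  list(threshold = threshold, means = mu, sds = s, weights = w,
       unimodal = unimodal, n = length(x))
}

#' Per-ancestor thresholds for a diversity profile
#'
#' Runs [bimodalThreshold()] on each ancestor's diversity-decreased values.
#'
#' @param profile a [DiversityProfile-class].
#' @param ... passed to [bimodalThreshold()].
#' @return Named list of threshold fits, one per ancestor.
#' @export
ancestryThresholds <- function(profile, ...) {
  out <- lapply(profile@ancestors, function(a)
    bimodalThreshold(profile@decrease[, a], ...))
  names(out) <- profile@ancestors
  out
}

# ---- block calling ---------------------------------------------------------

# Window labels: the ancestor whose decrease passes its threshold and is
# maximal; "uncertain" when none passes, when the top two passing ancestors
# are within tieMargin, or when the window is uninformative. For tied
# windows the tying pair is recorded: a run of windows consistently tied
# between the same two ancestors is a heterozygous region (one homolog
# from each) rather than a boundary artefact.
.windowLabels <- function(decrease, thresholds, tieMargin) {
  anc <- colnames(decrease)
  thr <- vapply(anc, function(a) thresholds[[a]]$threshold, numeric(1))
  out <- data.frame(label = character(nrow(decrease)),
                    tiePair = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(decrease))) {
    v <- decrease[i, ]
    pass <- !is.na(v) & v > thr
    if (!any(pass)) { out$label[i] <- "uncertain"; next }
    vp <- v[pass]
    o <- order(vp, decreasing = TRUE)
    if (length(vp) > 1 && vp[o[1]] - vp[o[2]] < tieMargin) {
      out$label[i] <- "uncertain"
      out$tiePair[i] <- paste(sort(names(vp)[o[1:2]]), collapse = "|")
    } else {
      out$label[i] <- names(vp)[o[1]]
    }
  }
  out
}

#' Call ancestor-of-origin haplotype blocks
#'
#' Each window is assigned the ancestor whose diversity-decreased level
#' exceeds its threshold and is maximal; windows where no ancestor passes,
#' or where the top two passing ancestors are within `tieMargin`, are
#' uncertain. Overlapping-window assignments are resolved on the step-sized
#' tiling: each step tile takes the label of the window whose centre is
#' closest to the tile's centre. Consecutive same-origin tiles merge into
#' blocks. An uncertain run whose windows are consistently tied between the
#' same two ancestors is a residual heterozygous region (one homolog from
#' each ancestor) and is apportioned equally between the two; other
#' uncertain runs strictly between two determinate blocks are split at
#' their midpoint and apportioned half to each, and uncertain runs at
#' chromosome ends attach to the single adjacent block. A chromosome that
#' is entirely uncertain is reported unassigned with a warning.
#'
#' @param profile a [DiversityProfile-class].
#' @param thresholds per-ancestor list from [ancestryThresholds()] (or a
#'   named numeric vector of thresholds).
#' @param tieMargin margin within which two passing ancestors tie
#'   (default 0.05).
#' @return `GRanges` of blocks with metadata columns `origin`,
#'   `mean_decrease`, `n_windows`; blocks per chromosome are sorted and
#'   non-overlapping.
#' @export
callBlocks <- function(profile, thresholds, tieMargin = 0.05) {
  if (is.numeric(thresholds))
    thresholds <- lapply(thresholds, function(t) list(threshold = t))
  windows <- profile@windows
  lab <- .windowLabels(profile@decrease, thresholds, tieMargin)
  labels <- lab$label
  tiePairs <- lab$tiePair
  stepBp <- metadata(windows)$stepBp
  if (is.null(stepBp)) stepBp <- min(diff(sort(unique(start(windows)))))
  out <- list()
  for (ch in seqlevels(windows)) {
    wi <- which(as.character(seqnames(windows)) == ch)
    if (!length(wi)) next
    wch <- windows[wi]
    o <- order(start(wch))
    wi <- wi[o]; wch <- wch[o]
    L <- seqlengths(windows)[ch]
    if (is.na(L)) L <- max(end(wch))
    # step tiles: tile k = [starts[k], starts[k+1]-1], last one runs to L
    starts <- start(wch)
    ends <- c(starts[-1] - 1L, L)
    # centre-matched window for each tile
    tileCentre <- (starts + ends) / 2
    winCentre <- (start(wch) + end(wch)) / 2
    nearest <- findInterval(tileCentre, winCentre)
    nearest <- pmin(pmax(nearest, 1L), length(wch))
    nearestUp <- pmin(nearest + 1L, length(wch))
    useUp <- abs(winCentre[nearestUp] - tileCentre) <
      abs(winCentre[nearest] - tileCentre)
    pick <- ifelse(useUp, nearestUp, nearest)
    tileLab <- labels[wi][pick]
    tilePair <- tiePairs[wi][pick]
    tileDec <- vapply(seq_along(pick), function(k) {
      lb <- tileLab[k]
      if (lb == "uncertain") NA_real_
      else profile@decrease[wi[pick[k]], lb]
    }, numeric(1))
    # merge runs
    runId <- cumsum(c(TRUE, tileLab[-1] != tileLab[-length(tileLab)]))
    runs <- data.frame(
      start = tapply(starts, runId, min),
      end = tapply(ends, runId, max),
      origin = tileLab[!duplicated(runId)],
      mean_decrease = as.numeric(tapply(tileDec, runId, function(v)
        mean(v, na.rm = TRUE))),
      n_windows = as.integer(table(runId)), row.names = NULL,
      stringsAsFactors = FALSE)
    # an uncertain run consistently tied between the same two ancestors is
    # a heterozygous region (one homolog from each): apportion it equally
    # between the two, keeping the flank-matching ancestor on the left
    runPair <- vapply(unique(runId), function(g) {
      pairs <- tilePair[runId == g & !is.na(tilePair)]
      if (!length(pairs) || length(pairs) <= sum(runId == g) / 2)
        return(NA_character_)
      names(sort(table(pairs), decreasing = TRUE))[1]
    }, "")
    hetRuns <- which(runs$origin == "uncertain" & !is.na(runPair))
    if (length(hetRuns)) {
      pieces <- vector("list", nrow(runs))
      for (r in seq_len(nrow(runs))) pieces[[r]] <- runs[r, , drop = FALSE]
      for (r in hetRuns) {
        pair <- strsplit(runPair[r], "|", fixed = TRUE)[[1]]
        leftFlank <- if (r > 1) runs$origin[r - 1] else NA_character_
        if (!is.na(leftFlank) && leftFlank %in% pair)
          pair <- c(leftFlank, setdiff(pair, leftFlank))
        mid <- floor((runs$start[r] + runs$end[r]) / 2)
        half <- runs[c(r, r), , drop = FALSE]
        half$origin <- pair
        half$end[1] <- mid; half$start[2] <- mid + 1
        half$n_windows <- c(ceiling(runs$n_windows[r] / 2),
                            floor(runs$n_windows[r] / 2))
        dec1 <- profile@decrease[wi[pick[runId == r]], pair[1]]
        dec2 <- profile@decrease[wi[pick[runId == r]], pair[2]]
        half$mean_decrease <- c(mean(dec1, na.rm = TRUE),
                                mean(dec2, na.rm = TRUE))
        pieces[[r]] <- half
      }
      runs <- do.call(rbind, pieces)
      rownames(runs) <- NULL
    }
    det <- runs$origin != "uncertain"
    if (!any(det)) {
      warning("chromosome ", ch, " entirely uncertain; left unassigned")
      next
    }
    # remaining uncertain runs: boundary regions between two determinate
    # blocks split at the midpoint; terminal runs attach to their single
    # neighbour
    for (r in which(!det)) {
      left <- if (r > 1) r - 1 else NA
      right <- if (r < nrow(runs)) r + 1 else NA
      if (!is.na(left) && !is.na(right)) {
        mid <- floor((runs$start[r] + runs$end[r]) / 2)
        runs$end[left] <- mid
        runs$start[right] <- mid + 1
      } else if (!is.na(left)) {
        runs$end[left] <- runs$end[r]
      } else if (!is.na(right)) {
        runs$start[right] <- runs$start[r]
      }
    }
    runs <- runs[det, , drop = FALSE]
    # merge adjacent blocks that ended up with the same origin
    grp <- cumsum(c(TRUE, runs$origin[-1] != runs$origin[-nrow(runs)]))
    merged <- data.frame(
      start = tapply(runs$start, grp, min),
      end = tapply(runs$end, grp, max),
      origin = runs$origin[!duplicated(grp)],
      mean_decrease = as.numeric(tapply(
        runs$mean_decrease * runs$n_windows, grp, sum)) /
        as.numeric(tapply(runs$n_windows, grp, sum)),
      n_windows = as.integer(tapply(runs$n_windows, grp, sum)),
      row.names = NULL, stringsAsFactors = FALSE)
    gr <- GRanges(factor(ch, levels = seqlevels(windows)),
                  IRanges(merged$start, merged$end),
                  origin = merged$origin,
                  mean_decrease = merged$mean_decrease,
                  n_windows = merged$n_windows)
    out[[ch]] <- gr
  }
  if (!length(out)) {
    blocks <- GRanges()
  } else {
    blocks <- suppressWarnings(do.call(c, unname(out)))
    seqlengths(blocks) <- seqlengths(windows)[seqlevels(blocks)]
  }
  blocks
}

#' Contribution fractions from a block mosaic
#'
#' Fractions are computed over the assigned genome only; unassigned length
#' (chromosome regions without a called block) is reported separately.
#'
#' @param blocks `GRanges` from [callBlocks()].
#' @param genome data.frame with `chrom`, `length_bp`, or named length
#'   vector; used to measure the unassigned remainder.
#' @return List with `fractions` (named, sums to 1), `assigned_bp`,
#'   `unassigned_bp`.
#' @export
contributionFractions <- function(blocks, genome) {
  if (is.data.frame(genome))
    genome <- setNames(genome$length_bp, genome$chrom)
  if (!length(blocks)) stop("no assigned blocks: zero assigned length")
  bp <- tapply(as.numeric(width(blocks)), mcols(blocks)$origin, sum)
  assigned <- sum(as.numeric(bp))
  if (assigned == 0) stop("zero assigned length")
  list(fractions = setNames(as.numeric(bp) / assigned, names(bp)),
       assigned_bp = assigned,
       unassigned_bp = sum(as.numeric(genome)) - assigned)
}

#' Agreement of called blocks with simulation truth
#'
#' Fraction of assigned genome length on which the called origin is among
#' the true origins of the two homologs at that position (heterosomal
#' regions carry two true origins; a call matching either is counted
#' correct).
#'
#' @param blocks `GRanges` from [callBlocks()].
#' @param mosaic a [TruthMosaic-class] for the same line.
#' @return Fraction in \[0, 1\].
#' @export
mosaicAccuracy <- function(blocks, mosaic) {
  truth <- truthOriginRanges(mosaic)
  ov <- findOverlaps(blocks, truth)
  inter <- pintersect(blocks[queryHits(ov)], truth[subjectHits(ov)])
  callOrigin <- mcols(blocks)$origin[queryHits(ov)]
  trueOrigins <- mcols(truth)$origins[subjectHits(ov)]
  hit <- mapply(function(o, set) o %in% set, callOrigin, trueOrigins)
  sum(as.numeric(width(inter))[hit]) / sum(as.numeric(width(blocks)))
}

#' Write blocks as BED
#'
#' Columns: chrom, start (0-based), end, origin, mean diversity-decreased
#' level.
#'
#' @param blocks `GRanges` from [callBlocks()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeBlocksBed <- function(blocks, path) {
  df <- data.frame(chrom = as.character(seqnames(blocks)),
                   start = start(blocks) - 1L, end = end(blocks),
                   origin = mcols(blocks)$origin,
                   score = round(mcols(blocks)$mean_decrease, 6))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
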