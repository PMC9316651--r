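# Windowed copy-number profiling: binning, median normalization, penalized
# least-squares segmentation, integer / arm-level / gene-level calls.

#' Bin mapped reads into the window grid
#'
#' Each mapped read increments exactly one window; reads on chromosomes
#' absent from the model (alternative contigs), beyond the chromosome end, or
#' in masked windows are dropped and tallied.
#'
#' @param reads a \linkS4class{ReadSet}.
#' @param grid a \linkS4class{WindowGrid} (built and masked).
#' @return a \linkS4class{BinCounts}; \code{sum(binCounts(x)) +
#'   droppedReads(x) == mappedCount(reads)}.
#' @export
binReads <- function(reads, grid) {
  idx <- locateWindow(grid, reads@chrom, reads@pos)
  msk <- windowMask(grid)
  ok <- !is.na(idx)
  ok[ok] <- !msk[idx[ok]]
  counts <- tabulate(idx[ok], nbins = nWindows(grid))
  new("BinCounts", counts = as.integer(counts),
      dropped = as.numeric(mappedCount(reads) - sum(ok)), grid = grid)
}

#' Normalize window counts to copy number
#'
#' Counts are first scaled to full-window density (a terminal window shorter
#' than the window size has proportionally fewer reads), then
#' \code{cn_i = ploidy * density_i / median(density over unmasked windows)},
#' so the median window sits at the ploidy by construction. Masked windows
#' get NA. The scale of the counts cancels: doubling all counts leaves the
#' copy numbers unchanged.
#'
#' @param bins a \linkS4class{BinCounts}.
#' @param ploidy baseline copy number (default 2).
#' @return numeric per-window copy number aligned to the grid.
#' @export
normalizeToCopyNumber <- function(bins, ploidy = 2) {
  grid <- bins@grid
  msk <- windowMask(grid)
  dens <- bins@counts *
    (windowSize(grid) / GenomicRanges::width(grid@windows))
  ref <- dens[!msk]
  if (!length(ref) || all(ref == 0))
    stop("all unmasked window counts are zero: cannot normalize")
  med <- stats::median(ref)
  if (med == 0)
    stop("median unmasked window count is zero: profile too sparse to normalize")
  cn <- ploidy * dens / med
  cn[msk] <- NA_real_
  cn
}

# Optimal partition of one chromosome's copy-number vector by penalized
# (weighted) least squares: minimize the sum of within-segment weighted
# squared error plus penalty per segment. Weights are window widths relative
# to the full window size, since the estimator variance of a partial window
# scales inversely with its width. Exact O(n^2) dynamic program; ties broken
# toward fewer segments.
segmentOneChrom <- function(y, w, penalty) {
  n <- length(y)
  cw0 <- c(0, cumsum(w))
  cs0 <- c(0, cumsum(w * y))
  cs20 <- c(0, cumsum(w * y * y))
  F <- c(0, rep(Inf, n))
  K <- integer(n + 1)
  prev <- integer(n + 1)
  for (j in seq_len(n)) {
    t <- 0:(j - 1)
    sw <- cw0[j + 1] - cw0[t + 1]
    s1 <- cs0[j + 1] - cs0[t + 1]
    s2 <- cs20[j + 1] - cs20[t + 1]
    cost <- s2 - s1 * s1 / sw
    vals <- F[t + 1] + cost + penalty
    best <- which.min(vals)
    tol <- 1e-9 * (1 + abs(vals[best]))
    cand <- which(vals <= vals[best] + tol)
    if (length(cand) > 1L) best <- cand[which.min(K[cand])]
    F[j + 1] <- vals[best]
    prev[j + 1] <- best - 1L
    K[j + 1] <- K[best] + 1L
  }
  bounds <- integer(0)
  j <- n
  while (j > 0) {
    bounds <- c(prev[j + 1], bounds)
    j <- prev[j + 1]
  }
  cbind(first = bounds + 1L, last = c(bounds[-1], n))
}

#' Segment a per-window copy-number profile
#'
#' Per-chromosome least-squares changepoint segmentation minimizing the
#' within-segment squared error plus \code{penalty} per changepoint, solved
#' exactly by dynamic programming. Windows are weighted by their width
#' relative to the window size (all 1 except terminal partial windows, whose
#' copy-number estimates are noisier in proportion), so with a regular grid
#' this is ordinary least squares. Segments never span chromosome
#' boundaries; each segment's level is the (weighted) mean copy number of
#' its windows. The default penalty is BIC-like,
#' \code{2 * sigma^2 * log(n)}, with \code{sigma} estimated from the median
#' absolute deviation of successive window differences.
#'
#' @param cn per-window copy number (NA for masked windows), aligned to
#'   \code{grid}.
#' @param grid the \linkS4class{WindowGrid}.
#' @param penalty positive penalty per changepoint; NULL for the default.
#' @return data.frame with columns chrom, start, end (0-based half-open over
#'   the segment's windows), nWindows, level; the window-to-segment
#'   assignment is in attribute \code{windowSegment}.
#' @export
segmentProfile <- function(cn, grid, penalty = NULL) {
  wt <- windowTable(grid)
  use <- !wt$mask & !is.na(cn)
  chroms <- chromNames(grid@genome)
  if (is.null(penalty)) {
    d <- unlist(lapply(chroms, function(cc) {
      diff(cn[use & wt$chrom == cc])
    }), use.names = FALSE)
    sigma <- stats::mad(d) / sqrt(2)
    penalty <- 2 * sigma^2 * log(max(sum(use), 2))
    if (!is.finite(penalty) || penalty <= 0) penalty <- 1e-8
  }
  if (penalty <= 0) stop("penalty must be positive")
  wgt <- (wt$end - wt$start) / windowSize(grid)
  segs <- list()
  windowSegment <- rep(NA_integer_, nrow(wt))
  segId <- 0L
  for (cc in chroms) {
    idx <- which(use & wt$chrom == cc)
    if (!length(idx)) next
    if (length(idx) == 1L) {
      bounds <- cbind(first = 1L, last = 1L)
    } else {
      bounds <- segmentOneChrom(cn[idx], wgt[idx], penalty)
    }
    for (b in seq_len(nrow(bounds))) {
      segId <- segId + 1L
      win <- idx[bounds[b, "first"]:bounds[b, "last"]]
      segs[[segId]] <- data.frame(
        chrom = cc, start = wt$start[win[1]], end = wt$end[win[length(win)]],
        nWindows = length(win),
        level = sum(wgt[win] * cn[win]) / sum(wgt[win]),
        stringsAsFactors = FALSE)
      windowSegment[win] <- segId
    }
  }
  out <- do.call(rbind, segs)
  if (is.null(out))
    out <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), nWindows = integer(0),
                      level = numeric(0))
  attr(out, "windowSegment") <- windowSegment
  attr(out, "penalty") <- penalty
  out
}

#' Round segment levels to integer copy number and call states
#'
#' Integer CN is the segment level rounded and clamped to [0, maxCN]; state
#' is gain above the ploidy, loss below, neutral at it.
#'
#' @param segments segment data.frame from \code{\link{segmentProfile}}.
#' @param ploidy baseline copy number (default 2).
#' @param maxCN clamp for the integer copy number (default 20).
#' @return the segments with added columns cn and state.
#' @export
callIntegerCN <- function(segments, ploidy = 2, maxCN = 20) {
  if (nrow(segments) && any(segments$level < 0))
    stop("segment levels must be >= 0")
  cn <- as.integer(pmin(pmax(round(segments$level), 0), maxCN))
  segments$cn <- cn
  segments$state <- ifelse(cn > ploidy, "gain",
                           ifelse(cn < ploidy, "loss", "neutral"))
  segments
}

#' Full copy-number profile for one cell
#'
#' Bins the reads, normalizes to copy number, segments, and calls integer
#' copy numbers and states.
#'
#' @param reads a \linkS4class{ReadSet}.
#' @param grid a \linkS4class{WindowGrid}.
#' @param ploidy baseline copy number (default 2).
#' @param penalty segmentation penalty (NULL = BIC-like default).
#' @param maxCN integer-CN clamp (default 20).
#' @return a \linkS4class{CopyNumberProfile}.
#' @export
callCNVProfile <- function(reads, grid, ploidy = 2, penalty = NULL,
                           maxCN = 20) {
  bins <- binReads(reads, grid)
  cn <- normalizeToCopyNumber(bins, ploidy)
  segs <- segmentProfile(cn, grid, penalty)
  windowSegment <- attr(segs, "windowSegment")
  attr(segs, "windowSegment") <- NULL
  segs <- callIntegerCN(segs, ploidy = ploidy, maxCN = maxCN)
  new("CopyNumberProfile", bins = bins, cn = cn,
      windowSegment = windowSegment, segments = segs,
      ploidy = as.integer(ploidy))
}

#' Arm-level gain/loss calls
#'
#' For each chromosome arm, the altered fraction is the share of usable arm
#' windows lying in non-neutral segments of a consistent direction; an arm
#' state is called when that fraction reaches \code{minFraction}.
#'
#' @param profile a \linkS4class{CopyNumberProfile}.
#' @param minFraction fraction of arm windows required (default 0.8).
#' @return data.frame with columns chrom, arm, nWindows, gainFraction,
#'   lossFraction, fraction (the larger direction), state (gain/loss/none).
#' @export
callArmEvents <- function(profile, minFraction = 0.8) {
  grid <- profile@bins@grid
  wt <- windowTable(grid)
  st <- rep(NA_character_, nrow(wt))
  ok <- !is.na(profile@windowSegment)
  st[ok] <- profile@segments$state[profile@windowSegment[ok]]
  keyChrom <- factor(wt$chrom, levels = chromNames(grid@genome))
  key <- interaction(keyChrom, wt$arm, drop = FALSE, lex.order = TRUE)
  res <- lapply(levels(key)[levels(key) %in% unique(as.character(key[ok]))],
                function(k) {
    sel <- ok & as.character(key) == k
    n <- sum(sel)
    gf <- sum(st[sel] == "gain") / n
    lf <- sum(st[sel] == "loss") / n
    parts <- strsplit(k, ".", fixed = TRUE)[[1]]
    data.frame(chrom = parts[1], arm = parts[2], nWindows = n,
               gainFraction = gf, lossFraction = lf,
               fraction = max(gf, lf),
               state = if (gf >= minFraction) "gain"
                       else if (lf >= minFraction) "loss" else "none",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Gene-level copy-number status
#'
#' Each gene takes the integer copy number and state of the segment
#' containing its midpoint; genes whose midpoint falls in a masked window (or
#' off the model) are reported as no-call.
#'
#' @param profile a \linkS4class{CopyNumberProfile}.
#' @param genes data.frame with columns chrom, start, end (0-based
#'   half-open), gene — e.g. from \code{\link{readGeneBed}}.
#' @return data.frame with columns gene, chrom, midpoint, cn, state.
#' @export
annotateGenes <- function(profile, genes) {
  grid <- profile@bins@grid
  mid <- floor((genes$start + genes$end) / 2)
  widx <- locateWindow(grid, genes$chrom, mid)
  cn <- rep(NA_integer_, nrow(genes))
  state <- rep("no-call", nrow(genes))
  ok <- !is.na(widx)
  seg <- rep(NA_integer_, nrow(genes))
  seg[ok] <- profile@windowSegment[widx[ok]]
  hit <- !is.na(seg)
  cn[hit] <- profile@segments$cn[seg[hit]]
  state[hit] <- profile@segments$state[seg[hit]]
  data.frame(gene = genes$gene, chrom = genes$chrom, midpoint = mid,
             cn = cn, state = state, stringsAsFactors = FALSE)
}
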