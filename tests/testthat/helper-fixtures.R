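# Shared builders for toy genomes and read sets.

toyGenome <- function(n = 3, len = 4e7, cent = len / 2) {
  GenomeModel(paste0("chr", seq_len(n)), rep(len, n), rep(cent, n))
}

toyGrid <- function(n = 3, len = 4e7, windowSize = 1e6, cent = len / 2) {
  buildWindowGrid(toyGenome(n, len, cent), windowSize)
}

# A ReadSet placing `counts[i]` reads in window i of a single-chromosome grid
# (read at the window midpoint).
readsFromWindowCounts <- function(grid, counts) {
  wt <- sclpCNV:::windowTable(grid)
  stopifnot(length(counts) == nrow(wt))
  idx <- rep.int(seq_along(counts), counts)
  ReadSet(wt$chrom[idx], floor((wt$start[idx] + wt$end[idx]) / 2))
}

# Brute-force penalized least-squares segmentation by enumerating all
# changepoint subsets (feasible for n <= ~14). Returns the minimal objective.
bruteForceSegmentCost <- function(y, penalty) {
  n <- length(y)
  best <- Inf
  for (code in 0:(2^(n - 1) - 1)) {
    cps <- which(bitwAnd(code, 2^(0:(n - 2))) != 0)
    bounds <- c(0, cps, n)
    cost <- 0
    for (b in seq_len(length(bounds) - 1)) {
      seg <- y[(bounds[b] + 1):bounds[b + 1]]
      cost <- cost + sum((seg - mean(seg))^2)
    }
    cost <- cost + penalty * (length(bounds) - 1)
    if (cost < best) best <- cost
  }
  best
}

# Objective value achieved by a segmentation data.frame on a single-chromosome
# equal-width profile.
segmentationCost <- function(segs, y, grid, penalty) {
  ws <- attr(segs, "windowSegment")
  cost <- 0
  for (s in seq_len(nrow(segs))) {
    seg <- y[which(ws == s)]
    cost <- cost + sum((seg - mean(seg))^2)
  }
  cost + penalty * nrow(segs)
}
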