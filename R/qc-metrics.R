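# Cell-level QC battery: genome integrity index, mapped-read gate, DLRS,
# R50, and the combined keep/discard decision.

#' Genome integrity index (GII)
#'
#' The number of diagnostic QC bands present on the whole-genome-amplification
#' quality gel, out of 4; 4 indicates the highest quality and a GII of at
#' least 2 is the conventional sequencing-eligibility bar.
#'
#' @param bands logical vector of exactly 4 band-presence indicators.
#' @return integer in 0..4.
#' @examples
#' genomeIntegrityIndex(c(TRUE, TRUE, TRUE, TRUE))   # 4
#' genomeIntegrityIndex(c(TRUE, FALSE, TRUE, FALSE)) # 2
#' @export
genomeIntegrityIndex <- function(bands) {
  if (!is.logical(bands) || length(bands) != 4L || anyNA(bands))
    stop("band presence must be exactly 4 non-missing logical values")
  as.integer(sum(bands))
}

#' Mapped-read gate
#'
#' @param reads a \linkS4class{ReadSet}.
#' @param threshold minimum mapped reads (inclusive; default 200,000).
#' @return TRUE iff mappedCount(reads) >= threshold.
#' @export
mappedReadGate <- function(reads, threshold = 2e5) {
  mappedCount(reads) >= threshold
}

#' DLRS statistic on a copy-number vector
#'
#' Literal derivative log ratio spread: the sample standard deviation of
#' \code{diff(log2(cn / 2)) / sqrt(2)}, with differences taken only between
#' windows on the same chromosome when \code{chrom} is supplied. All \code{cn}
#' values must be positive.
#'
#' @param cn positive per-window copy numbers, in genome order.
#' @param chrom optional chromosome label per window; differences never cross
#'   a chromosome boundary.
#' @return the DLRS value.
#' @export
dlrsStatistic <- function(cn, chrom = NULL) {
  if (any(cn <= 0)) stop("dlrsStatistic requires positive copy numbers")
  x <- log2(cn / 2)
  d <- if (is.null(chrom)) diff(x)
  else {
    f <- factor(chrom, levels = unique(chrom))
    unlist(lapply(split(x, f), diff), use.names = FALSE)
  }
  if (length(d) < 2L) stop("fewer than 2 window differences: DLRS undefined")
  stats::sd(d / sqrt(2))
}

#' Derivative log ratio spread of a cell
#'
#' Procedure: draw a seeded uniform subsample of \code{subsample} mapped reads
#' (all reads, flagged, when fewer are available); bin into unmasked windows;
#' normalize to copy number at the given ploidy (median window = ploidy); drop
#' zero-copy-number windows (their count is reported — at low pass a zero
#' count reflects dropout, not signal); then apply \code{\link{dlrsStatistic}}
#' with differences confined within chromosomes.
#'
#' @param reads a \linkS4class{ReadSet}.
#' @param grid a \linkS4class{WindowGrid}.
#' @param ploidy normalization ploidy (default 2).
#' @param subsample reads used for the metric (default 200,000).
#' @param seed subsampling seed.
#' @return the DLRS value, with attributes \code{zeroWindowsDropped},
#'   \code{readsUsed} and \code{subsampled}.
#' @export
computeDLRS <- function(reads, grid, ploidy = 2, subsample = 2e5, seed = NULL)
  withSeed(seed, {
    m <- mappedCount(reads)
    subsampled <- m > subsample
    sub <- if (subsampled) {
      keep <- sample.int(m, subsample)
      new("ReadSet", chrom = reads@chrom[keep], pos = reads@pos[keep],
          fragment = integer(0), unmapped = 0)
    } else reads
    bins <- binReads(sub, grid)
    cn <- normalizeToCopyNumber(bins, ploidy)
    msk <- windowMask(grid)
    use <- !msk & !is.na(cn) & cn > 0
    if (sum(use) < 3L) stop("fewer than 3 usable windows: DLRS undefined")
    chrom <- as.character(GenomicRanges::seqnames(grid@windows))
    val <- dlrsStatistic(cn[use], chrom[use])
    attr(val, "zeroWindowsDropped") <- sum(!msk & !is.na(cn) & cn == 0)
    attr(val, "readsUsed") <- mappedCount(sub)
    attr(val, "subsampled") <- subsampled
    val
  })

#' R50 from per-fragment read counts
#'
#' Sort detected fragments by read count (descending); \code{N1} is the
#' smallest number of top fragments whose cumulative reads reach half the
#' total, \code{N2} the number of fragments with at least one read; R50 is
#' \code{100 * N1 / N2}. A uniform library gives ~50; a library dominated by
#' one fragment gives ~100/N2 — low values mean poor complexity.
#'
#' @param counts non-negative per-fragment read counts.
#' @return R50 percentage in (0, 100].
#' @examples
#' r50FromCounts(rep(50, 4000))      # 50
#' r50FromCounts(c(150000, rep(1, 50000)))  # ~0.002
#' @export
r50FromCounts <- function(counts) {
  counts <- counts[counts > 0]
  if (!length(counts)) stop("no fragments with reads")
  s <- sort(counts, decreasing = TRUE)
  n1 <- which(cumsum(s) >= ceiling(sum(s) / 2))[1]
  100 * n1 / length(s)
}

#' R50 library-complexity metric of a cell
#'
#' Computed on a seeded 200,000-read subsample of the mapped reads (all
#' reads when fewer are available), over amplification-fragment-of-origin
#' labels.
#'
#' @param reads a \linkS4class{ReadSet} with fragment ids.
#' @param subsample reads used (default 200,000).
#' @param seed subsampling seed.
#' @return the R50 value with attributes \code{topFragments} (N1),
#'   \code{detectedFragments} (N2) and \code{readsUsed}.
#' @export
computeR50 <- function(reads, subsample = 2e5, seed = NULL)
  withSeed(seed, {
    if (!hasFragmentIds(reads))
      stop("reads carry no fragment assignments: R50 unavailable")
    m <- mappedCount(reads)
    frag <- if (m > subsample) reads@fragment[sample.int(m, subsample)]
            else reads@fragment
    counts <- tabulate(frag)
    val <- r50FromCounts(counts)
    s <- sort(counts[counts > 0], decreasing = TRUE)
    attr(val, "topFragments") <- which(cumsum(s) >= ceiling(sum(s) / 2))[1]
    attr(val, "detectedFragments") <- length(s)
    attr(val, "readsUsed") <- length(frag)
    val
  })

#' QC thresholds configuration
#'
#' @param giiMin minimum GII for sequencing eligibility (default 2).
#' @param mappedMin minimum mapped reads, inclusive (default 200,000).
#' @param dlrsMax maximum tolerated DLRS (default 0.35).
#' @param r50Min minimum R50; NA (default) makes the R50 gate report-only.
#' @return named list of thresholds.
#' @export
qcThresholds <- function(giiMin = 2, mappedMin = 2e5, dlrsMax = 0.35,
                         r50Min = NA_real_) {
  list(giiMin = giiMin, mappedMin = mappedMin, dlrsMax = dlrsMax,
       r50Min = r50Min)
}

#' Evaluate the full QC battery for one cell
#'
#' Gates are applied in order GII, mapped reads, DLRS, R50. A cell failing
#' the GII gate is not sequencing-eligible, so the downstream gates are
#' marked not applicable. The R50 gate is report-only unless an
#' \code{r50Min} threshold is configured, and is skipped when the reads carry
#' no fragment assignments. The overall verdict is keep iff every applicable
#' gate passes.
#'
#' @param reads a \linkS4class{ReadSet}.
#' @param grid a \linkS4class{WindowGrid}.
#' @param gii the genome integrity index: either the integer 0-4 or the 4
#'   band-presence logicals.
#' @param thresholds see \code{\link{qcThresholds}}.
#' @param ploidy normalization ploidy for DLRS (default 2).
#' @param seed subsampling seed, recorded in the report.
#' @return a \linkS4class{QCReport}.
#' @export
evaluateCell <- function(reads, grid, gii, thresholds = qcThresholds(),
                         ploidy = 2, seed = NULL) {
  giiVal <- if (is.logical(gii)) genomeIntegrityIndex(gii)
            else as.integer(gii)
  if (is.na(giiVal) || giiVal < 0L || giiVal > 4L)
    stop("gii must be in 0..4 or 4 band indicators")
  m <- mappedCount(reads)
  giiPass <- giiVal >= thresholds$giiMin
  eligible <- giiPass

  mappedPass <- if (eligible) mappedReadGate(reads, thresholds$mappedMin) else NA

  dlrs <- NA_real_
  dlrsPass <- NA
  dlrsReason <- ""
  details <- list(seed = seed)
  if (eligible) {
    res <- tryCatch(computeDLRS(reads, grid, ploidy = ploidy,
                                seed = childSeed(seed, 1L)),
                    error = function(e) e)
    if (inherits(res, "error")) {
      dlrsPass <- FALSE
      dlrsReason <- paste0("DLRS undefined: ", conditionMessage(res))
    } else {
      dlrs <- as.numeric(res)
      details$dlrsZeroWindowsDropped <- attr(res, "zeroWindowsDropped")
      details$dlrsSubsampled <- attr(res, "subsampled")
      dlrsPass <- dlrs <= thresholds$dlrsMax
      if (!dlrsPass) dlrsReason <- sprintf("DLRS > %g", thresholds$dlrsMax)
    }
  }

  r50 <- NA_real_
  r50Pass <- NA
  r50Applicable <- FALSE
  r50Reason <- ""
  if (eligible) {
    if (!hasFragmentIds(reads)) {
      r50Reason <- "no fragment assignments: R50 unavailable, gate skipped"
    } else {
      r50Applicable <- TRUE
      r50 <- as.numeric(computeR50(reads, seed = childSeed(seed, 2L)))
      if (is.na(thresholds$r50Min)) {
        r50Pass <- TRUE
        r50Reason <- "report-only (no threshold configured)"
      } else {
        r50Pass <- r50 >= thresholds$r50Min
        if (!r50Pass) r50Reason <- sprintf("R50 < %g", thresholds$r50Min)
      }
    }
  }

  gates <- data.frame(
    gate = c("gii", "mapped_reads", "dlrs", "r50"),
    value = c(giiVal, m, dlrs, r50),
    threshold = c(thresholds$giiMin, thresholds$mappedMin, thresholds$dlrsMax,
                  thresholds$r50Min),
    passed = c(giiPass, mappedPass, dlrsPass, r50Pass),
    applicable = c(TRUE, eligible, eligible, r50Applicable),
    reason = c(if (giiPass) "" else sprintf("GII < %g", thresholds$giiMin),
               if (!eligible) "not applicable (GII gate failed)"
               else if (mappedPass) "" else "too few mapped reads",
               if (!eligible) "not applicable (GII gate failed)" else dlrsReason,
               if (!eligible && !r50Applicable) "not applicable (GII gate failed)"
               else r50Reason),
    stringsAsFactors = FALSE)

  appl <- gates$applicable & !is.na(gates$passed)
  keep <- all(gates$passed[appl])
  new("QCReport", mappedReads = as.numeric(m), gii = giiVal, dlrs = dlrs,
      r50 = r50, gates = gates, keep = keep, details = details)
}
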