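#' @import methods
#' @importFrom GenomicRanges GRanges findOverlaps pintersect reduce seqnames start end width mcols mcols<-
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits
NULL

#' GenomeModel: the reference coordinate system
#'
#' Ordered primary chromosomes with lengths and centromere positions. The
#' default human model is hg19-like; the \code{"female"} sex mode exposes the
#' 22 autosomes plus X (23 chromosomes), \code{"male"} additionally includes Y.
#' All coordinates in the package are 0-based half-open; SAM input (1-based) is
#' converted at the reader boundary.
#'
#' @slot chrom character vector of unique chromosome names, in genome order.
#' @slot length numeric vector of chromosome lengths in base pairs.
#' @slot centromere numeric vector of centromere positions (0-based); a
#'   position at or beyond the centromere belongs to the q arm.
#' @slot sexMode either \code{"female"} or \code{"male"}.
#' @export
setClass("GenomeModel",
  slots = c(chrom = "character", length = "numeric",
            centromere = "numeric", sexMode = "character"))

setValidity("GenomeModel", function(object) {
  msg <- character(0)
  n <- length(object@chrom)
  if (length(object@length) != n || length(object@centromere) != n)
    msg <- c(msg, "chrom, length and centromere must have equal length")
  if (anyDuplicated(object@chrom)) msg <- c(msg, "chromosome names must be unique")
  if (any(object@length <= 0)) msg <- c(msg, "chromosome lengths must be > 0")
  if (length(object@length) == n &&
      any(object@centromere <= 0 | object@centromere >= object@length))
    msg <- c(msg, "centromere positions must satisfy 0 < centromere < length")
  if (length(object@sexMode) != 1L || !object@sexMode %in% c("female", "male"))
    msg <- c(msg, "sexMode must be 'female' or 'male'")
  if (length(msg)) msg else TRUE
})

#' WindowGrid: fixed-size window tiling of a genome model
#'
#' Windows tile each chromosome without gaps or overlaps; every window except
#' possibly the terminal one per chromosome has width \code{windowSize}. Each
#' window carries the chromosome arm of its midpoint and a mask flag; masked
#' windows are excluded from binning, copy-number estimation and DLRS.
#'
#' @slot windows a \code{GRanges} of the tiling, with metadata columns
#'   \code{arm} ("p"/"q") and \code{mask} (logical, TRUE = excluded).
#' @slot windowSize window width in base pairs.
#' @slot genome the \linkS4class{GenomeModel} the grid was built from.
#' @export
setClass("WindowGrid",
  slots = c(windows = "GRanges", windowSize = "numeric", genome = "GenomeModel"))

setValidity("WindowGrid", function(object) {
  msg <- character(0)
  if (length(object@windowSize) != 1L || object@windowSize < 1)
    msg <- c(msg, "windowSize must be a single value >= 1")
  mc <- GenomicRanges::mcols(object@windows)
  if (!all(c("arm", "mask") %in% colnames(mc)))
    msg <- c(msg, "windows must carry 'arm' and 'mask' metadata columns")
  if (length(msg)) msg else TRUE
})

#' ReadSet: mapped single-cell read positions
#'
#' Mapped read positions (0-based) with an unmapped-read tally and optional
#' fragment-of-origin labels (used by the R50 complexity metric).
#'
#' @slot chrom chromosome of each mapped read.
#' @slot pos 0-based position of each mapped read.
#' @slot fragment integer fragment-of-origin ids (length 0 when unavailable).
#' @slot unmapped number of unmapped (e.g. contaminating) reads.
#' @export
setClass("ReadSet",
  slots = c(chrom = "character", pos = "numeric",
            fragment = "integer", unmapped = "numeric"))

setValidity("ReadSet", function(object) {
  msg <- character(0)
  n <- length(object@chrom)
  if (length(object@pos) != n) msg <- c(msg, "chrom and pos must have equal length")
  if (!length(object@fragment) %in% c(0L, n))
    msg <- c(msg, "fragment ids must be absent or one per mapped read")
  if (n && any(object@pos < 0)) msg <- c(msg, "read positions must be >= 0")
  if (length(object@unmapped) != 1L || is.na(object@unmapped) || object@unmapped < 0)
    msg <- c(msg, "unmapped count must be a single value >= 0")
  if (length(msg)) msg else TRUE
})

#' TruthProfile: ground-truth copy-number track for simulation
#'
#' A baseline ploidy plus non-overlapping copy-number events (0-based
#' half-open). Windows straddling an event boundary take the copy number of
#' the plurality overlap.
#'
#' @slot genome the \linkS4class{GenomeModel} events are placed on.
#' @slot ploidy baseline integer copy number outside events.
#' @slot events \code{GRanges} with an integer \code{cn} metadata column.
#' @export
setClass("TruthProfile",
  slots = c(genome = "GenomeModel", ploidy = "integer", events = "GRanges"))

setValidity("TruthProfile", function(object) {
  msg <- character(0)
  if (length(object@ploidy) != 1L || object@ploidy < 0)
    msg <- c(msg, "ploidy must be a single integer >= 0")
  ev <- object@events
  if (length(ev)) {
    if (!"cn" %in% colnames(GenomicRanges::mcols(ev)))
      msg <- c(msg, "events must carry a 'cn' metadata column")
    else if (any(GenomicRanges::mcols(ev)$cn < 0))
      msg <- c(msg, "event copy numbers must be >= 0")
    ci <- match(as.character(GenomicRanges::seqnames(ev)), object@genome@chrom)
    if (anyNA(ci))
      msg <- c(msg, "events reference chromosomes absent from the genome model")
    else if (any(GenomicRanges::end(ev) > object@genome@length[ci]))
      msg <- c(msg, "events extend beyond chromosome bounds")
    if (length(GenomicRanges::reduce(ev)) != length(ev) ||
        sum(GenomicRanges::width(GenomicRanges::reduce(ev))) != sum(GenomicRanges::width(ev)))
      msg <- c(msg, "events must be non-overlapping")
  }
  if (length(msg)) msg else TRUE
})

#' FragmentLibrary: amplification fragments of a single-cell WGA library
#'
#' Restriction-fragment proxy for PCR-based whole genome amplification:
#' contiguous fragments partitioning each chromosome, each with an
#' amplification weight and a dropout flag. Four designated fragments are the
#' diagnostic QC loci whose post-WGA presence defines the genome integrity
#' index (GII).
#'
#' @slot chrom,start,end parallel vectors of fragment coordinates
#'   (0-based half-open).
#' @slot weight amplification weight (local copy number times lognormal
#'   efficiency; 0 for dropped fragments). All 1 before WGA.
#' @slot dropped logical dropout flags (all FALSE before WGA).
#' @slot qcLoci indices of the 4 diagnostic QC fragments.
#' @slot giiBands presence of the 4 QC bands after WGA (length 0 before WGA).
#' @export
setClass("FragmentLibrary",
  slots = c(chrom = "character", start = "numeric", end = "numeric",
            weight = "numeric", dropped = "logical",
            qcLoci = "integer", giiBands = "logical"))

setValidity("FragmentLibrary", function(object) {
  msg <- character(0)
  n <- length(object@chrom)
  if (length(object@start) != n || length(object@end) != n ||
      length(object@weight) != n || length(object@dropped) != n)
    msg <- c(msg, "fragment vectors must have equal length")
  else {
    if (any(object@end <= object@start)) msg <- c(msg, "fragments must have positive width")
    if (any(object@weight < 0)) msg <- c(msg, "fragment weights must be >= 0")
  }
  if (length(object@qcLoci) != 4L || any(object@qcLoci < 1L) || any(object@qcLoci > n))
    msg <- c(msg, "exactly 4 QC loci within fragment range required")
  if (!length(object@giiBands) %in% c(0L, 4L))
    msg <- c(msg, "giiBands must be absent or length 4")
  if (length(msg)) msg else TRUE
})

#' SyntheticCell: one simulated single-cell library
#'
#' Bundle of ground truth, post-WGA fragment library, generated reads and the
#' parameters/seed that deterministically produced them.
#'
#' @slot truth the \linkS4class{TruthProfile} simulated from.
#' @slot library the post-WGA \linkS4class{FragmentLibrary}.
#' @slot reads the generated \linkS4class{ReadSet}.
#' @slot seed the driving seed (NA when simulated off the ambient RNG).
#' @slot params named list of generator parameters.
#' @export
setClass("SyntheticCell",
  slots = c(truth = "TruthProfile", library = "FragmentLibrary",
            reads = "ReadSet", seed = "numeric", params = "list"))

#' BinCounts: reads binned into the window grid
#'
#' @slot counts integer read counts aligned to the grid's windows (masked
#'   windows hold 0 by construction).
#' @slot dropped number of mapped reads not counted (unmodeled chromosome,
#'   beyond chromosome end, or masked window).
#' @slot grid the \linkS4class{WindowGrid} the counts are aligned to.
#' @export
setClass("BinCounts",
  slots = c(counts = "integer", dropped = "numeric", grid = "WindowGrid"))

setValidity("BinCounts", function(object) {
  if (length(object@counts) != length(object@grid@windows))
    return("counts must align to the grid's windows")
  if (any(object@counts < 0)) return("counts must be >= 0")
  TRUE
})

#' QCReport: per-cell quality-control verdicts
#'
#' The cell-level QC battery — GII, mapped-read minimum, DLRS, R50 — applied
#' in order, with one row per gate and an overall keep/discard verdict. Gates
#' downstream of a failed sequencing-eligibility (GII) gate are marked not
#' applicable.
#'
#' @slot mappedReads number of mapped reads.
#' @slot gii genome integrity index (0-4).
#' @slot dlrs derivative log ratio spread (NA when undefined).
#' @slot r50 R50 library-complexity percentage (NA when unavailable).
#' @slot gates data.frame with columns gate, value, threshold, passed,
#'   applicable, reason.
#' @slot keep overall verdict: TRUE iff all applicable gates pass.
#' @slot details list of provenance (subsample seed, windows dropped, ...).
#' @export
setClass("QCReport",
  slots = c(mappedReads = "numeric", gii = "integer", dlrs = "numeric",
            r50 = "numeric", gates = "data.frame", keep = "logical",
            details = "list"))

#' CopyNumberProfile: windowed copy-number calls for one cell
#'
#' Per-window copy-number estimates, penalized least-squares segments with
#' integer copy number and gain/loss/neutral state, and the window-to-segment
#' assignment.
#'
#' @slot bins the \linkS4class{BinCounts} the profile was estimated from.
#' @slot cn per-window copy-number estimate (NA for masked windows).
#' @slot windowSegment integer segment id per window (NA for masked windows).
#' @slot segments data.frame: chrom, start, end, nWindows, level, cn, state.
#' @slot ploidy baseline ploidy copy-number states are called against.
#' @export
setClass("CopyNumberProfile",
  slots = c(bins = "BinCounts", cn = "numeric", windowSegment = "integer",
            segments = "data.frame", ploidy = "integer"))

#' CohortSummary: per-cell QC and profiling results across a run
#'
#' @slot cells data.frame with one row per input cell: id, mappedReads, gii,
#'   dlrs, r50, keep, firstFail.
#' @slot thresholds the QC thresholds applied.
#' @slot outputs character vector of files written (empty for in-memory runs).
#' @export
setClass("CohortSummary",
  slots = c(cells = "data.frame", thresholds = "list", outputs = "character"))
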