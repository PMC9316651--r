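# Constructors for plain containers, accessors and show methods.

#' Construct a ReadSet from mapped positions
#'
#' @param chrom chromosome per mapped read.
#' @param pos 0-based position per mapped read.
#' @param fragment optional integer fragment-of-origin ids.
#' @param unmapped unmapped-read tally (default 0).
#' @return a \linkS4class{ReadSet}.
#' @examples
#' r <- ReadSet(rep("chr1", 3), c(0, 5e5, 1.2e6))
#' mappedCount(r)
#' @export
ReadSet <- function(chrom, pos, fragment = NULL, unmapped = 0) {
  new("ReadSet", chrom = as.character(chrom), pos = as.numeric(pos),
      fragment = if (is.null(fragment)) integer(0) else as.integer(fragment),
      unmapped = as.numeric(unmapped))
}

#' @rdname GenomeModel-class
#' @param x a GenomeModel
#' @export
chromNames <- function(x) x@chrom

#' @rdname GenomeModel-class
#' @export
chromLengths <- function(x) stats::setNames(x@length, x@chrom)

#' @rdname GenomeModel-class
#' @export
centromerePositions <- function(x) stats::setNames(x@centromere, x@chrom)

#' @rdname GenomeModel-class
#' @export
sexMode <- function(x) x@sexMode

#' @rdname WindowGrid-class
#' @param x a WindowGrid
#' @export
windowRanges <- function(x) x@windows

#' @rdname WindowGrid-class
#' @export
windowSize <- function(x) x@windowSize

#' @rdname WindowGrid-class
#' @export
windowMask <- function(x) GenomicRanges::mcols(x@windows)$mask

#' @rdname WindowGrid-class
#' @export
windowArms <- function(x)
  paste0(as.character(GenomicRanges::seqnames(x@windows)),
         GenomicRanges::mcols(x@windows)$arm)

#' @rdname WindowGrid-class
#' @export
nWindows <- function(x) length(x@windows)

#' @rdname WindowGrid-class
#' @export
gridGenome <- function(x) x@genome

# Window coordinates as a plain 0-based data.frame (internal convenience).
windowTable <- function(grid) {
  w <- grid@windows
  data.frame(chrom = as.character(GenomicRanges::seqnames(w)),
             start = GenomicRanges::start(w) - 1,
             end = GenomicRanges::end(w),
             arm = GenomicRanges::mcols(w)$arm,
             mask = GenomicRanges::mcols(w)$mask,
             stringsAsFactors = FALSE)
}

#' @rdname ReadSet-class
#' @param x a ReadSet
#' @export
mappedCount <- function(x) length(x@pos)

#' @rdname ReadSet-class
#' @export
unmappedCount <- function(x) x@unmapped

#' @rdname ReadSet-class
#' @export
hasFragmentIds <- function(x) length(x@fragment) > 0L

#' @rdname ReadSet-class
#' @export
readPositions <- function(x) {
  data.frame(chrom = x@chrom, pos = x@pos,
             fragment = if (hasFragmentIds(x)) x@fragment else NA_integer_,
             stringsAsFactors = FALSE)
}

#' @rdname FragmentLibrary-class
#' @param x a FragmentLibrary
#' @export
nFragments <- function(x) length(x@chrom)

#' @rdname FragmentLibrary-class
#' @export
fragmentRanges <- function(x) {
  GenomicRanges::GRanges(x@chrom, IRanges::IRanges(x@start + 1, x@end),
                         weight = x@weight, dropped = x@dropped)
}

#' @rdname FragmentLibrary-class
#' @export
qcLoci <- function(x) x@qcLoci

#' @rdname FragmentLibrary-class
#' @export
giiBands <- function(x) x@giiBands

#' @rdname BinCounts-class
#' @param x a BinCounts
#' @export
binCounts <- function(x) x@counts

#' @rdname BinCounts-class
#' @export
droppedReads <- function(x) x@dropped

#' @rdname BinCounts-class
#' @export
binGrid <- function(x) x@grid

#' @rdname CopyNumberProfile-class
#' @param x a CopyNumberProfile
#' @export
windowCN <- function(x) x@cn

#' @rdname CopyNumberProfile-class
#' @export
cnvSegments <- function(x) x@segments

#' @rdname CopyNumberProfile-class
#' @export
profileGrid <- function(x) x@bins@grid

#' Per-window integer copy number inherited from the covering segment
#'
#' @param x a CopyNumberProfile
#' @return integer vector aligned to the grid windows (NA for masked windows).
#' @export
windowIntegerCN <- function(x) {
  out <- rep(NA_integer_, length(x@windowSegment))
  ok <- !is.na(x@windowSegment)
  out[ok] <- x@segments$cn[x@windowSegment[ok]]
  out
}

#' @rdname QCReport-class
#' @param x a QCReport
#' @export
qcGates <- function(x) x@gates

#' @rdname QCReport-class
#' @export
qcKeep <- function(x) x@keep

#' First failing gate of a QC report (NA when the cell is kept)
#' @param x a QCReport
#' @export
firstFailingGate <- function(x) {
  g <- x@gates
  bad <- which(g$applicable & !is.na(g$passed) & !g$passed)
  if (length(bad)) g$gate[bad[1]] else NA_character_
}

#' @rdname CohortSummary-class
#' @param x a CohortSummary
#' @export
cohortCells <- function(x) x@cells

setMethod("show", "GenomeModel", function(object) {
  cat(sprintf("GenomeModel (%s): %d chromosomes, %.2f Gb\n",
              object@sexMode, length(object@chrom), sum(object@length) / 1e9))
})

setMethod("show", "WindowGrid", function(object) {
  cat(sprintf("WindowGrid: %d windows of %s bp over %d chromosomes (%d masked)\n",
              length(object@windows), format(object@windowSize, big.mark = ","),
              length(object@genome@chrom), sum(windowMask(object))))
})

setMethod("show", "ReadSet", function(object) {
  cat(sprintf("ReadSet: %d mapped, %d unmapped%s\n",
              mappedCount(object), object@unmapped,
              if (hasFragmentIds(object)) ", fragment ids present" else ""))
})

setMethod("show", "FragmentLibrary", function(object) {
  cat(sprintf("FragmentLibrary: %d fragments, %d dropped%s\n",
              nFragments(object), sum(object@dropped),
              if (length(object@giiBands))
                sprintf(", GII bands %s", paste(as.integer(object@giiBands), collapse = ""))
              else " (pre-WGA)"))
})

setMethod("show", "SyntheticCell", function(object) {
  cat(sprintf("SyntheticCell (seed %s): %d mapped / %d unmapped reads, GII %d\n",
              format(object@seed), mappedCount(object@reads),
              unmappedCount(object@reads),
              sum(object@library@giiBands)))
})

setMethod("show", "QCReport", function(object) {
  cat(sprintf("QCReport: mapped=%d GII=%d DLRS=%s R50=%s -> %s\n",
              object@mappedReads, object@gii,
              ifelse(is.na(object@dlrs), "NA", sprintf("%.3f", object@dlrs)),
              ifelse(is.na(object@r50), "NA", sprintf("%.2f", object@r50)),
              if (object@keep) "keep" else
                sprintf("discard (%s)", firstFailingGate(object))))
})

setMethod("show", "CopyNumberProfile", function(object) {
  st <- table(factor(object@segments$state, c("loss", "neutral", "gain")))
  cat(sprintf("CopyNumberProfile: %d windows, %d segments (%d loss / %d neutral / %d gain), ploidy %d\n",
              length(object@cn), nrow(object@segments),
              st[["loss"]], st[["neutral"]], st[["gain"]], object@ploidy))
})

setMethod("show", "CohortSummary", function(object) {
  cat(sprintf("CohortSummary: %d cells, %d kept, %d discarded\n",
              nrow(object@cells), sum(object@cells$keep),
              sum(!object@cells$keep)))
})
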