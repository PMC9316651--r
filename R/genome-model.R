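#' Construct a genome model
#'
#' @param chrom chromosome names, in genome order.
#' @param length chromosome lengths in base pairs.
#' @param centromere centromere positions (0-based, strictly inside the
#'   chromosome). Positions at or beyond the centromere belong to the q arm.
#' @param sexMode \code{"female"} (no Y) or \code{"male"}.
#' @return a \linkS4class{GenomeModel}.
#' @examples
#' g <- GenomeModel(c("chr1", "chr2"), c(5e6, 3e6), c(2e6, 1e6))
#' chromNames(g)
#' @export
GenomeModel <- function(chrom, length, centromere, sexMode = "female") {
  new("GenomeModel", chrom = as.character(chrom), length = as.numeric(length),
      centromere = as.numeric(centromere), sexMode = sexMode)
}

#' Built-in hg19-like human genome model
#'
#' Primary chromosomes with hg19 lengths and approximate centromere midpoints
#' (shipped as plain-text tables). The female model exposes exactly 23
#' chromosomes (22 autosomes + X); the male model adds Y.
#'
#' @param sex \code{"female"} (default) or \code{"male"}.
#' @return a \linkS4class{GenomeModel}.
#' @examples
#' length(chromNames(hg19GenomeModel()))  # 23
#' @export
hg19GenomeModel <- function(sex = c("female", "male")) {
  sex <- match.arg(sex)
  sizes <- utils::read.table(
    system.file("extdata", "hg19_chrom_sizes.tsv", package = "sclpCNV"),
    header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  cents <- utils::read.table(
    system.file("extdata", "hg19_centromeres.tsv", package = "sclpCNV"),
    header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (sex == "female") sizes <- sizes[sizes$chrom != "chrY", ]
  cent <- cents$centromere[match(sizes$chrom, cents$chrom)]
  GenomeModel(sizes$chrom, sizes$length, cent, sexMode = sex)
}

#' Read a genome model from chrom-sizes and centromere tables
#'
#' @param sizesPath two-column table (chrom, length) with header.
#' @param centromerePath two-column table (chrom, centromere) with header.
#' @param sexMode passed to \code{\link{GenomeModel}}.
#' @export
readGenomeModel <- function(sizesPath, centromerePath, sexMode = "female") {
  sizes <- utils::read.table(sizesPath, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  cents <- utils::read.table(centromerePath, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  cent <- cents[[2]][match(sizes[[1]], cents[[1]])]
  if (anyNA(cent)) stop("centromere table missing chromosomes: ",
                        paste(sizes[[1]][is.na(cent)], collapse = ", "))
  GenomeModel(sizes[[1]], sizes[[2]], cent, sexMode = sexMode)
}

#' Tile a genome model with fixed-size windows
#'
#' Each chromosome is tiled left to right with \code{windowSize}-bp windows;
#' the terminal window of a chromosome may be shorter. Every window is
#' assigned the arm (p/q) containing its midpoint, so each window maps to
#' exactly one arm. The mask starts all-FALSE; see
#' \code{\link{applyExclusions}}.
#'
#' @param genome a \linkS4class{GenomeModel}.
#' @param windowSize window width in base pairs (default 1 Mbp).
#' @return a \linkS4class{WindowGrid}.
#' @examples
#' g <- GenomeModel("chr1", 2.5e6, 1.2e6)
#' nWindows(buildWindowGrid(g, 1e6))  # 3
#' @export
buildWindowGrid <- function(genome, windowSize = 1e6) {
  if (!is.numeric(windowSize) || length(windowSize) != 1L || windowSize < 1)
    stop("windowSize must be a single value >= 1")
  windowSize <- floor(windowSize)
  per <- lapply(seq_along(genome@chrom), function(i) {
    len <- genome@length[i]
    n <- ceiling(len / windowSize)
    start0 <- (seq_len(n) - 1) * windowSize
    end0 <- pmin(start0 + windowSize, len)
    mid <- (start0 + end0) / 2
    list(chrom = rep(genome@chrom[i], n), start0 = start0, end0 = end0,
         arm = ifelse(mid < genome@centromere[i], "p", "q"))
  })
  gr <- GenomicRanges::GRanges(
    unlist(lapply(per, `[[`, "chrom")),
    IRanges::IRanges(unlist(lapply(per, `[[`, "start0")) + 1,
                     unlist(lapply(per, `[[`, "end0"))),
    arm = unlist(lapply(per, `[[`, "arm")),
    mask = FALSE)
  new("WindowGrid", windows = gr, windowSize = windowSize, genome = genome)
}

#' Mask windows overlapping a blacklist of low-quality regions
#'
#' A window becomes masked when the fraction of its bases covered by the
#' blacklist exceeds \code{threshold}. Masked windows are excluded from read
#' binning, copy-number estimation and DLRS. Blacklist intervals on
#' chromosomes absent from the grid are ignored with a warning.
#'
#' @param grid a \linkS4class{WindowGrid}.
#' @param blacklist a \code{GRanges}, or a data.frame with columns
#'   chrom/start/end (0-based half-open, BED-compatible), or a BED file path.
#' @param threshold overlap fraction above which a window is masked
#'   (default 0.5).
#' @return the grid with an updated mask (existing masking is retained).
#' @export
applyExclusions <- function(grid, blacklist, threshold = 0.5) {
  bl <- asIntervalGRanges(blacklist)
  known <- as.character(GenomicRanges::seqnames(bl)) %in% grid@genome@chrom
  if (any(!known)) {
    warning("ignoring ", sum(!known),
            " blacklist interval(s) on chromosomes absent from the genome model")
    bl <- bl[known]
  }
  if (length(bl)) {
    bl <- GenomicRanges::reduce(bl)
    hits <- GenomicRanges::findOverlaps(grid@windows, bl)
    if (length(hits)) {
      ov <- GenomicRanges::width(GenomicRanges::pintersect(
        grid@windows[S4Vectors::queryHits(hits)], bl[S4Vectors::subjectHits(hits)]))
      cov <- tapply(ov, S4Vectors::queryHits(hits), sum)
      idx <- as.integer(names(cov))
      frac <- as.numeric(cov) / GenomicRanges::width(grid@windows[idx])
      mask <- GenomicRanges::mcols(grid@windows)$mask
      mask[idx[frac > threshold]] <- TRUE
      GenomicRanges::mcols(grid@windows)$mask <- mask
    }
  }
  grid
}

# Coerce BED path / data.frame (0-based half-open) / GRanges to GRanges.
asIntervalGRanges <- function(x) {
  if (methods::is(x, "GRanges")) return(x)
  if (is.character(x) && length(x) == 1L) x <- readBed(x)
  if (is.data.frame(x)) {
    if (!nrow(x)) return(GenomicRanges::GRanges())
    gr <- GenomicRanges::GRanges(x[[1]], IRanges::IRanges(x[[2]] + 1, x[[3]]))
    if (ncol(x) >= 4) GenomicRanges::mcols(gr)$name <- x[[4]]
    return(gr)
  }
  stop("cannot interpret intervals of class ", class(x)[1])
}

#' Read a BED file (3+ columns, 0-based half-open)
#'
#' @param path BED file path; column 4, when present, is kept as \code{name}.
#' @return a data.frame with columns chrom, start, end (0-based half-open)
#'   and optionally name.
#' @export
readBed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- utils::read.table(path, header = FALSE, sep = "\t",
                         stringsAsFactors = FALSE,
                         col.names = c("chrom", "start", "end", "name",
                                       "score", "strand")[1:max(3, countBedCols(path))],
                         fill = TRUE)
  x[seq_len(min(ncol(x), 4))]
}

countBedCols <- function(path) {
  first <- readLines(path, n = 1L)
  if (!length(first)) return(3L)
  length(strsplit(first, "\t", fixed = TRUE)[[1]])
}

#' Read a 4-column gene annotation BED (chrom, start, end, symbol)
#'
#' @param path BED file path.
#' @return data.frame with columns chrom, start, end, gene.
#' @export
readGeneBed <- function(path) {
  x <- readBed(path)
  if (ncol(x) < 4) stop("gene annotation BED needs a 4th (symbol) column")
  names(x)[4] <- "gene"
  if (anyDuplicated(x$gene)) stop("gene symbols must be unique")
  x
}

#' Locate the window containing a genomic position
#'
#' @param grid a \linkS4class{WindowGrid}.
#' @param chrom chromosome name(s).
#' @param pos 0-based position(s).
#' @return integer window index (1-based, global over the grid), or NA for
#'   chromosomes absent from the model (e.g. alternative contigs) or positions
#'   beyond the chromosome end.
#' @examples
#' g <- GenomeModel("chr1", 2.5e6, 1.2e6)
#' grid <- buildWindowGrid(g, 1e6)
#' locateWindow(grid, "chr1", 1e6)  # 2: half-open windows
#' @export
locateWindow <- function(grid, chrom, pos) {
  stopIfNot0Based(pos)
  chrom <- as.character(chrom)
  g <- grid@genome
  nwin <- ceiling(g@length / grid@windowSize)
  offset <- c(0, cumsum(nwin))[seq_along(nwin)]
  ci <- match(chrom, g@chrom)
  idx <- rep(NA_integer_, length(pos))
  ok <- !is.na(ci) & pos < g@length[ifelse(is.na(ci), 1L, ci)]
  idx[ok] <- as.integer(offset[ci[ok]] + pos[ok] %/% grid@windowSize + 1)
  idx
}

#' Chromosome arm of a position
#'
#' Positions strictly left of the centromere are on the p arm; the centromere
#' position itself and everything right of it is q (half-open arms).
#'
#' @param genome a \linkS4class{GenomeModel}.
#' @param chrom chromosome name(s).
#' @param pos 0-based position(s) within the chromosome.
#' @return character vector of "p"/"q".
#' @export
armOf <- function(genome, chrom, pos) {
  ci <- match(as.character(chrom), genome@chrom)
  if (anyNA(ci)) stop("unknown chromosome(s): ",
                      paste(unique(chrom[is.na(ci)]), collapse = ", "))
  stopIfNot0Based(pos)
  if (any(pos >= genome@length[ci])) stop("position beyond chromosome end")
  ifelse(pos < genome@centromere[ci], "p", "q")
}
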