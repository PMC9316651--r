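# Synthetic single-cell WGA libraries: ground-truth CN events, a
# restriction-fragment library, lognormal amplification bias with fragment
# dropout (driving the GII), and unmapped-read contamination. All generators
# are pure functions of (parameters, seed).

#' Simulate a ground-truth copy-number profile
#'
#' Baseline ploidy everywhere, overridden by non-overlapping events. The
#' canonical tumor scenario combines an arm-level gain, an arm-level loss and
#' a focal amplicon (see \code{\link{armEvent}} and
#' \code{\link{patientScenarioEvents}}).
#'
#' @param genome a \linkS4class{GenomeModel}.
#' @param events NULL (no events), or a data.frame with columns
#'   chrom, start, end (0-based half-open) and cn (integer >= 0).
#' @param ploidy baseline integer copy number (default 2).
#' @param seed optional seed (the operation is deterministic; accepted for
#'   API symmetry with the other generators).
#' @return a \linkS4class{TruthProfile}.
#' @export
simulateTruthProfile <- function(genome, events = NULL, ploidy = 2, seed = NULL) {
  ev <- if (is.null(events) || (is.data.frame(events) && !nrow(events))) {
    GenomicRanges::GRanges()
  } else {
    if (!all(c("chrom", "start", "end", "cn") %in% names(events)))
      stop("events need columns chrom, start, end, cn")
    GenomicRanges::GRanges(events$chrom,
                           IRanges::IRanges(events$start + 1, events$end),
                           cn = as.integer(events$cn))
  }
  new("TruthProfile", genome = genome, ploidy = as.integer(ploidy), events = ev)
}

#' Whole-arm event helper
#'
#' @param genome a \linkS4class{GenomeModel}.
#' @param chrom chromosome name.
#' @param arm "p" or "q".
#' @param cn integer copy number of the event.
#' @return one-row event data.frame spanning the full arm.
#' @export
armEvent <- function(genome, chrom, arm = c("q", "p"), cn) {
  arm <- match.arg(arm)
  i <- match(chrom, genome@chrom)
  if (is.na(i)) stop("unknown chromosome: ", chrom)
  if (arm == "p")
    data.frame(chrom = chrom, start = 0, end = genome@centromere[i], cn = cn)
  else
    data.frame(chrom = chrom, start = genome@centromere[i],
               end = genome@length[i], cn = cn)
}

#' Canonical patient-like CTC event set: 1q gain, 5q loss, focal 8q amplicon
#'
#' The arm-level 1q gain (CN 3) and 5q loss (CN 1) mirror the alterations
#' reported for a metastatic pancreatic-cancer CTC; the 2 Mbp CN-6 amplicon on
#' 8q emulates a Myc-like focal amplification.
#'
#' @param genome a \linkS4class{GenomeModel} containing chr1, chr5 and chr8.
#' @return event data.frame for \code{\link{simulateTruthProfile}}.
#' @export
patientScenarioEvents <- function(genome) {
  ampStart <- genome@centromere[match("chr8", genome@chrom)] + 8e7
  rbind(armEvent(genome, "chr1", "q", 3),
        armEvent(genome, "chr5", "q", 1),
        data.frame(chrom = "chr8", start = ampStart, end = ampStart + 2e6, cn = 6))
}

#' Truth copy number at positions
#'
#' @param truth a \linkS4class{TruthProfile}.
#' @param chrom,pos parallel chromosome / 0-based position vectors.
#' @return integer copy number at each position.
#' @export
truthCNAt <- function(truth, chrom, pos) {
  cn <- rep(truth@ploidy, length(pos))
  ev <- truth@events
  if (length(ev)) {
    evc <- as.character(GenomicRanges::seqnames(ev))
    s0 <- GenomicRanges::start(ev) - 1
    e0 <- GenomicRanges::end(ev)
    evcn <- GenomicRanges::mcols(ev)$cn
    for (k in seq_along(ev)) {
      sel <- chrom == evc[k] & pos >= s0[k] & pos < e0[k]
      cn[sel] <- evcn[k]
    }
  }
  cn
}

#' Per-window truth copy number under the plurality-overlap rule
#'
#' A window takes the copy number covering the plurality of its bases; the
#' baseline-ploidy residual competes like an event, and exact ties go to the
#' ploidy.
#'
#' @param truth a \linkS4class{TruthProfile}.
#' @param grid a \linkS4class{WindowGrid} on the same genome.
#' @return integer vector of truth CN aligned to the grid windows.
#' @export
truthWindowCN <- function(truth, grid) {
  w <- grid@windows
  cn <- rep(truth@ploidy, length(w))
  ev <- truth@events
  if (!length(ev)) return(cn)
  hits <- GenomicRanges::findOverlaps(w, ev)
  if (!length(hits)) return(cn)
  ov <- GenomicRanges::width(GenomicRanges::pintersect(
    w[S4Vectors::queryHits(hits)], ev[S4Vectors::subjectHits(hits)]))
  evcn <- GenomicRanges::mcols(ev)$cn[S4Vectors::subjectHits(hits)]
  ww <- GenomicRanges::width(w)[S4Vectors::queryHits(hits)]
  for (q in unique(S4Vectors::queryHits(hits))) {
    sel <- S4Vectors::queryHits(hits) == q
    covs <- ov[sel]
    resid <- ww[sel][1] - sum(covs)  # bases still at baseline ploidy
    best <- which.max(covs)
    if (covs[best] > resid) cn[q] <- evcn[sel][best]
  }
  cn
}

#' Simulate an amplification-fragment library
#'
#' Chromosomes are partitioned into contiguous fragments with geometric
#' lengths around \code{meanFragmentLen} (a restriction-digest proxy), every
#' base covered exactly once. Four fragments are designated diagnostic QC
#' loci — one on each of the first four chromosomes when the genome has at
#' least four, otherwise four distinct random fragments.
#'
#' @param genome a \linkS4class{GenomeModel}.
#' @param meanFragmentLen mean fragment length in bp (>= 50; default 10,000,
#'   which keeps a human-scale library around 3e5 fragments with roughly 100
#'   fragments per 1 Mbp window).
#' @param seed optional seed.
#' @return a pre-WGA \linkS4class{FragmentLibrary} (unit weights, no dropout).
#' @export
simulateFragmentLibrary <- function(genome, meanFragmentLen = 1e4, seed = NULL)
  withSeed(seed, {
    if (meanFragmentLen < 50) stop("meanFragmentLen must be >= 50")
    cl <- vector("list", length(genome@chrom))
    sl <- el <- cl
    for (i in seq_along(genome@chrom)) {
      len <- genome@length[i]
      lens <- numeric(0)
      repeat {
        need <- ceiling((len - sum(lens)) / meanFragmentLen * 1.2) + 10
        lens <- c(lens, stats::rgeom(need, 1 / meanFragmentLen) + 1)
        if (sum(lens) >= len) break
      }
      ends <- cumsum(lens)
      k <- which(ends >= len)[1]
      ends <- ends[seq_len(k)]
      ends[k] <- len
      sl[[i]] <- c(0, ends[-k])
      el[[i]] <- ends
      cl[[i]] <- rep(genome@chrom[i], k)
    }
    chrom <- unlist(cl)
    nf <- length(chrom)
    if (nf < 4L) stop("genome too small: fewer than 4 fragments")
    nchr <- length(genome@chrom)
    loci <- if (nchr >= 4L) {
      vapply(genome@chrom[1:4], function(cc) {
        idx <- which(chrom == cc)
        idx[sample.int(length(idx), 1L)]
      }, integer(1))
    } else sample.int(nf, 4L)
    new("FragmentLibrary", chrom = chrom, start = unlist(sl), end = unlist(el),
        weight = rep(1, nf), dropped = rep(FALSE, nf),
        qcLoci = as.integer(unname(loci)), giiBands = logical(0))
  })

#' Apply whole-genome-amplification bias to a fragment library
#'
#' Each fragment is independently dropped with probability
#' \code{dropoutRate}; a retained fragment's weight is the local truth copy
#' number (at the fragment midpoint) times a lognormal amplification
#' efficiency \code{exp(N(0, amplificationSd^2))}. The presence of the four
#' QC bands — hence the GII — is the not-dropped status of the QC loci.
#'
#' @param library a pre-WGA \linkS4class{FragmentLibrary}.
#' @param truth a \linkS4class{TruthProfile}.
#' @param dropoutRate fragment dropout probability in [0, 1).
#' @param amplificationSd sd of the lognormal log-efficiency (>= 0).
#' @param seed optional seed.
#' @return the library with weights, dropout flags and GII bands filled in.
#' @export
simulateWGA <- function(library, truth, dropoutRate = 0.1,
                        amplificationSd = 0.3, seed = NULL)
  withSeed(seed, {
    if (dropoutRate < 0 || dropoutRate >= 1) stop("dropoutRate must be in [0, 1)")
    if (amplificationSd < 0) stop("amplificationSd must be >= 0")
    nf <- nFragments(library)
    dropped <- stats::runif(nf) < dropoutRate
    mid <- floor((library@start + library@end) / 2)
    cn <- truthCNAt(truth, library@chrom, mid)
    eff <- exp(stats::rnorm(nf, 0, amplificationSd))
    w <- cn * eff
    w[dropped] <- 0
    library@weight <- w
    library@dropped <- dropped
    library@giiBands <- !dropped[library@qcLoci]
    library
  })

#' Draw reads from a weighted fragment library
#'
#' The number of unmapped (contaminating) reads is binomial in
#' \code{contaminationFrac}; the remaining reads are drawn multinomially over
#' fragments proportional to template mass — amplification weight times
#' fragment length — with positions uniform within the fragment, so in the
#' noiseless limit the read density of a region is exactly proportional to
#' its copy number. Fragment-of-origin labels are retained for R50.
#'
#' @param library a post-WGA \linkS4class{FragmentLibrary}.
#' @param nReads total reads sequenced (> 0).
#' @param contaminationFrac share of reads that fail to map, in [0, 1).
#' @param seed optional seed.
#' @return a \linkS4class{ReadSet}.
#' @export
simulateReads <- function(library, nReads, contaminationFrac = 0, seed = NULL)
  withSeed(seed, {
    if (nReads <= 0) stop("nReads must be > 0")
    if (contaminationFrac < 0 || contaminationFrac >= 1)
      stop("contaminationFrac must be in [0, 1)")
    w <- library@weight
    if (all(w <= 0))
      stop("all fragment weights are zero: no mapped reads can be generated")
    nUnmapped <- if (contaminationFrac > 0)
      stats::rbinom(1L, nReads, contaminationFrac) else 0L
    nMapped <- nReads - nUnmapped
    if (nMapped > 0) {
      counts <- as.vector(stats::rmultinom(1L, nMapped,
                                           w * (library@end - library@start)))
      idx <- rep.int(seq_along(counts), counts)
      flen <- library@end[idx] - library@start[idx]
      pos <- library@start[idx] + floor(stats::runif(length(idx)) * flen)
      pos <- pmin(pos, library@end[idx] - 1)
    } else {
      idx <- integer(0)
      pos <- numeric(0)
    }
    new("ReadSet", chrom = library@chrom[idx], pos = pos,
        fragment = as.integer(idx), unmapped = as.numeric(nUnmapped))
  })

#' Simulate one complete synthetic cell
#'
#' Chains truth profile, fragment library, WGA bias and read generation under
#' one seed, so the whole cell is reproducible from (parameters, seed).
#'
#' @param genome a \linkS4class{GenomeModel}.
#' @param events event data.frame (see \code{\link{simulateTruthProfile}}).
#' @param ploidy baseline copy number (default 2).
#' @param nReads total reads (default 500,000).
#' @param meanFragmentLen mean amplification-fragment length (default 10 kb).
#' @param dropoutRate fragment dropout probability (default 0.1).
#' @param amplificationSd lognormal amplification-bias sd (default 0.3).
#' @param contaminationFrac unmapped-read share (default 0).
#' @param seed optional driving seed.
#' @return a \linkS4class{SyntheticCell}.
#' @examples
#' g <- GenomeModel(paste0("chr", 1:3), rep(1e7, 3), rep(5e6, 3))
#' cell <- simulateCell(g, nReads = 1e4, seed = 1)
#' mappedCount(cell@reads) + unmappedCount(cell@reads)  # 10000
#' @export
simulateCell <- function(genome, events = NULL, ploidy = 2, nReads = 5e5,
                         meanFragmentLen = 1e4, dropoutRate = 0.1,
                         amplificationSd = 0.3, contaminationFrac = 0,
                         seed = NULL)
  withSeed(seed, {
    truth <- simulateTruthProfile(genome, events, ploidy = ploidy)
    lib <- simulateFragmentLibrary(genome, meanFragmentLen)
    lib <- simulateWGA(lib, truth, dropoutRate, amplificationSd)
    reads <- simulateReads(lib, nReads, contaminationFrac)
    new("SyntheticCell", truth = truth, library = lib, reads = reads,
        seed = if (is.null(seed)) NA_real_ else as.numeric(seed),
        params = list(ploidy = ploidy, nReads = nReads,
                      meanFragmentLen = meanFragmentLen,
                      dropoutRate = dropoutRate,
                      amplificationSd = amplificationSd,
                      contaminationFrac = contaminationFrac))
  })

#' Write a synthetic cell as plain-text fixture files
#'
#' Emits the read positions (TSV or minimal single-end SAM), truth copy
#' number per window, GII band presence (JSON) and the parameter record
#' (YAML). The files round-trip through \code{\link{readReads}}.
#'
#' @param cell a \linkS4class{SyntheticCell}.
#' @param dir output directory (created if missing).
#' @param format "tsv" (positions table + sidecar unmapped count) or "sam".
#' @param grid optional \linkS4class{WindowGrid} for the truth track
#'   (default: 1 Mbp grid on the cell's genome).
#' @param prefix file-name prefix (default "cell").
#' @return invisibly, the named vector of files written.
#' @export
writeFixture <- function(cell, dir, format = c("tsv", "sam"),
                         grid = NULL, prefix = "cell") {
  format <- match.arg(format)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (is.null(grid)) grid <- buildWindowGrid(cell@truth@genome, 1e6)
  files <- c()
  if (format == "tsv") {
    readsPath <- file.path(dir, paste0(prefix, "_reads.tsv"))
    writeReadsTsv(cell@reads, readsPath)
    files["reads"] <- readsPath
  } else {
    readsPath <- file.path(dir, paste0(prefix, "_reads.sam"))
    writeReadsSam(cell@reads, cell@truth@genome, readsPath)
    files["reads"] <- readsPath
  }
  truthPath <- file.path(dir, paste0(prefix, "_truth_windows.tsv"))
  wt <- windowTable(grid)
  wt$cn <- truthWindowCN(cell@truth, grid)
  utils::write.table(wt[c("chrom", "start", "end", "cn")], truthPath,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  files["truth"] <- truthPath
  giiPath <- file.path(dir, paste0(prefix, "_gii.json"))
  jsonlite::write_json(list(bands = cell@library@giiBands,
                            gii = sum(cell@library@giiBands)),
                       giiPath, auto_unbox = TRUE)
  files["gii"] <- giiPath
  paramsPath <- file.path(dir, paste0(prefix, "_params.yaml"))
  yaml::write_yaml(c(cell@params, list(seed = cell@seed)), paramsPath)
  files["params"] <- paramsPath
  invisible(files)
}
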