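# Pipeline orchestration and file I/O: read-position readers/writers (SAM,
# BAM, positions TSV), run configuration, per-cell outputs, cohort summary.

#' Read mapped reads from SAM, BAM or a positions TSV
#'
#' SAM/BAM: 1-based positions are converted to the package's 0-based
#' convention; secondary and supplementary alignments are excluded; unmapped
#' records are counted but not positioned; an integer \code{XF} tag, when
#' present on every mapped record, is taken as the fragment-of-origin label.
#' TSV: tab-separated with header \code{chrom, pos, fragment} (pos 0-based,
#' fragment optional); a sidecar file \code{<path>.unmapped} holding one
#' integer supplies the unmapped count. An empty file yields an empty ReadSet.
#'
#' @param path input file.
#' @param mode "auto" (by extension), "sam", "bam" or "tsv".
#' @return a \linkS4class{ReadSet}.
#' @export
readReads <- function(path, mode = c("auto", "sam", "bam", "tsv")) {
  mode <- match.arg(mode)
  if (!file.exists(path)) stop("no such file: ", path)
  if (mode == "auto") {
    ext <- tolower(tools::file_ext(path))
    mode <- if (ext == "sam") "sam" else if (ext == "bam") "bam" else "tsv"
  }
  if (mode == "tsv") return(readReadsTsv(path))
  bam <- if (mode == "sam") {
    dest <- tempfile(fileext = "")
    tryCatch(Rsamtools::asBam(path, dest, overwrite = TRUE,
                              indexDestination = FALSE),
             error = function(e) stop("malformed SAM '", path, "': ",
                                      conditionMessage(e)))
  } else path
  param <- Rsamtools::ScanBamParam(
    what = c("rname", "pos", "flag"), tag = "XF",
    flag = Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE))
  rec <- Rsamtools::scanBam(bam, param = param)[[1]]
  unmapped <- bitwAnd(rec$flag, 4L) != 0L
  chrom <- as.character(rec$rname)[!unmapped]
  pos <- rec$pos[!unmapped] - 1
  frag <- rec$tag$XF
  frag <- if (!is.null(frag) && !anyNA(frag[!unmapped]))
    as.integer(frag[!unmapped]) else integer(0)
  new("ReadSet", chrom = chrom, pos = as.numeric(pos), fragment = frag,
      unmapped = as.numeric(sum(unmapped)))
}

readReadsTsv <- function(path) {
  unmappedPath <- paste0(path, ".unmapped")
  unmapped <- if (file.exists(unmappedPath))
    as.numeric(readLines(unmappedPath, n = 1L)) else 0
  if (file.size(path) == 0)
    return(new("ReadSet", chrom = character(0), pos = numeric(0),
               fragment = integer(0), unmapped = unmapped))
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  if (!all(c("chrom", "pos") %in% names(x)))
    stop("positions TSV needs columns 'chrom' and 'pos': ", path)
  frag <- if ("fragment" %in% names(x) && !anyNA(x$fragment))
    as.integer(x$fragment) else integer(0)
  new("ReadSet", chrom = as.character(x$chrom), pos = as.numeric(x$pos),
      fragment = frag, unmapped = unmapped)
}

#' Write a ReadSet as a positions TSV with sidecar unmapped count
#'
#' @param reads a \linkS4class{ReadSet}.
#' @param path output TSV path; the unmapped tally goes to
#'   \code{<path>.unmapped}.
#' @export
writeReadsTsv <- function(reads, path) {
  df <- data.frame(chrom = reads@chrom, pos = reads@pos)
  if (hasFragmentIds(reads)) df$fragment <- reads@fragment
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(as.character(unmappedCount(reads)), paste0(path, ".unmapped"))
  invisible(path)
}

#' Write a ReadSet as a minimal single-end SAM file
#'
#' Mapped records get FLAG 0, MAPQ 60, a nominal 150M CIGAR (the binning
#' model is insensitive to read length) and the fragment id as an \code{XF}
#' tag; unmapped records get FLAG 4. Positions are emitted 1-based per the
#' SAM convention.
#'
#' @param reads a \linkS4class{ReadSet}.
#' @param genome the \linkS4class{GenomeModel} supplying the header.
#' @param path output SAM path.
#' @export
writeReadsSam <- function(reads, genome, path) {
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", genome@chrom,
                      as.integer(genome@length)))
  n <- mappedCount(reads)
  mappedLines <- if (n) {
    tag <- if (hasFragmentIds(reads))
      sprintf("\tXF:i:%d", reads@fragment) else ""
    sprintf("r%06d\t0\t%s\t%d\t60\t150M\t*\t0\t0\t*\t*%s",
            seq_len(n), reads@chrom, as.integer(reads@pos + 1), tag)
  } else character(0)
  nu <- unmappedCount(reads)
  unmappedLines <- if (nu > 0)
    sprintf("u%06d\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*", seq_len(nu))
  else character(0)
  writeLines(c(header, mappedLines, unmappedLines), path)
  invisible(path)
}

#' Read / write a pipeline run configuration (YAML)
#'
#' A run configuration holds the genome source, window size, ploidy, QC
#' thresholds, seed and output directory. It round-trips through YAML
#' unchanged.
#'
#' @param path YAML file.
#' @return the validated configuration list.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  validateRunConfig(cfg)
}

#' @rdname readRunConfig
#' @param cfg configuration list (see \code{\link{defaultRunConfig}}).
#' @export
writeRunConfig <- function(cfg, path) {
  yaml::write_yaml(validateRunConfig(cfg), path)
  invisible(path)
}

#' Default run configuration
#'
#' @param windowSize window size in bp.
#' @param ploidy baseline copy number.
#' @param seed run seed.
#' @param outDir output directory (NULL = in-memory run).
#' @export
defaultRunConfig <- function(windowSize = 1e6, ploidy = 2, seed = 1,
                             outDir = NULL) {
  list(genome = "hg19", sex = "female", windowSize = windowSize,
       ploidy = ploidy, thresholds = qcThresholds(), seed = seed,
       outDir = outDir)
}

validateRunConfig <- function(cfg) {
  need <- c("genome", "windowSize", "ploidy", "thresholds", "seed")
  miss <- setdiff(need, names(cfg))
  if (length(miss)) stop("run config missing fields: ",
                         paste(miss, collapse = ", "))
  if (cfg$windowSize < 1) stop("windowSize must be >= 1")
  th <- cfg$thresholds
  for (f in c("giiMin", "mappedMin", "dlrsMax"))
    if (is.null(th[[f]]) || th[[f]] <= 0)
      stop("threshold '", f, "' must be present and positive")
  cfg
}

#' Run the full pipeline over a cohort of cells
#'
#' For each cell: the QC battery is evaluated; only kept cells proceed to
#' copy-number calling; per-cell outputs and a cohort summary are written
#' when \code{outDir} is given. Failures are isolated per cell — one bad
#' input does not abort the cohort. The run is reproducible from
#' (inputs, thresholds, seed).
#'
#' @param cells named list; each element is a list with fields \code{reads}
#'   (a \linkS4class{ReadSet} or a file path for \code{\link{readReads}}) and
#'   \code{gii} (integer 0-4 or 4 band logicals).
#' @param grid a \linkS4class{WindowGrid}.
#' @param thresholds see \code{\link{qcThresholds}}.
#' @param ploidy baseline copy number (default 2).
#' @param outDir output directory (NULL = no files written).
#' @param seed run seed; per-cell subsampling seeds are derived from it.
#' @param genes optional gene annotation for per-cell gene calls.
#' @return a \linkS4class{CohortSummary}; kept cells' profiles are in
#'   attribute \code{profiles}.
#' @export
runPipeline <- function(cells, grid, thresholds = qcThresholds(), ploidy = 2,
                        outDir = NULL, seed = NULL, genes = NULL) {
  ids <- names(cells)
  if (is.null(ids)) ids <- sprintf("cell%02d", seq_along(cells))
  rows <- vector("list", length(cells))
  profiles <- list()
  outputs <- character(0)
  if (!is.null(outDir) && !dir.exists(outDir))
    dir.create(outDir, recursive = TRUE)
  for (i in seq_along(cells)) {
    id <- ids[i]
    row <- tryCatch({
      cell <- cells[[i]]
      reads <- if (is.character(cell$reads)) readReads(cell$reads)
               else cell$reads
      report <- evaluateCell(reads, grid, cell$gii, thresholds,
                             ploidy = ploidy, seed = childSeed(seed, i))
      if (report@keep) {
        prof <- callCNVProfile(reads, grid, ploidy = ploidy)
        profiles[[id]] <- prof
        if (!is.null(outDir))
          outputs <- c(outputs,
                       writeCellOutputs(prof, report, outDir, id, genes))
      } else if (!is.null(outDir)) {
        outputs <- c(outputs, writeQCReportJson(report, outDir, id))
      }
      data.frame(id = id, mappedReads = report@mappedReads,
                 gii = report@gii, dlrs = report@dlrs, r50 = report@r50,
                 keep = report@keep, firstFail = firstFailingGate(report),
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(id = id, mappedReads = NA_real_, gii = NA_integer_,
                 dlrs = NA_real_, r50 = NA_real_, keep = FALSE,
                 firstFail = paste0("error: ", conditionMessage(e)),
                 stringsAsFactors = FALSE)
    })
    rows[[i]] <- row
  }
  summary <- if (length(rows)) do.call(rbind, rows)
  else data.frame(id = character(0), mappedReads = numeric(0),
                  gii = integer(0), dlrs = numeric(0), r50 = numeric(0),
                  keep = logical(0), firstFail = character(0))
  if (!is.null(outDir)) {
    sumPath <- file.path(outDir, "cohort_summary.tsv")
    utils::write.table(summary, sumPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    logPath <- file.path(outDir, "run_log.txt")
    writeLines(c(
      sprintf("sclpCNV %s", as.character(utils::packageVersion("sclpCNV"))),
      sprintf("seed: %s", format(if (is.null(seed)) NA else seed)),
      sprintf("ploidy: %d", as.integer(ploidy)),
      sprintf("windowSize: %d", as.integer(windowSize(grid))),
      sprintf("threshold giiMin: %g", thresholds$giiMin),
      sprintf("threshold mappedMin: %g", thresholds$mappedMin),
      sprintf("threshold dlrsMax: %g", thresholds$dlrsMax),
      sprintf("threshold r50Min: %s", format(thresholds$r50Min)),
      sprintf("cells: %d kept: %d", nrow(summary), sum(summary$keep))),
      logPath)
    outputs <- c(outputs, sumPath, logPath)
  }
  res <- new("CohortSummary", cells = summary, thresholds = thresholds,
             outputs = outputs)
  attr(res, "profiles") <- profiles
  res
}

writeQCReportJson <- function(report, dir, id) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  path <- file.path(dir, sprintf("qc_%s.json", id))
  jsonlite::write_json(list(
    mappedReads = report@mappedReads, gii = report@gii,
    dlrs = report@dlrs, r50 = report@r50, keep = report@keep,
    firstFail = firstFailingGate(report), gates = report@gates),
    path, auto_unbox = TRUE, na = "null", digits = NA)
  path
}

#' Write per-cell profile and QC tables
#'
#' Emits the QC JSON, a per-window TSV (chrom, start, end, count, cn,
#' segmentCn, state), a BED-like segments TSV, arm calls, and (when a gene
#' annotation is given) gene-level calls. All files parse back through the
#' package's own readers.
#'
#' @param profile a \linkS4class{CopyNumberProfile}.
#' @param report the cell's \linkS4class{QCReport}.
#' @param dir output directory.
#' @param id cell identifier used in file names.
#' @param genes optional gene annotation data.frame.
#' @return the paths written.
#' @export
writeCellOutputs <- function(profile, report, dir, id, genes = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- writeQCReportJson(report, dir, id)
  wt <- windowTable(profile@bins@grid)
  wt$count <- profile@bins@counts
  wt$cn <- profile@cn
  segCN <- windowIntegerCN(profile)
  wt$segmentCn <- segCN
  st <- rep(NA_character_, nrow(wt))
  ok <- !is.na(profile@windowSegment)
  st[ok] <- profile@segments$state[profile@windowSegment[ok]]
  wt$state <- st
  winPath <- file.path(dir, sprintf("windows_%s.tsv", id))
  utils::write.table(wt[c("chrom", "start", "end", "count", "cn",
                          "segmentCn", "state")],
                     winPath, sep = "\t", quote = FALSE, row.names = FALSE)
  segPath <- file.path(dir, sprintf("segments_%s.tsv", id))
  utils::write.table(profile@segments, segPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  armPath <- file.path(dir, sprintf("arms_%s.tsv", id))
  utils::write.table(callArmEvents(profile), armPath, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths <- c(paths, winPath, segPath, armPath)
  if (!is.null(genes)) {
    genePath <- file.path(dir, sprintf("genes_%s.tsv", id))
    utils::write.table(annotateGenes(profile, genes), genePath, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    paths <- c(paths, genePath)
  }
  paths
}
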