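test_that("truth profiles place events under the plurality-overlap rule", {
  g <- toyGenome(n = 2, len = 1e7, cent = 5e6)
  grid <- buildWindowGrid(g, 1e6)

  # no events: all windows at the ploidy
  t0 <- simulateTruthProfile(g, NULL, ploidy = 2)
  expect_true(all(truthWindowCN(t0, grid) == 2L))

  # whole-q-arm gain: all q windows at 3, all p windows at 2
  t1 <- simulateTruthProfile(g, armEvent(g, "chr1", "q", 3))
  cn <- truthWindowCN(t1, grid)
  wt <- sclpCNV:::windowTable(grid)
  expect_true(all(cn[wt$chrom == "chr1" & wt$arm == "q"] == 3L))
  expect_true(all(cn[wt$chrom == "chr1" & wt$arm == "p"] == 2L))
  expect_true(all(cn[wt$chrom == "chr2"] == 2L))

  # focal 2 Mbp amplicon offset by half a window: 2 windows take CN 6
  # (60% overlap), the 40%-overlap window stays at ploidy
  t2 <- simulateTruthProfile(g, data.frame(chrom = "chr2", start = 1.6e6,
                                           end = 3.6e6, cn = 6))
  cn2 <- truthWindowCN(t2, grid)[wt$chrom == "chr2"]
  expect_equal(cn2[1:5], c(2L, 2L, 6L, 6L, 2L))

  # overlapping events are rejected
  expect_error(simulateTruthProfile(g, data.frame(
    chrom = "chr1", start = c(0, 5e5), end = c(1e6, 2e6), cn = c(3, 1))),
    "non-overlapping")
})

test_that("fragment libraries partition the genome with geometric lengths", {
  g <- toyGenome(n = 1, len = 1e6)
  lib <- simulateFragmentLibrary(g, meanFragmentLen = 1000, seed = 3)
  # partition: every base covered exactly once
  expect_equal(lib@start[1], 0)
  expect_equal(lib@end[nFragments(lib)], 1e6)
  expect_true(all(lib@start[-1] == lib@end[-nFragments(lib)]))
  expect_true(all(lib@end > lib@start))
  # ~1000 fragments: renewal count within a generous Monte-Carlo band
  expect_gt(nFragments(lib), 1000 - 4 * sqrt(1000))
  expect_lt(nFragments(lib), 1000 + 4 * sqrt(1000))
  # determinism
  lib2 <- simulateFragmentLibrary(g, meanFragmentLen = 1000, seed = 3)
  expect_identical(lib@end, lib2@end)
  expect_identical(lib@qcLoci, lib2@qcLoci)
  # 4 distinct QC loci; on a >=4-chromosome genome, on 4 different chromosomes
  g4 <- toyGenome(n = 5, len = 2e6)
  lib4 <- simulateFragmentLibrary(g4, meanFragmentLen = 5000, seed = 1)
  expect_equal(length(unique(qcLoci(lib4))), 4L)
  expect_equal(length(unique(lib4@chrom[qcLoci(lib4)])), 4L)
  expect_error(simulateFragmentLibrary(g, meanFragmentLen = 10), ">= 50")
})

test_that("WGA weights are proportional to truth CN in the noiseless limit", {
  g <- toyGenome(n = 1, len = 1e7)
  truth <- simulateTruthProfile(g, data.frame(chrom = "chr1", start = 0,
                                              end = 4e6, cn = 3))
  lib <- simulateFragmentLibrary(g, meanFragmentLen = 1e4, seed = 5)
  wga <- simulateWGA(lib, truth, dropoutRate = 0, amplificationSd = 0, seed = 5)
  mid <- floor((wga@start + wga@end) / 2)
  expect_equal(wga@weight, ifelse(mid < 4e6, 3, 2))
  expect_equal(giiBands(wga), rep(TRUE, 4))

  # homozygous-deletion limit: CN-0 fragments get weight 0
  truth0 <- simulateTruthProfile(g, data.frame(chrom = "chr1", start = 0,
                                               end = 4e6, cn = 0))
  wga0 <- simulateWGA(lib, truth0, dropoutRate = 0, amplificationSd = 0)
  expect_true(all(wga0@weight[mid < 4e6] == 0))
  expect_true(all(wga0@weight[mid >= 4e6] > 0))
})

test_that("GII band dropout follows the binomial closed form", {
  g <- toyGenome(n = 4, len = 2e5)
  truth <- simulateTruthProfile(g)
  lib <- simulateFragmentLibrary(g, meanFragmentLen = 1e4, seed = 8)
  gii <- vapply(seq_len(10000), function(s) {
    sum(giiBands(simulateWGA(lib, truth, dropoutRate = 0.5,
                             amplificationSd = 0, seed = s)))
  }, numeric(1))
  # P(GII = 4) = 0.5^4 = 0.0625; +/- 4 binomial sd over 10,000 seeds
  tol <- 4 * sqrt(0.0625 * (1 - 0.0625) / 10000)
  expect_lt(abs(mean(gii == 4) - 0.0625), tol)
  expect_lt(abs(mean(gii) - 2), 4 * sqrt(4 * 0.25 / 10000))
})

test_that("read generation conserves counts and respects weights", {
  g <- toyGenome(n = 1, len = 1e6)
  truth <- simulateTruthProfile(g)
  lib <- simulateWGA(simulateFragmentLibrary(g, 1e4, seed = 2), truth,
                     dropoutRate = 0, amplificationSd = 0, seed = 2)

  # conservation: mapped + unmapped = nReads
  r <- simulateReads(lib, nReads = 5e4, contaminationFrac = 0.3, seed = 9)
  expect_equal(mappedCount(r) + unmappedCount(r), 5e4)
  # contamination is binomial around the requested fraction
  expect_lt(abs(unmappedCount(r) - 0.3 * 5e4), 4 * sqrt(5e4 * 0.3 * 0.7))

  # single retained fragment gets every mapped read
  lib1 <- lib
  lib1@weight[-1] <- 0
  r1 <- simulateReads(lib1, nReads = 1000, seed = 1)
  expect_true(all(r1@fragment == 1L))
  expect_true(all(r1@pos >= lib1@start[1] & r1@pos < lib1@end[1]))

  # all weights zero is an invalid state
  lib0 <- lib
  lib0@weight[] <- 0
  expect_error(simulateReads(lib0, 100), "zero")
})

test_that("noiseless simulation converges to the truth copy number", {
  # 50-window toy genome, no dropout / amplification noise / contamination:
  # normalized window counts approach the truth CN
  g <- toyGenome(n = 1, len = 5e7, cent = 2.5e7)
  grid <- buildWindowGrid(g, 1e6)
  ev <- data.frame(chrom = "chr1", start = c(1e7, 3e7), end = c(2e7, 3.5e7),
                   cn = c(3, 1))
  cell <- simulateCell(g, ev, nReads = 1e6, dropoutRate = 0,
                       amplificationSd = 0, contaminationFrac = 0,
                       meanFragmentLen = 2000, seed = 21)
  cn <- normalizeToCopyNumber(binReads(cell@reads, grid))
  expect_lt(max(abs(cn - truthWindowCN(cell@truth, grid))), 0.1)
})

test_that("cells are deterministic in (parameters, seed)", {
  g <- toyGenome(n = 2, len = 2e6)
  a <- simulateCell(g, nReads = 1e4, seed = 77)
  b <- simulateCell(g, nReads = 1e4, seed = 77)
  expect_identical(a@reads@pos, b@reads@pos)
  expect_identical(a@reads@fragment, b@reads@fragment)
  expect_identical(giiBands(a@library), giiBands(b@library))
  c <- simulateCell(g, nReads = 1e4, seed = 78)
  expect_false(identical(a@reads@pos, c@reads@pos))
})

test_that("DLRS increases with amplification noise on average", {
  g <- toyGenome(n = 1, len = 4e7)
  grid <- buildWindowGrid(g, 1e6)
  meanDlrs <- vapply(c(0.1, 0.6, 1.5), function(sd) {
    mean(vapply(1:20, function(s) {
      cell <- simulateCell(g, nReads = 5e4, dropoutRate = 0,
                           amplificationSd = sd, meanFragmentLen = 1e4,
                           seed = 1000 * s)
      as.numeric(computeDLRS(cell@reads, grid, subsample = 5e4, seed = s))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(meanDlrs) > 0))
})

test_that("fixtures round-trip through the package readers", {
  g <- toyGenome(n = 2, len = 3e6)
  grid <- buildWindowGrid(g, 1e6)
  cell <- simulateCell(g, nReads = 2000, contaminationFrac = 0.2, seed = 5)
  dir <- tempfile()

  files <- writeFixture(cell, dir, format = "tsv", grid = grid)
  back <- readReads(files[["reads"]])
  expect_equal(mappedCount(back), mappedCount(cell@reads))
  expect_equal(unmappedCount(back), unmappedCount(cell@reads))
  expect_equal(back@pos, cell@reads@pos)
  truth <- read.table(files[["truth"]], header = TRUE, sep = "\t")
  expect_equal(nrow(truth), nWindows(grid))
  expect_equal(truth$cn, truthWindowCN(cell@truth, grid))
  gii <- jsonlite::read_json(files[["gii"]], simplifyVector = TRUE)
  expect_equal(gii$gii, sum(giiBands(cell@library)))

  # regeneration reproduces byte-identical TSVs
  dir2 <- tempfile()
  cell2 <- simulateCell(g, nReads = 2000, contaminationFrac = 0.2, seed = 5)
  files2 <- writeFixture(cell2, dir2, format = "tsv", grid = grid)
  expect_identical(readLines(files[["reads"]]), readLines(files2[["reads"]]))

  # SAM round-trip preserves counts and 0-based positions
  filesSam <- writeFixture(cell, dir, format = "sam", grid = grid)
  backSam <- readReads(filesSam[["reads"]])
  expect_equal(mappedCount(backSam), mappedCount(cell@reads))
  expect_equal(unmappedCount(backSam), unmappedCount(cell@reads))
  expect_equal(sort(backSam@pos), sort(cell@reads@pos))
})
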