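test_that("genome integrity index counts present bands", {
  expect_equal(genomeIntegrityIndex(c(TRUE, TRUE, TRUE, TRUE)), 4L)
  expect_equal(genomeIntegrityIndex(c(FALSE, FALSE, FALSE, FALSE)), 0L)
  expect_equal(genomeIntegrityIndex(c(TRUE, FALSE, TRUE, FALSE)), 2L)
  # permutation invariance
  set.seed(1)
  for (i in 1:10) {
    b <- sample(c(TRUE, TRUE, FALSE, TRUE))
    expect_equal(genomeIntegrityIndex(b), 3L)
  }
  expect_error(genomeIntegrityIndex(c(TRUE, TRUE)), "4")
  expect_error(genomeIntegrityIndex(c(1, 0, 1, 0)), "logical")
})

test_that("mapped-read gate is inclusive at the threshold", {
  mk <- function(n) ReadSet(rep("chr1", n), seq_len(n) - 1)
  expect_true(mappedReadGate(mk(200), threshold = 200))
  expect_false(mappedReadGate(mk(199), threshold = 200))
  expect_false(mappedReadGate(ReadSet(character(0), numeric(0),
                                      unmapped = 350000), threshold = 200))
})

test_that("DLRS matches hand evaluation on the 6-window toy", {
  # CN (2,4,2,4,2,4): x = (0,1,0,1,0,1), d = (1,-1,1,-1,1)/sqrt(2),
  # sample sd = sqrt(0.6)
  expect_equal(dlrsStatistic(c(2, 4, 2, 4, 2, 4)), sqrt(0.6),
               tolerance = 1e-12)
  # constant profile: exactly 0
  expect_equal(dlrsStatistic(rep(2, 10)), 0)
  expect_error(dlrsStatistic(c(0, 2, 2)), "positive")
})

test_that("DLRS equals the brute-force formula on random profiles", {
  set.seed(42)
  for (i in 1:100) {
    cn <- 2 * 2^rnorm(sample(10:200, 1), 0, 0.3)
    oracle <- sd(diff(log2(cn / 2)) / sqrt(2))
    expect_equal(dlrsStatistic(cn), oracle, tolerance = 1e-12)
  }
})

test_that("DLRS recovers the sd of i.i.d. log-ratio noise", {
  # differencing doubles the variance of i.i.d. noise; the sqrt(2) restores it
  set.seed(7)
  x <- rnorm(2000, 0, 0.2)
  expect_equal(dlrsStatistic(2 * 2^x), 0.2, tolerance = 0.05 * 0.2 / 0.2)
  expect_lt(abs(dlrsStatistic(2 * 2^x) - 0.2), 0.01)
})

test_that("DLRS is scale-invariant and reversal-symmetric", {
  set.seed(13)
  for (i in 1:20) {
    cn <- 2 * 2^rnorm(50, 0, 0.4)
    expect_equal(dlrsStatistic(cn * runif(1, 0.5, 4)), dlrsStatistic(cn),
                 tolerance = 1e-12)
    expect_equal(dlrsStatistic(rev(cn)), dlrsStatistic(cn),
                 tolerance = 1e-12)
  }
})

test_that("DLRS differences never cross chromosome boundaries", {
  # two flat chromosomes at different levels: within-chromosome differences
  # are all zero, so DLRS = 0; pooling across the boundary would not be
  cn <- c(rep(2, 10), rep(4, 10))
  chrom <- rep(c("chr1", "chr2"), each = 10)
  expect_equal(dlrsStatistic(cn, chrom), 0)
  expect_gt(dlrsStatistic(cn), 0)
})

test_that("computeDLRS follows the subsample-bin-normalize procedure", {
  g <- toyGenome(n = 1, len = 2e7)
  grid <- buildWindowGrid(g, 1e6)
  # uniform reads: constant profile, DLRS ~ 0 up to counting noise
  set.seed(31)
  r <- ReadSet(rep("chr1", 1e5), floor(runif(1e5) * 2e7))
  d <- computeDLRS(r, grid, subsample = 5e4, seed = 4)
  expect_lt(as.numeric(d), 0.1)
  expect_true(attr(d, "subsampled"))
  expect_equal(attr(d, "readsUsed"), 5e4)
  # deterministic in the seed
  expect_equal(as.numeric(computeDLRS(r, grid, subsample = 5e4, seed = 4)),
               as.numeric(d))
  # fewer reads than the subsample: all used, flagged
  r2 <- ReadSet(rep("chr1", 1000), floor(runif(1000) * 2e7))
  d2 <- computeDLRS(r2, grid, seed = 1)
  expect_false(attr(d2, "subsampled"))
  # degenerate input: far too few reads for a defined metric
  expect_error(computeDLRS(ReadSet(rep("chr1", 3), c(0, 1, 2)), grid,
                           seed = 1),
               "too sparse|usable windows")
})

test_that("R50 closed forms hold", {
  # uniform library: 50 (exactly, for an even fragment count)
  expect_equal(r50FromCounts(rep(50, 4000)), 50)
  # two fragments with 100,000 reads each
  expect_equal(r50FromCounts(c(1e5, 1e5)), 50)
  # one dominant fragment + 50,000 singletons: N1 = 1, N2 = 50001
  expect_equal(r50FromCounts(c(150000, rep(1, 50000))), 100 / 50001)
  # odd uniform count rounds by one fragment
  expect_equal(r50FromCounts(rep(10, 5)), 100 * 3 / 5)
  expect_error(r50FromCounts(integer(0)), "no fragments")
})

test_that("computeR50 subsamples and reports fragment tallies", {
  set.seed(5)
  frag <- sample.int(500, 3e5, replace = TRUE)
  r <- ReadSet(rep("chr1", 3e5), seq_len(3e5), fragment = frag)
  v <- computeR50(r, subsample = 2e5, seed = 2)
  expect_equal(attr(v, "readsUsed"), 2e5)
  expect_true(as.numeric(v) > 0 && as.numeric(v) <= 100)
  # near-uniform library sits near 50
  expect_gt(as.numeric(v), 40)
  expect_equal(as.numeric(computeR50(r, subsample = 2e5, seed = 2)),
               as.numeric(v))
  expect_error(computeR50(ReadSet("chr1", 1)), "fragment")
})

test_that("R50 decreases as library skew increases", {
  skewR50 <- vapply(c(0.2, 1, 2.5), function(sd) {
    mean(vapply(1:20, function(s) {
      set.seed(100 * s)
      w <- exp(rnorm(2000, 0, sd))
      counts <- as.vector(rmultinom(1, 5e4, w))
      r50FromCounts(counts)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(skewR50) < 0))
})

test_that("evaluateCell applies gates in order with correct verdicts", {
  g <- toyGenome(n = 1, len = 2e7)
  grid <- buildWindowGrid(g, 1e6)
  set.seed(17)
  goodReads <- ReadSet(rep("chr1", 250000), floor(runif(250000) * 2e7),
                       fragment = sample.int(2000, 250000, replace = TRUE))

  # GII 1: discard at the GII gate, downstream gates not applicable
  rep1 <- evaluateCell(goodReads, grid, 1L, seed = 1)
  expect_false(qcKeep(rep1))
  expect_equal(firstFailingGate(rep1), "gii")
  gates <- qcGates(rep1)
  expect_false(any(gates$applicable[gates$gate != "gii"]))
  expect_true(is.na(rep1@dlrs))

  # clean cell passes everything
  rep2 <- evaluateCell(goodReads, grid, c(TRUE, TRUE, FALSE, TRUE), seed = 1)
  expect_true(qcKeep(rep2))
  expect_equal(rep2@gii, 3L)
  expect_true(is.na(firstFailingGate(rep2)))

  # too few mapped reads: mapped gate is the first failure
  fewReads <- ReadSet(rep("chr1", 150000), floor(runif(150000) * 2e7),
                      unmapped = 350000)
  rep3 <- evaluateCell(fewReads, grid, 4L, seed = 1)
  expect_false(qcKeep(rep3))
  expect_equal(firstFailingGate(rep3), "mapped_reads")
  expect_match(qcGates(rep3)$reason[2], "too few mapped reads")

  # high DLRS: discarded at the DLRS gate
  noisy <- ReadSet(rep("chr1", 250000),
                   floor(2e7 * rbeta(250000, 0.08, 0.08)))
  rep4 <- evaluateCell(noisy, grid, 4L, seed = 1)
  expect_false(qcKeep(rep4))
  expect_equal(firstFailingGate(rep4), "dlrs")
  expect_gt(rep4@dlrs, 0.35)
  expect_match(qcGates(rep4)$reason[3], "DLRS > 0.35")

  # R50 gate is report-only without a threshold, enforced with one
  expect_true(qcGates(rep2)$applicable[4])
  rep5 <- evaluateCell(goodReads, grid, 4L,
                       thresholds = qcThresholds(r50Min = 99.9), seed = 1)
  expect_false(qcKeep(rep5))
  expect_equal(firstFailingGate(rep5), "r50")
})
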