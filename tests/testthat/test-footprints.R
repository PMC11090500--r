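test_that("protected regions are strict sub-threshold runs with strict borders", {
  p <- CutProfile(c(20, 0, 0, 0, 0, 0, 15))
  fp <- callProtectedRegions(p, threshold = 10)
  expect_equal(length(fp), 1L)
  expect_equal(GenomicRanges::start(fp), 2L)   # run [2,6], length 5
  expect_equal(GenomicRanges::end(fp), 6L)
  expect_equal(fp$leftCount, 20)
  expect_equal(fp$rightCount, 15)
  expect_equal(fp$score, 20)

  # runs of length 4 or 51 between high borders are rejected
  short <- CutProfile(c(20, 20, 0, 0, 0, 0, 15, 15))
  expect_equal(length(callProtectedRegions(short, 10)), 0L)
  long <- CutProfile(c(20, rep(0, 51), 15))
  expect_equal(length(callProtectedRegions(long, 10)), 0L)

  # a position equal to the threshold terminates and disqualifies a run
  eq <- CutProfile(c(20, 0, 0, 10, 0, 0, 15))
  expect_equal(length(callProtectedRegions(eq, 10, minLen = 2)), 0L)
  eqBorder <- CutProfile(c(10, 0, 0, 0, 0, 0, 15))
  expect_equal(length(callProtectedRegions(eqBorder, 10)), 0L)

  # runs touching the interval edges have no border and are discarded
  edge <- CutProfile(c(0, 0, 0, 0, 0, 15, 15, 15))
  expect_equal(length(callProtectedRegions(edge, 10)), 0L)

  expect_warning(callProtectedRegions(CutProfile(c(1, 2, 3)), 10), "short")
})

test_that("the caller agrees with the enumerate-all-runs oracle", {
  set.seed(10)
  for (i in seq_len(1000)) {
    n <- sample(60:140, 1)
    thr <- sample(c(2, 3, 5, 8), 1)
    y <- rpois(n, thr)
    minLen <- sample(2:5, 1)
    maxLen <- sample(6:50, 1)
    got <- callProtectedRegions(CutProfile(y), thr, minLen, maxLen)
    want <- oracleProtectedRuns(y, thr, minLen, maxLen)
    expect_equal(cbind(GenomicRanges::start(got), GenomicRanges::end(got)),
                 matrix(as.integer(want), ncol = 2),
                 ignore_attr = TRUE)
  }
})

test_that("planted fully-protected footprints of admissible lengths are all recovered", {
  # one footprint of every length 5..50, plus a 4 bp and a 51 bp decoy
  lens <- c(4L, 5:50, 51L)
  gap <- 40L
  starts <- cumsum(c(200L, head(lens, -1) + gap))
  fp <- IRanges::IRanges(starts, width = lens)
  L <- max(IRanges::end(fp)) + 200L
  fx <- simFixture(len = L, footprints = fp, depletion = 0,
                   nEvents = 4e5L, seed = 51L)
  pooled <- countCuts(fx$frags, start = 1L, end = L)
  thr <- 5
  calls <- callProtectedRegions(pooled, thr)
  admissible <- fp[IRanges::width(fp) >= 5 & IRanges::width(fp) <= 50]
  hits <- GenomicRanges::countOverlaps(
    GenomicRanges::GRanges("synth1", admissible), calls, type = "equal")
  expect_equal(mean(hits > 0), 1.0)          # recall 1.0, exact boundaries
  decoys <- fp[IRanges::width(fp) %in% c(4L, 51L)]
  expect_equal(sum(GenomicRanges::countOverlaps(
    GenomicRanges::GRanges("synth1", decoys), calls)), 0L)
  # every call respects the run/border invariants
  y <- cutCounts(pooled)
  for (i in seq_along(calls)) {
    s <- GenomicRanges::start(calls)[i]; e <- GenomicRanges::end(calls)[i]
    expect_true(all(y[s:e] < thr))
    expect_gt(y[s - 1], thr)
    expect_gt(y[e + 1], thr)
  }
})

test_that("uniform bins tile the region and average exactly", {
  p1 <- CutProfile(rep(2, 10), state = "normalized", librarySize = 1)
  bs <- binRegion(list(p1), nBins = 2)
  expect_equal(IRanges::start(binRanges(bs)), c(1L, 6L))
  expect_equal(IRanges::end(binRanges(bs)), c(5L, 10L))
  expect_equal(as.vector(binMeans(bs)), c(2, 2))

  # remainder goes to the leading bins: 10 bp in 3 bins -> 4,3,3
  bs3 <- binRegion(list(p1), nBins = 3)
  expect_equal(IRanges::width(binRanges(bs3)), c(4L, 3L, 3L))

  # step profile matches a direct averaging oracle, and widths x means
  # reconstruct the region total
  y <- c(rep(1, 7), rep(9, 6))
  p2 <- CutProfile(y, state = "normalized", librarySize = 1)
  bs4 <- binRegion(list(p2), nBins = 4)
  w <- IRanges::width(binRanges(bs4))
  direct <- vapply(seq_len(4), function(i) {
    s <- IRanges::start(binRanges(bs4))[i]
    mean(y[s:(s + w[i] - 1)])
  }, numeric(1))
  expect_equal(as.vector(binMeans(bs4)), direct)
  expect_equal(sum(w * binMeans(bs4)), sum(y))

  expect_error(binRegion(list(p1), nBins = 11), "more bins")
})

test_that("site-adjacent accessibility change is measured against the remainder", {
  n <- 100
  sites <- IRanges::IRanges(41, 50)
  flank <- 5L
  mask <- rep(FALSE, n); mask[36:55] <- TRUE
  t0 <- CutProfile(rep(10, n), state = "normalized", librarySize = 1,
                   sampleId = "t0")
  # site-adjacent positions gain 6, the remainder drifts by 0.5
  y1 <- rep(10.5, n); y1[mask] <- 16
  t1 <- CutProfile(y1, state = "normalized", librarySize = 1,
                   sampleId = "t1")
  res <- siteAdjacentChange(list(t0, t1), sites, flank = flank)
  expect_equal(res$siteMean, 6)
  expect_equal(res$remainderMean, 0.5)
  expect_equal(res$ratio, 12)

  # identical consecutive profiles: change is zero, ratio undefined
  expect_warning(res0 <- siteAdjacentChange(list(t0, t0), sites), "undefined")
  expect_true(is.na(res0$ratio))

  # a site (plus flank) covering the whole region leaves no remainder
  expect_error(siteAdjacentChange(list(t0, t1), IRanges::IRanges(1, n)),
               "remainder")
  expect_error(siteAdjacentChange(list(t0), sites), "two timepoints")
})

test_that("in-site vs out-of-site counts are compared by rank sum", {
  y <- c(rep(0, 20), rep(10, 80))
  p <- CutProfile(y)
  sep <- compareInOutSites(p, IRanges::IRanges(1, 20))
  expect_lt(sep$p.value, 1e-10)
  same <- CutProfile(rep(c(1, 2), 50))
  ht <- compareInOutSites(same, IRanges::IRanges(1, 50))
  expect_gt(ht$p.value, 0.9)
  # exact enumeration oracle on small tie-free vectors
  a <- c(1.2, 3.4, 0.5, 2.2, 5.1)
  b <- c(6.3, 0.9, 4.4, 7.2, 8.0)
  p2 <- CutProfile(c(a, b), state = "corrected")
  ht2 <- compareInOutSites(p2, IRanges::IRanges(1, 5), exact = TRUE)
  expect_equal(ht2$p.value, oracleRankSumP(a, b))
  expect_error(compareInOutSites(p, IRanges::IRanges(1, 100)), "required")
})

test_that("footprint/known-site overlap matches interval intersection", {
  calls <- GenomicRanges::GRanges("c1", IRanges::IRanges(c(10, 50), c(20, 60)))
  known <- GenomicRanges::GRanges("c1", IRanges::IRanges(c(10, 30, 58), c(20, 40, 70)))
  rep <- overlapKnownSites(calls, known)
  expect_equal(rep$overlaps, c(TRUE, FALSE, TRUE))
  expect_equal(attr(rep, "fraction"), 2 / 3)
  # random instances vs brute-force intersection
  set.seed(11)
  for (i in 1:50) {
    s1 <- sample(100, 5); s2 <- sample(100, 5)
    gr1 <- GenomicRanges::GRanges("c1", IRanges::IRanges(s1, s1 + sample(0:10, 5, TRUE)))
    gr2 <- GenomicRanges::GRanges("c1", IRanges::IRanges(s2, s2 + sample(0:10, 5, TRUE)))
    got <- overlapKnownSites(gr1, gr2)$overlaps
    want <- vapply(seq_along(gr2), function(j)
      any(GenomicRanges::start(gr2)[j] <= GenomicRanges::end(gr1) &
          GenomicRanges::end(gr2)[j] >= GenomicRanges::start(gr1)),
      logical(1))
    expect_equal(got, want)
  }
})
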