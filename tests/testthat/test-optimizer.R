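test_that("TIC filter keeps the ceiling of i% of charge-surviving scans", {
  # 10 scans all charge 2, i = 50 -> exactly the 5 largest TICs
  tb <- make_table(rt = 1:10, tic = c(5, 9, 1, 7, 3, 10, 2, 8, 4, 6))
  f <- filterScans(tb, OptimizationParams(iPercent = 50))
  expect_identical(length(f), 5L)
  expect_setequal(scans(f)$tic, c(10, 9, 8, 7, 6))
  # 7 scans, i = 50 -> K = ceiling(3.5) = 4; cross-checked against the
  # smallest count covering at least i% of the scans
  tb7 <- make_table(rt = 1:7, tic = 7:1)
  f7 <- filterScans(tb7, OptimizationParams(iPercent = 50))
  expect_identical(length(f7), oracle_keep_count(50, 7))
  expect_identical(length(f7), 4L)
  for (i in c(10, 33, 66.7, 100)) {
    fi <- filterScans(tb7, OptimizationParams(iPercent = i))
    expect_identical(length(fi), oracle_keep_count(i, 7))
  }
})

test_that("charge filtering precedes the TIC cut", {
  tb <- make_table(rt = 1:4, tic = c(100, 90, 10, 5),
                   charge = c(1L, 1L, 2L, 3L))
  f <- filterScans(tb, OptimizationParams(iPercent = 100, minCharge = 2))
  expect_setequal(scans(f)$precursor_charge, c(2L, 3L))
  # the two high-TIC singly charged scans never enter the TIC ranking
  f50 <- filterScans(tb, OptimizationParams(iPercent = 50, minCharge = 2))
  expect_identical(scans(f50)$tic, 10)
  at <- f50@metadata$attrition
  expect_identical(unname(at), c(4L, 4L, 2L, 1L))
})

test_that("unknown charge is dropped by default, kept on request", {
  tb <- make_table(rt = 1:3, charge = c(2L, NA, NA))
  expect_identical(length(filterScans(tb, OptimizationParams(iPercent = 100))),
                   1L)
  keep <- OptimizationParams(iPercent = 100, includeUnknownCharge = TRUE)
  expect_identical(length(filterScans(tb, keep)), 3L)
})

test_that("MS1 scans never enter the optimization", {
  tb <- make_table(rt = 1:4, ms_level = c(1L, 2L, 1L, 2L),
                   charge = c(NA, 2L, NA, 2L))
  f <- filterScans(tb, OptimizationParams(iPercent = 100,
                                          includeUnknownCharge = TRUE))
  expect_identical(length(f), 2L)
})

test_that("an empty post-filter set is an error with attrition counts", {
  tb <- make_table(rt = 1:3, charge = c(1L, 1L, 1L))
  expect_error(filterScans(tb), "no scans survive")
})

test_that("TIC filtering is invariant to rescaling (rank-based)", {
  set.seed(13)
  tb <- make_table(rt = 1:20, tic = runif(20, 1e4, 1e7))
  f1 <- filterScans(tb)
  tb2 <- make_table(rt = 1:20, tic = scans(tb)$tic * 17.3)
  f2 <- filterScans(tb2)
  expect_identical(scans(f1)$scan_id, scans(f2)$scan_id)
})

test_that("TIC ties at the cutoff break by rt then scan_id", {
  tb <- make_table(rt = c(3, 1, 2), tic = c(100, 100, 100))
  f <- filterScans(tb, OptimizationParams(iPercent = 34))
  # K = ceiling(0.34 * 3) = 2; the two earliest-eluting tied scans win
  expect_identical(sort(scans(f)$rt), c(1, 2))
})

test_that("scanPercentB maps, sorts and applies the span policy", {
  g <- lin_gradient()
  tb <- make_table(rt = c(45, 15, 30))
  b <- scanPercentB(filterScans(tb, OptimizationParams(iPercent = 100)), g)
  expect_equal(as.numeric(b), c(10, 20, 30))
  # dead-volume delay pushes an early scan before the gradient start
  tb2 <- make_table(rt = c(1, 30, 40, 50))
  d <- DelayModel(deadVolumeDelay = 5)
  f2 <- filterScans(tb2, OptimizationParams(iPercent = 100))
  b_drop <- scanPercentB(f2, g, d, policy = "drop")
  expect_length(b_drop, 3L)
  expect_identical(attr(b_drop, "nOutside"), 1L)
  b_clamp <- scanPercentB(f2, g, d, policy = "clamp")
  expect_length(b_clamp, 4L)
  expect_equal(min(b_clamp), 0)
  # all scans outside the span: advisory error
  tb3 <- make_table(rt = c(1, 2))
  expect_error(scanPercentB(filterScans(tb3, OptimizationParams(iPercent = 100)),
                            g, DelayModel(deadVolumeDelay = 10)),
               "check the gradient declaration and delay")
})

test_that("the worked six-scan example builds program [0, 10, 20, 40]", {
  og <- buildOptimizedGradient(c(5, 10, 10, 20, 30, 35), lin_gradient(),
                               OptimizationParams(stepIntervalMin = 20))
  bp <- breakpoints(program(og))
  expect_equal(bp$percent_b, c(0, 10, 20, 40))
  expect_equal(bp$time_min, c(0, 20, 40, 60))
  expect_identical(nUsed(og), 6L)
  expect_equal(quantileValues(og), c(10, 20))
  expect_identical(equalCountCheck(og, c(5, 10, 10, 20, 30, 35)),
                   c(2L, 2L, 2L))
})

test_that("a 60-min analytical window at T = 5 gives 12 steps", {
  tb <- generateRun(syntheticRunSpec(nScans = 300, seed = 2))
  og <- optimizeGradient(tb, lin_gradient())
  expect_identical(length(program(og)@time) - 1L, 12L)
  expect_equal(program(og)@time, seq(0, 60, by = 5))
})

test_that("uniform input recovers the standard linear program", {
  g <- lin_gradient()
  rt <- (seq_len(599) / 600) * 60
  bvals <- rt / 60 * 40
  og <- buildOptimizedGradient(bvals, g, OptimizationParams())
  bp <- breakpoints(program(og))
  # every breakpoint within one inter-scan %B spacing of the straight line
  expect_lt(max(abs(bp$percent_b - bp$time_min / 60 * 40)), 40 / 599)
})

test_that("equal-fraction counts hold across random inputs", {
  set.seed(101)
  for (rep in 1:40) {
    n <- sample(30:600, 1)
    b <- sort(runif(n, 0, 40))
    og <- buildOptimizedGradient(b, lin_gradient(), OptimizationParams())
    counts <- equalCountCheck(og, b)
    s <- length(counts)
    expect_identical(sum(counts), n)
    expect_true(all(counts >= floor(n / s) & counts <= ceiling(n / s)))
    expect_true(all(diff(program(og)@percentB) >= 0))
  }
})

test_that("exact divisibility gives exactly N/S scans per step", {
  set.seed(7)
  b <- sort(runif(120, 0, 40))
  og <- buildOptimizedGradient(b, lin_gradient(), OptimizationParams())
  expect_identical(equalCountCheck(og, b), rep(10L, 12L))
  # N = S: one scan per step
  b12 <- sort(runif(12, 1, 39))
  og12 <- buildOptimizedGradient(b12, lin_gradient(), OptimizationParams())
  expect_identical(equalCountCheck(og12, b12), rep(1L, 12L))
})

test_that("boundary ties perturb counts by at most their multiplicity", {
  set.seed(8)
  base <- sort(runif(100, 0, 40))
  b <- sort(c(base, rep(base[25], 3)))  # quadruple one value
  og <- buildOptimizedGradient(b, lin_gradient(), OptimizationParams())
  counts <- equalCountCheck(og, b)
  n <- length(b); s <- length(counts)
  expect_identical(sum(counts), n)
  expect_true(all(abs(counts - n / s) <= 4 + 1))
})

test_that("too few scans for the step count is an error", {
  expect_error(buildOptimizedGradient(c(5, 30, 35), lin_gradient(),
                                      OptimizationParams()),
               "too few scans")
})

test_that("endpoints are pinned and the remainder rule preserves duration", {
  g <- GradientProgram(c(0, 62), c(2, 38))
  set.seed(9)
  b <- sort(runif(200, 2, 38))
  og <- buildOptimizedGradient(b, g, OptimizationParams())
  bp <- breakpoints(program(og))
  expect_equal(bp$percent_b[1], 2)
  expect_equal(bp$percent_b[nrow(bp)], 38)
  # S = round(62/5) = 12; grid 0,5,...,55 then the 62-min close
  expect_equal(bp$time_min, c(seq(0, 55, by = 5), 62))
})

test_that("declared wash segments are carried through verbatim", {
  g <- GradientProgram(c(0, 60, 65, 70), c(0, 40, 80, 2), washStart = 60)
  set.seed(10)
  b <- sort(runif(100, 0, 40))
  og <- buildOptimizedGradient(b, g, OptimizationParams())
  bp <- breakpoints(program(og))
  expect_equal(tail(bp$time_min, 2), c(65, 70))
  expect_equal(tail(bp$percent_b, 2), c(80, 2))
  expect_equal(bp$time_min[1:13], seq(0, 60, by = 5))
})

test_that("rt shift with compensating MS start delay changes nothing", {
  g <- lin_gradient()
  tb <- generateRun(syntheticRunSpec(nScans = 200, rtPreset = "late",
                                     seed = 4))
  og1 <- optimizeGradient(tb, g)
  sc <- scans(tb); sc$rt <- sc$rt + 7
  tb2 <- ScanTable(sc, runId = runId(tb), runLength = runLength(tb) + 7,
                   metadata = tb@metadata)
  og2 <- optimizeGradient(tb2, g, d = DelayModel(deadVolumeDelay = 7))
  expect_equal(breakpoints(program(og1)), breakpoints(program(og2)),
               tolerance = 1e-9)
})
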