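test_that("self-prediction recovers the original retention times", {
  g <- lin_gradient()
  tb <- make_table(rt = c(6, 15, 24, 33, 42, 51))
  f <- filterScans(tb, OptimizationParams(iPercent = 100))
  for (d in list(DelayModel(), DelayModel(3, 1))) {
    b <- scanPercentB(f, g, d)
    expect_equal(as.numeric(predictElution(b, g, d)), scans(tb)$rt,
                 tolerance = 1e-9)
  }
})

test_that("predictElution inverts the linear map and preserves order", {
  g <- lin_gradient()
  expect_equal(as.numeric(predictElution(20, g)), 30)
  set.seed(21)
  b <- runif(100, 0, 40)
  t <- predictElution(b, g, DelayModel(2, 1))
  expect_identical(order(t), order(b))
  # out-of-range compositions are flagged, not errors
  t2 <- predictElution(c(10, 45), g)
  expect_true(is.na(t2[2]))
  expect_identical(attr(t2, "nExcluded"), 1L)
})

test_that("the six-scan worked example puts 2 scans in each step", {
  b <- c(5, 10, 10, 20, 30, 35)
  og <- buildOptimizedGradient(b, lin_gradient(),
                               OptimizationParams(stepIntervalMin = 20))
  # the equal-fraction assignment gives 2 scans per step; the scans tied at
  # a boundary composition elute exactly at the step boundary time
  expect_identical(equalCountCheck(og, b), c(2L, 2L, 2L))
  t <- as.numeric(predictElution(b, program(og)))
  expect_equal(t, c(10, 20, 20, 40, 50, 55))
  # distinct compositions bin cleanly: a step's closing order statistic
  # elutes exactly at the boundary time and belongs to the step it closes
  b2 <- c(5, 9.99, 10, 20, 30, 35)
  og2 <- buildOptimizedGradient(b2, lin_gradient(),
                                OptimizationParams(stepIntervalMin = 20))
  t2 <- as.numeric(predictElution(b2, program(og2)))
  expect_identical(as.integer(table(cut(t2, c(0, 20, 40, 60),
                                        include.lowest = TRUE))),
                   c(2L, 2L, 2L))
})

test_that("the KS statistic matches the reference implementation", {
  set.seed(31)
  x <- runif(200, 0, 60)^1.3 / 60^0.3
  ours <- msgrad:::.ks_uniform(x, 0, 60)
  ref <- suppressWarnings(stats::ks.test(x, "punif", 0, 60)$statistic)
  expect_equal(ours, unname(ref), tolerance = 1e-12)
})

test_that("a late-eluting run is uniformized by the optimized gradient", {
  g <- lin_gradient()
  tb <- generateRun(syntheticRunSpec(nScans = 2000, rtPreset = "late",
                                     seed = 42))
  params <- OptimizationParams()
  f <- filterScans(tb, params)
  b <- scanPercentB(f, g)
  og <- buildOptimizedGradient(b, g, params, sourceRun = runId(tb))
  rep <- uniformityReport(b, g, og)
  expect_lt(ksUniform(rep), rep@comparison$ksUniform)
  n <- length(predictedRts(rep)); s <- rep@provenance$steps
  expect_identical(sum(binCounts(rep)), n)
  expect_true(all(abs(binCounts(rep) - n / s) <= 1))
})

test_that("already-uniform input leaves nothing to improve", {
  g <- lin_gradient()
  b <- sort((seq_len(600) / 600) * 40)
  og <- buildOptimizedGradient(b, g, OptimizationParams())
  rep <- uniformityReport(b, g, og)
  expect_lt(abs(ksUniform(rep) - rep@comparison$ksUniform), 0.05)
})

test_that("degenerate and underpowered inputs are refused or flagged", {
  g <- lin_gradient()
  b <- rep(20, 30)
  og <- buildOptimizedGradient(b, g, OptimizationParams())
  expect_warning(uniformityReport(b, g, og), "degenerate")
  expect_error(suppressWarnings(
    uniformityReport(rep(20, 4), g,
                     buildOptimizedGradient(rep(20, 4), g,
                                            OptimizationParams(stepIntervalMin = 30)))),
    "fewer than 5")
})

test_that("reports serialize to JSON and a two-column rt table", {
  g <- lin_gradient()
  tb <- generateRun(syntheticRunSpec(nScans = 400, rtPreset = "early",
                                     seed = 6))
  res <- runPipeline(tb, g, quiet = TRUE)
  json <- withr::local_tempfile(fileext = ".json")
  rts <- withr::local_tempfile(fileext = ".tsv")
  exportReport(res$report, json, rts)
  obj <- jsonlite::read_json(json)
  expect_equal(obj$ks_uniform_optimized, ksUniform(res$report))
  expect_equal(obj$provenance$params$iPercent, 50)
  df <- read.delim(rts)
  expect_identical(names(df), c("rt_standard_min", "rt_optimized_min"))
  expect_identical(nrow(df), length(predictedRts(res$report)))
})
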