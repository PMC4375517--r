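test_that("scan-table TSV round trip is the identity", {
  tb <- make_table(rt = c(1.5, 2.25, 10.123456789, 30, 59.9),
                   tic = c(1e5, 2e6, 3.5e4, 7e6, 1.2e5),
                   charge = c(2L, NA, 3L, 1L, 4L))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeScanTable(tb, path)
  back <- readScanTable(path, runId = runId(tb))
  expect_equal(scans(back)$rt, scans(tb)$rt, tolerance = 1e-12)
  expect_equal(scans(back)$tic, scans(tb)$tic, tolerance = 1e-12)
  expect_identical(scans(back)$scan_id, scans(tb)$scan_id)
  expect_identical(scans(back)$precursor_charge, scans(tb)$precursor_charge)
  expect_identical(scans(back)$ms_level, scans(tb)$ms_level)
})

test_that("scan tables are re-sorted by rt on read, blank charge is unknown", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("scan_id\trt_min\tms_level\ttic\tprecursor_charge",
               "b\t5.0\t2\t100\t2",
               "a\t1.0\t2\t200\t",
               "c\t3.0\t2\t300\t3"), path)
  tb <- readScanTable(path)
  expect_identical(scans(tb)$scan_id, c("a", "c", "b"))
  expect_identical(scans(tb)$precursor_charge, c(NA_integer_, 3L, 2L))
})

test_that("scan-table schema and value errors are reported", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("scan_id\trt_min\ttic", "a\t1\t100"), path)
  expect_error(readScanTable(path), "missing required column.*ms_level")
  writeLines(c("scan_id\trt_min\tms_level\ttic\tprecursor_charge",
               "a\t-1\t2\t100\t2"), path)
  expect_error(readScanTable(path), "row 1")
})

test_that("mzML fixtures round-trip, converting seconds to minutes", {
  tb <- make_table(rt = c(1, 2, 3), tic = c(1e4, 2e4, 3e4))
  path <- withr::local_tempfile(fileext = ".mzML")
  writeFixtureMzML(tb, path)
  # the fixture writes scan start times of 60, 120, 180 seconds
  expect_true(any(grepl('value="60" unit', readLines(path))))
  back <- readMzML(path)
  expect_equal(scans(back)$rt, c(1, 2, 3), tolerance = 1e-9)
  expect_equal(scans(back)$tic, scans(tb)$tic, tolerance = 1e-9)
  expect_identical(scans(back)$precursor_charge, scans(tb)$precursor_charge)
})

test_that("mzML reader maps MS1 and unknown charge to NA", {
  tb <- make_table(rt = c(1, 2), charge = c(NA, 2L), ms_level = c(1L, 2L))
  path <- withr::local_tempfile(fileext = ".mzML")
  writeFixtureMzML(tb, path)
  back <- readMzML(path)
  expect_identical(scans(back)$ms_level, c(1L, 2L))
  expect_identical(scans(back)$precursor_charge, c(NA_integer_, 2L))
})

test_that("TIC falls back to the sum of peak intensities when absent", {
  tb <- make_table(rt = 1, tic = 1000)
  path <- withr::local_tempfile(fileext = ".mzML")
  writeFixtureMzML(tb, path, omitTic = "scan=1",
                   peakData = list("scan=1" = cbind(c(100.1, 200.2, 300.3),
                                                    c(100, 250, 650))))
  expect_false(any(grepl("total ion current", readLines(path))))
  back <- readMzML(path)
  expect_equal(scans(back)$tic, 1000)
})

test_that("unreadable or empty mzML files give informative errors", {
  path <- withr::local_tempfile(fileext = ".mzML")
  writeLines("this is not xml", path)
  expect_error(readMzML(path), path)
  expect_error(readMzML(file.path(tempdir(), "nope.mzML")), "not found")
})

test_that("mzML and scan-table routes give identical optimizer output", {
  tb <- generateRun(syntheticRunSpec(nScans = 150, rtPreset = "late",
                                     seed = 5, nMs1 = 10L))
  mz_path <- withr::local_tempfile(fileext = ".mzML")
  tsv_path <- withr::local_tempfile(fileext = ".tsv")
  writeFixtureMzML(tb, mz_path)
  writeScanTable(tb, tsv_path)
  g <- lin_gradient()
  og1 <- optimizeGradient(readMzML(mz_path), g)
  og2 <- optimizeGradient(readScanTable(tsv_path), g)
  expect_equal(breakpoints(program(og1)), breakpoints(program(og2)),
               tolerance = 1e-9)
  expect_identical(nUsed(og1), nUsed(og2))
})
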