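#' Select the MS/MS scans that drive gradient optimization
#'
#' Three filters, applied in order, reduce a run's scans to the set assumed
#' identifiable: (1) keep MS level >= 2; (2) drop scans whose known precursor
#' charge is below `minCharge` (by default singly charged precursors, which
#' are largely chemical contaminants), dropping unknown-charge scans too
#' unless `includeUnknownCharge`; (3) of the M survivors keep the
#' `K = ceiling(iPercent/100 * M)` scans with the largest TIC — the working
#' assumption being that the identifiable fraction of MS/MS spectra is the
#' high-TIC fraction. Ties at the TIC cutoff are broken by earlier retention
#' time, then lexicographic scan id, so the selection is deterministic.
#' Per-stage attrition counts are recorded in the result's `metadata`
#' (element `attrition`).
#'
#' @param table a non-empty [ScanTable-class].
#' @param params an [OptimizationParams-class].
#' @return A [ScanTable-class] of the K selected scans (sorted by retention
#'   time), with `metadata(table)$attrition` holding the counts
#'   `input`, `ms2`, `after_charge`, `after_tic`.
#' @examples
#' tb <- generateRun(syntheticRunSpec(nScans = 200, seed = 1))
#' filtered <- filterScans(tb, OptimizationParams())
#' filtered@metadata$attrition
#' @export
filterScans <- function(table, params = OptimizationParams()) {
  stopifnot(is(table, "ScanTable"), is(params, "OptimizationParams"))
  sc <- scans(table)
  if (!nrow(sc)) stop("scan table is empty", call. = FALSE)
  n_input <- nrow(sc)

  sc <- sc[sc$ms_level >= 2L, , drop = FALSE]
  n_ms2 <- nrow(sc)

  known <- !is.na(sc$precursor_charge)
  keep <- (known & sc$precursor_charge >= params@minCharge) |
    (!known & params@includeUnknownCharge)
  sc <- sc[keep, , drop = FALSE]
  m <- nrow(sc)

  if (m == 0L)
    stop(sprintf(paste0("no scans survive filtering (input %d, MS2+ %d, ",
                        "after charge filter 0); relax minCharge or set ",
                        "includeUnknownCharge"), n_input, n_ms2),
         call. = FALSE)

  k <- ceiling(params@iPercent / 100 * m)
  ord <- order(-sc$tic, sc$rt, sc$scan_id)
  sc <- sc[ord[seq_len(k)], , drop = FALSE]

  ScanTable(sc, runId = runId(table), runLength = runLength(table),
            metadata = c(table@metadata,
                         list(attrition = c(input = as.integer(n_input),
                                            ms2 = as.integer(n_ms2),
                                            after_charge = as.integer(m),
                                            after_tic = as.integer(k)),
                              params = params)))
}

#' Solvent compositions at which the selected scans eluted
#'
#' Maps each scan's retention time to percent solvent B via
#' [rtToPercentB()] against the analytical segment of the standard program.
#' Scans eluting outside the program span (during loading or wash) are either
#' dropped (`policy = "drop"`, the default — their count is attached as the
#' `nOutside` attribute) or clamped to the nearer endpoint composition
#' (`policy = "clamp"`, for programs that start mid-composition).
#'
#' @param filtered a non-empty [ScanTable-class], normally the output of
#'   [filterScans()].
#' @param g the standard [GradientProgram-class] the run was acquired on.
#' @param d a [DelayModel-class].
#' @param policy `"drop"` or `"clamp"`.
#' @return Sorted ascending numeric vector of percent-B values; its length is
#'   N, the number of observations driving the optimization. Attribute
#'   `nOutside` counts out-of-span scans encountered.
#' @export
scanPercentB <- function(filtered, g, d = DelayModel(),
                         policy = c("drop", "clamp")) {
  stopifnot(is(filtered, "ScanTable"), is(g, "GradientProgram"),
            is(d, "DelayModel"))
  policy <- match.arg(policy)
  rt <- scans(filtered)$rt
  if (!length(rt)) stop("no scans to map", call. = FALSE)
  ga <- analyticalSegment(g)
  tau <- rt + d@msStartDelay - d@deadVolumeDelay
  lo <- ga@time[1L]; hi <- ga@time[length(ga@time)]
  below <- tau < lo; above <- tau > hi
  b <- rtToPercentB(rt, ga, d)
  n_outside <- sum(below | above)
  if (policy == "drop") {
    b <- b[!(below | above)]
  } else {
    b[below] <- ga@percentB[1L]
    b[above] <- ga@percentB[length(ga@percentB)]
  }
  if (!length(b))
    stop(paste0("all scans fall outside the declared gradient span; ",
                "check the gradient declaration and delay values"),
         call. = FALSE)
  structure(sort(b), nOutside = n_outside)
}

#' Build the equal-fraction stepped gradient
#'
#' The defining construction: given the sorted percent-B values at which the
#' N selected scans eluted on the standard gradient, build a stepped program
#' of S linear segments over the same analytical window whose steps each
#' bracket an equal fraction of the N scans.
#'
#' With T = `params@stepIntervalMin` and D the analytical duration of the
#' standard program, the number of steps is `S = round(D / T)` (at least 2).
#' Breakpoint times are `0, T, 2T, ...` on the pump clock; when `S * T != D`
#' the final step absorbs the remainder so the optimized run keeps exactly
#' the standard run's analytical duration. The endpoint compositions are
#' pinned to the standard program's start and end %B — the optimized run
#' still spans the full composition range, so no analyte class is lost — and
#' the interior breakpoint at step k is the empirical quantile of the
#' observations at probability k/S, using the order statistic
#' `q = x_(ceiling(k N / S))`. That rule returns an actually observed
#' composition and makes the per-step counts exactly N/S whenever S divides
#' N. The %B sequence is non-decreasing by construction. Any declared wash
#' block of the standard program is appended verbatim.
#'
#' @param bvals numeric vector of percent-B values (will be sorted), from
#'   [scanPercentB()].
#' @param gStd the standard [GradientProgram-class].
#' @param params an [OptimizationParams-class]; only `stepIntervalMin` is
#'   used here.
#' @param sourceRun run identifier recorded as provenance.
#' @return An [OptimizedGradient-class].
#' @seealso [equalCountCheck()] verifies the defining per-step counts;
#'   [optimizeGradient()] runs the whole chain from a [ScanTable-class].
#' @examples
#' g <- GradientProgram(c(0, 60), c(0, 40))
#' og <- buildOptimizedGradient(c(5, 10, 10, 20, 30, 35), g,
#'                              OptimizationParams(stepIntervalMin = 20))
#' breakpoints(program(og))
#' equalCountCheck(og, c(5, 10, 10, 20, 30, 35))
#' @export
buildOptimizedGradient <- function(bvals, gStd, params = OptimizationParams(),
                                   sourceRun = "run") {
  stopifnot(is(gStd, "GradientProgram"), is(params, "OptimizationParams"))
  bvals <- sort(as.numeric(bvals))
  n <- length(bvals)
  if (!n) stop("no percent-B observations supplied", call. = FALSE)

  ga <- analyticalSegment(gStd)
  t0 <- ga@time[1L]
  dur <- ga@time[length(ga@time)] - t0
  tt <- params@stepIntervalMin
  s <- max(2L, as.integer(round(dur / tt)))
  if (n < s)
    stop(sprintf(paste0("too few scans to build %d steps (N = %d); increase ",
                        "the step interval T or the TIC percentage i"), s, n),
         call. = FALSE)

  # grid 0, T, 2T, ... with the final step absorbing any remainder; fall back
  # to an even grid when T is too coarse to fit S steps into the window
  times <- if ((s - 1L) * tt < dur)
    c(t0 + (seq_len(s) - 1L) * tt, t0 + dur)
  else
    seq(t0, t0 + dur, length.out = s + 1L)

  b_start <- ga@percentB[1L]
  b_end <- ga@percentB[length(ga@percentB)]
  q <- bvals[ceiling(seq_len(s - 1L) / s * n)]
  q <- pmin(pmax(q, b_start), b_end)
  pb <- c(b_start, q, b_end)

  wash <- if (!is.na(gStd@washStart)) gStd@time > gStd@washStart else
    rep(FALSE, length(gStd@time))
  # wash breakpoints strictly after the analytical end carry over unchanged
  wash <- wash & gStd@time > ga@time[length(ga@time)]
  prog <- GradientProgram(c(times, gStd@time[wash]),
                          c(pb, gStd@percentB[wash]),
                          label = paste0(gStd@label, " (optimized)"),
                          washStart = if (any(wash)) t0 + dur else NA_real_)

  new("OptimizedGradient", program = prog, standard = gStd,
      nUsed = as.integer(n), quantileValues = as.numeric(q), params = params,
      sourceRun = as.character(sourceRun))
}

#' Verify the equal-fraction property of an optimized gradient
#'
#' Counts, for each of the S steps of an optimized program, how many of the
#' driving percent-B observations fall in that step's composition interval.
#' Because interior breakpoints are observed order statistics, observations
#' tied exactly at a step boundary are split between the adjacent steps the
#' way the equal-fraction assignment dictates (the boundary observation's
#' rank decides); for all-distinct observations this reduces to plain
#' interval counting. When S divides N and values are distinct every count is
#' exactly N/S; in general counts lie in `{floor(N/S), ceiling(N/S)}` up to
#' boundary-tie multiplicity.
#'
#' @param og an [OptimizedGradient-class].
#' @param bvals the percent-B observations `og` was built from.
#' @return Integer vector of S per-step counts (sums to the number of
#'   observations inside the program's range).
#' @export
equalCountCheck <- function(og, bvals) {
  stopifnot(is(og, "OptimizedGradient"))
  sb <- sort(as.numeric(bvals))
  n <- length(sb)
  s <- length(og@quantileValues) + 1L
  q <- og@quantileValues
  at_most <- vapply(q, function(x) sum(sb <= x), integer(1L))
  below <- vapply(q, function(x) sum(sb < x), integer(1L))
  ideal <- as.integer(ceiling(seq_len(s - 1L) * n / s))
  ranks <- pmin(pmax(ideal, below), at_most)
  as.integer(diff(c(0L, ranks, n)))
}

#' Optimize a gradient from a run's scan table
#'
#' Convenience wrapper running the full optimization chain:
#' [filterScans()] then [scanPercentB()] then [buildOptimizedGradient()].
#'
#' @param table a [ScanTable-class] acquired on `gStd`.
#' @param gStd the standard [GradientProgram-class].
#' @param d a [DelayModel-class].
#' @param params an [OptimizationParams-class].
#' @return An [OptimizedGradient-class].
#' @examples
#' tb <- generateRun(syntheticRunSpec(nScans = 500, rtPreset = "late",
#'                                    seed = 11))
#' g <- GradientProgram(c(0, 60), c(0, 40))
#' og <- optimizeGradient(tb, g)
#' og
#' @export
optimizeGradient <- function(table, gStd, d = DelayModel(),
                             params = OptimizationParams()) {
  filtered <- filterScans(table, params)
  b <- scanPercentB(filtered, gStd, d, policy = params@outOfSpanPolicy)
  og <- buildOptimizedGradient(b, gStd, params, sourceRun = runId(table))
  og
}
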