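#' Predict elution times under a candidate gradient
#'
#' Uses the characteristic-composition elution model implicit in the
#' equal-fraction construction: a precursor observed to elute at a given
#' percent B elutes, under any other program, when the delivered composition
#' first reaches that percent B. The predicted MS retention time is the pump
#' time from [timeAtPercentB()] shifted back onto the MS clock
#' (`+ deadVolumeDelay - msStartDelay`). Gradient-slope effects on retention
#' and peak width are deliberately ignored; within this model, predicting a
#' run's own compositions under its own program recovers the original
#' retention times exactly.
#'
#' @param bvals numeric percent-B values.
#' @param gNew the candidate [GradientProgram-class].
#' @param d a [DelayModel-class].
#' @return numeric vector of predicted retention times in minutes; values of
#'   `bvals` outside the candidate's analytical %B range yield `NA` and are
#'   counted in the `nExcluded` attribute.
#' @export
predictElution <- function(bvals, gNew, d = DelayModel()) {
  stopifnot(is(gNew, "GradientProgram"), is(d, "DelayModel"))
  bvals <- as.numeric(bvals)
  ga <- analyticalSegment(gNew)
  lo <- ga@percentB[1L]; hi <- ga@percentB[length(ga@percentB)]
  ok <- !is.na(bvals) & bvals >= lo & bvals <= hi
  out <- rep(NA_real_, length(bvals))
  if (any(ok))
    out[ok] <- timeAtPercentB(ga, bvals[ok]) +
      d@deadVolumeDelay - d@msStartDelay
  structure(out, nExcluded = sum(!ok))
}

# exact one-sample KS statistic against Uniform(a, b)
.ks_uniform <- function(x, a, b) {
  u <- sort((x - a) / (b - a))
  u <- pmin(pmax(u, 0), 1)
  n <- length(u)
  i <- seq_len(n)
  max(i / n - u, u - (i - 1) / n)
}

#' Quantify elution redistribution under an optimized gradient
#'
#' Predicts where the driving scans would elute under the optimized program
#' and under the standard program, and reports for each the
#' Kolmogorov-Smirnov distance of the predicted elution times from the
#' continuous uniform distribution over the analytical window, alongside
#' per-step bin counts. A smaller KS distance for the optimized program means
#' elution is spread more evenly across the run — the purpose of the
#' optimization.
#'
#' @param bvals numeric percent-B observations the gradient was built from.
#' @param gStd the standard [GradientProgram-class].
#' @param og the [OptimizedGradient-class] built from `bvals` on `gStd`.
#' @param d a [DelayModel-class].
#' @return A [RedistributionReport-class]. Refuses to compute (error) when
#'   fewer than 5 scans are evaluable; warns when all observations are
#'   identical (a degenerate single-composition run).
#' @export
uniformityReport <- function(bvals, gStd, og, d = DelayModel()) {
  stopifnot(is(gStd, "GradientProgram"), is(og, "OptimizedGradient"))
  bvals <- sort(as.numeric(bvals))
  if (length(unique(bvals)) == 1L)
    warning("all observations share one composition; ",
            "redistribution metrics are degenerate", call. = FALSE)

  shift <- d@deadVolumeDelay - d@msStartDelay
  prog <- analyticalSegment(program(og))
  std <- analyticalSegment(gStd)

  pred_opt <- predictElution(bvals, prog, d)
  pred_std <- predictElution(bvals, std, d)
  n_excl <- attr(pred_opt, "nExcluded")
  ok <- !is.na(pred_opt) & !is.na(pred_std)
  if (sum(ok) < 5L)
    stop("fewer than 5 evaluable scans; uniformity metrics refused",
         call. = FALSE)
  po <- pred_opt[ok]; ps <- pred_std[ok]

  win_opt <- range(prog@time) + shift
  win_std <- range(std@time) + shift
  s <- length(og@quantileValues) + 1L

  edges_opt <- prog@time + shift
  counts_opt <- .bin_counts(po, edges_opt)
  edges_std <- seq(win_std[1L], win_std[2L], length.out = s + 1L)
  counts_std <- .bin_counts(ps, edges_std)

  new("RedistributionReport",
      predictedRts = po,
      binCounts = counts_opt,
      ksUniform = .ks_uniform(po, win_opt[1L], win_opt[2L]),
      comparison = list(predictedRts = ps, binCounts = counts_std,
                        ksUniform = .ks_uniform(ps, win_std[1L], win_std[2L])),
      nExcluded = as.integer(n_excl),
      window = as.numeric(win_opt),
      provenance = list(nUsed = og@nUsed, sourceRun = og@sourceRun,
                        steps = s,
                        params = list(
                          iPercent = og@params@iPercent,
                          minCharge = og@params@minCharge,
                          includeUnknownCharge = og@params@includeUnknownCharge,
                          stepIntervalMin = og@params@stepIntervalMin,
                          outOfSpanPolicy = og@params@outOfSpanPolicy),
                        delays = list(deadVolumeDelay = d@deadVolumeDelay,
                                      msStartDelay = d@msStartDelay)))
}

# half-open [low, high) bins, final bin closed
.bin_counts <- function(x, edges) {
  idx <- findInterval(x, edges, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), length(edges) - 1L)
  as.integer(tabulate(idx, nbins = length(edges) - 1L))
}

#' Serialize a redistribution report
#'
#' Writes the metrics, bin counts and provenance as JSON and, optionally, the
#' per-scan predicted retention times under the standard and optimized
#' programs as a two-column TSV for plotting.
#'
#' @param report a [RedistributionReport-class].
#' @param jsonPath output path for the JSON report.
#' @param rtsPath optional output path for the predicted-retention-time TSV
#'   (columns `rt_standard_min`, `rt_optimized_min`).
#' @return Invisibly, `jsonPath`.
#' @export
exportReport <- function(report, jsonPath, rtsPath = NULL) {
  stopifnot(is(report, "RedistributionReport"))
  obj <- list(
    ks_uniform_optimized = report@ksUniform,
    ks_uniform_standard = report@comparison$ksUniform,
    bin_counts_optimized = report@binCounts,
    bin_counts_standard = report@comparison$binCounts,
    n_scans = length(report@predictedRts),
    n_excluded = report@nExcluded,
    window_min = report@window,
    provenance = report@provenance)
  jsonlite::write_json(obj, jsonPath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  if (!is.null(rtsPath)) {
    df <- data.frame(rt_standard_min = report@comparison$predictedRts,
                     rt_optimized_min = report@predictedRts)
    utils::write.table(df, rtsPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(jsonPath)
}
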