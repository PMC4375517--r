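#' Export a gradient program for LC control software
#'
#' Two dialects are supported. `"tsv"` writes a tab-separated table with
#' header `time_min<TAB>percent_b`, one breakpoint per line, readable back
#' with [readGradient()]. `"chromeleon_like"` writes a timed command script
#' in the style of Dionex Chromeleon instrument methods (one `%B` setpoint
#' per breakpoint); it is an explicit approximation of that vendor dialect,
#' not a bit-exact rendering, and says so in its header comment. Values are
#' rounded to the dialect precisions at export time only — typical LC input
#' granularity is 0.1 %B — while in-memory programs keep full precision.
#' Output is byte-deterministic for a given gradient.
#'
#' @param og an [OptimizedGradient-class] or a [GradientProgram-class].
#' @param path output path.
#' @param dialect `"tsv"` or `"chromeleon_like"`.
#' @param percentBPrecision decimal places for %B (default 1).
#' @param timePrecision decimal places for time (default 2).
#' @return Invisibly, `path`.
#' @export
exportGradient <- function(og, path, dialect = c("tsv", "chromeleon_like"),
                           percentBPrecision = 1L, timePrecision = 2L) {
  dialect <- match.arg(dialect)
  g <- if (is(og, "OptimizedGradient")) program(og) else og
  stopifnot(is(g, "GradientProgram"),
            percentBPrecision >= 0L, timePrecision >= 0L)
  tfmt <- sprintf("%%.%df", timePrecision)
  bfmt <- sprintf("%%.%df", percentBPrecision)
  lines <- switch(dialect,
    tsv = c("time_min\tpercent_b",
            sprintf(paste0(tfmt, "\t", bfmt), g@time, g@percentB)),
    chromeleon_like = c(
      "; Chromeleon-like gradient command script (approximation of the vendor dialect)",
      sprintf("; program: %s", g@label),
      "; time_min\tcommand",
      sprintf(paste0(tfmt, "\t%%%%B = ", bfmt), g@time, g@percentB)))
  if (dialect == "chromeleon_like")
    lines <- gsub("%%B", "%B", lines, fixed = TRUE)
  con <- tryCatch(file(path, open = "wb"),
                  error = function(e) stop("cannot write to '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Run the whole optimization pipeline
#'
#' Read scan metadata, filter, map to solvent composition, build the
#' equal-fraction stepped gradient, evaluate the redistribution, and
#' optionally export the gradient and report. Per-stage attrition counts and
#' every effective parameter are echoed via `message()` so runs are fully
#' auditable; the output is a pure function of the input file and the
#' configuration.
#'
#' @param input a [ScanTable-class], or a path to an mzML/mzXML file or a
#'   canonical scan-table TSV (dispatched on file extension).
#' @param gradient the standard gradient: a [GradientProgram-class], a path
#'   to a gradient TSV, or a shorthand string like `"0:0,60:40"`.
#' @param d a [DelayModel-class].
#' @param params an [OptimizationParams-class].
#' @param gradientOut optional path for the exported optimized gradient.
#' @param dialect export dialect, see [exportGradient()].
#' @param reportJson optional path for the JSON redistribution report.
#' @param reportRts optional path for the predicted-retention-time TSV.
#' @param quiet suppress progress messages.
#' @return A list with elements `optimized` (an [OptimizedGradient-class])
#'   and `report` (a [RedistributionReport-class]).
#' @examples
#' tb <- generateRun(syntheticRunSpec(nScans = 800, rtPreset = "late",
#'                                    seed = 3))
#' res <- runPipeline(tb, "0:0,60:40", quiet = TRUE)
#' res$optimized
#' @export
runPipeline <- function(input, gradient, d = DelayModel(),
                        params = OptimizationParams(), gradientOut = NULL,
                        dialect = "tsv", reportJson = NULL, reportRts = NULL,
                        quiet = FALSE) {
  say <- if (quiet) function(...) invisible(NULL) else
    function(...) message(sprintf(...))

  table <- if (is(input, "ScanTable")) input
    else if (grepl("\\.(mzML|mzXML)$", input, ignore.case = TRUE))
      readMzML(input)
    else readScanTable(input)
  g <- if (is(gradient, "GradientProgram")) gradient
    else if (file.exists(gradient)) readGradient(gradient)
    else parseGradient(gradient)

  say("run '%s': %d scans read", runId(table), length(table))
  say(paste0("parameters: i = %g%%, T = %g min, min charge = %d, ",
             "unknown charge %s, out-of-span policy = %s"),
      params@iPercent, params@stepIntervalMin, params@minCharge,
      if (params@includeUnknownCharge) "kept" else "dropped",
      params@outOfSpanPolicy)
  say("delays: dead volume %g min, MS start %g min",
      d@deadVolumeDelay, d@msStartDelay)

  filtered <- filterScans(table, params)
  at <- filtered@metadata$attrition
  say("attrition: %d read, %d MS2+, %d after charge filter, %d after TIC filter",
      at[["input"]], at[["ms2"]], at[["after_charge"]], at[["after_tic"]])

  b <- scanPercentB(filtered, g, d, policy = params@outOfSpanPolicy)
  if (attr(b, "nOutside") > 0L)
    say("%d scan(s) outside the gradient span (%s)", attr(b, "nOutside"),
        params@outOfSpanPolicy)
  say("N = %d scans drive the optimization", length(b))

  og <- buildOptimizedGradient(b, g, params, sourceRun = runId(table))
  say("optimized program: %d steps, %%B %s",
      length(program(og)@time) - 1L,
      paste(sprintf("%.1f", program(og)@percentB), collapse = " "))

  report <- uniformityReport(b, g, og, d)
  say("KS to uniform: %.4f optimized vs %.4f standard",
      ksUniform(report), report@comparison$ksUniform)

  if (!is.null(gradientOut)) {
    exportGradient(og, gradientOut, dialect = dialect)
    say("gradient written to %s (%s)", gradientOut, dialect)
  }
  if (!is.null(reportJson) || !is.null(reportRts)) {
    if (is.null(reportJson))
      reportJson <- file.path(tempdir(), "msgrad-report.json")
    exportReport(report, reportJson, reportRts)
    say("report written to %s", reportJson)
  }
  list(optimized = og, report = report)
}
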