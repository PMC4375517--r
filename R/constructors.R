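#' Construct a GradientProgram
#'
#' @param time numeric, breakpoint times in minutes (strictly increasing).
#' @param percentB numeric, percent solvent B at each breakpoint.
#' @param label single string describing the program.
#' @param washStart optional time (minutes) at which a trailing
#'   wash/re-equilibration block starts; breakpoints at or after it are not
#'   required to be monotone in %B and are never optimized.
#' @return A [GradientProgram-class] object.
#' @examples
#' g <- GradientProgram(c(0, 60), c(0, 40), label = "0-40%B in 60 min")
#' percentBAt(g, 30)
#' @export
GradientProgram <- function(time, percentB, label = "gradient",
                            washStart = NA_real_) {
  new("GradientProgram", time = as.numeric(time), percentB = as.numeric(percentB),
      label = as.character(label), washStart = as.numeric(washStart))
}

#' Construct a DelayModel
#'
#' @param deadVolumeDelay minutes the pump-programmed composition needs to
#'   reach the column/emitter.
#' @param msStartDelay minutes between pump-program start and MS acquisition
#'   start.
#' @return A [DelayModel-class] object.
#' @export
DelayModel <- function(deadVolumeDelay = 0, msStartDelay = 0) {
  new("DelayModel", deadVolumeDelay = as.numeric(deadVolumeDelay),
      msStartDelay = as.numeric(msStartDelay))
}

#' Construct a ScanTable
#'
#' Rows are re-sorted by retention time (ties broken by `scan_id`) so the
#' container's ordering contract holds however the rows arrive.
#'
#' @param scans `data.frame` with columns `scan_id`, `rt`, `ms_level`, `tic`,
#'   `precursor_charge` (`NA` = unknown).
#' @param runId single string identifying the run.
#' @param runLength acquisition duration in minutes; defaults to the last
#'   retention time.
#' @param metadata list of free-form provenance.
#' @return A [ScanTable-class] object.
#' @export
ScanTable <- function(scans, runId = "run", runLength = NA_real_,
                      metadata = list()) {
  scans <- as.data.frame(scans, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.scan_cols, names(scans))
  if (length(missing_cols))
    stop("scan table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  scans <- scans[.scan_cols]
  scans$scan_id <- as.character(scans$scan_id)
  scans$rt <- as.numeric(scans$rt)
  scans$ms_level <- as.integer(scans$ms_level)
  scans$tic <- as.numeric(scans$tic)
  scans$precursor_charge <- as.integer(scans$precursor_charge)
  scans <- scans[order(scans$rt, scans$scan_id), , drop = FALSE]
  rownames(scans) <- NULL
  if (is.na(runLength) && nrow(scans)) runLength <- max(scans$rt)
  new("ScanTable", runId = as.character(runId), scans = scans,
      runLength = as.numeric(runLength), metadata = metadata)
}

#' Construct optimization parameters
#'
#' @param iPercent percentage of charge-surviving MS/MS scans kept (highest
#'   TIC first). Default 50.
#' @param minCharge minimum known precursor charge kept. Default 2 (singly
#'   charged precursors excluded).
#' @param includeUnknownCharge keep unknown-charge scans? Default `FALSE`.
#' @param stepIntervalMin step resolution T in minutes. Default 5.
#' @param outOfSpanPolicy `"drop"` (default) or `"clamp"` for scans eluting
#'   outside the declared gradient span.
#' @return An [OptimizationParams-class] object.
#' @export
OptimizationParams <- function(iPercent = 50, minCharge = 2L,
                               includeUnknownCharge = FALSE,
                               stepIntervalMin = 5,
                               outOfSpanPolicy = c("drop", "clamp")) {
  outOfSpanPolicy <- match.arg(outOfSpanPolicy)
  new("OptimizationParams", iPercent = as.numeric(iPercent),
      minCharge = as.integer(minCharge),
      includeUnknownCharge = isTRUE(includeUnknownCharge),
      stepIntervalMin = as.numeric(stepIntervalMin),
      outOfSpanPolicy = outOfSpanPolicy)
}

## ---- accessors ----

#' @rdname ScanTable-class
#' @export
setMethod("scans", "ScanTable", function(x) x@scans)

#' @rdname ScanTable-class
#' @export
setMethod("runId", "ScanTable", function(x) x@runId)

#' @rdname ScanTable-class
#' @export
setMethod("runLength", "ScanTable", function(x) x@runLength)

#' @rdname ScanTable-class
#' @export
setMethod("length", "ScanTable", function(x) nrow(x@scans))

#' @rdname GradientProgram-class
#' @export
setMethod("breakpoints", "GradientProgram", function(x)
  data.frame(time_min = x@time, percent_b = x@percentB))

#' @rdname OptimizedGradient-class
#' @export
setMethod("program", "OptimizedGradient", function(x) x@program)

#' @rdname OptimizedGradient-class
#' @export
setMethod("nUsed", "OptimizedGradient", function(x) x@nUsed)

#' @rdname OptimizedGradient-class
#' @export
setMethod("quantileValues", "OptimizedGradient", function(x) x@quantileValues)

#' @rdname OptimizedGradient-class
#' @export
setMethod("optimizationParams", "OptimizedGradient", function(x) x@params)

#' @rdname RedistributionReport-class
#' @export
setMethod("ksUniform", "RedistributionReport", function(x) x@ksUniform)

#' @rdname RedistributionReport-class
#' @export
setMethod("binCounts", "RedistributionReport", function(x) x@binCounts)

#' @rdname RedistributionReport-class
#' @export
setMethod("predictedRts", "RedistributionReport", function(x) x@predictedRts)

## ---- show ----

setMethod("show", "ScanTable", function(object) {
  sc <- object@scans
  cat(sprintf("ScanTable '%s': %d scans (%d MS2+), %.2f min run\n",
              object@runId, nrow(sc), sum(sc$ms_level >= 2), object@runLength))
  if (nrow(sc)) {
    ch <- sc$precursor_charge[sc$ms_level >= 2]
    cat(sprintf("  rt range %.2f-%.2f min; charge known for %d/%d MS2+ scans\n",
                min(sc$rt), max(sc$rt), sum(!is.na(ch)), length(ch)))
  }
  invisible(NULL)
})

setMethod("show", "GradientProgram", function(object) {
  cat(sprintf("GradientProgram '%s': %d breakpoints, %.2f-%.2f min, %.1f-%.1f %%B%s\n",
              object@label, length(object@time), min(object@time),
              max(object@time), object@percentB[1L],
              object@percentB[length(object@percentB)],
              if (is.na(object@washStart)) "" else
                sprintf(" (wash from %.2f min)", object@washStart)))
  invisible(NULL)
})

setMethod("show", "DelayModel", function(object) {
  cat(sprintf("DelayModel: dead volume %.2f min, MS start %.2f min\n",
              object@deadVolumeDelay, object@msStartDelay))
  invisible(NULL)
})

setMethod("show", "OptimizationParams", function(object) {
  cat(sprintf(paste0("OptimizationParams: i = %g%%, min charge = %d",
                     " (unknown charge %s), T = %g min, out-of-span = %s\n"),
              object@iPercent, object@minCharge,
              if (object@includeUnknownCharge) "kept" else "dropped",
              object@stepIntervalMin, object@outOfSpanPolicy))
  invisible(NULL)
})

setMethod("show", "OptimizedGradient", function(object) {
  cat(sprintf("OptimizedGradient from run '%s' (N = %d scans)\n",
              object@sourceRun, object@nUsed))
  cat(sprintf("  %d steps; %%B breakpoints: %s\n",
              length(object@program@time) - 1L,
              paste(sprintf("%.1f", object@program@percentB), collapse = ", ")))
  show(object@params)
  invisible(NULL)
})

setMethod("show", "RedistributionReport", function(object) {
  cat(sprintf("RedistributionReport: %d scans over %.2f-%.2f min\n",
              length(object@predictedRts), object@window[1L], object@window[2L]))
  cat(sprintf("  KS to uniform: %.4f optimized vs %.4f standard\n",
              object@ksUniform, object@comparison$ksUniform))
  if (object@nExcluded > 0L)
    cat(sprintf("  %d scan(s) outside the candidate %%B range excluded\n",
                object@nExcluded))
  invisible(NULL)
})

setMethod("show", "SyntheticRunSpec", function(object) {
  cat(sprintf("SyntheticRunSpec: %d MS2 scans (+%d MS1) over %.1f min, rt = %s, seed = %d\n",
              object@nScans, object@nMs1, object@runLength,
              object@rtDistribution$kind, object@seed))
  invisible(NULL)
})
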