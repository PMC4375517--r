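#' @import methods
NULL

#' Piecewise-linear solvent program
#'
#' A `GradientProgram` describes a binary-pump solvent program as ordered
#' breakpoints of pump time (minutes) versus percent solvent B. Between
#' breakpoints the composition is linearly interpolated; this is the idealised
#' program the pump is asked to deliver, not a model of mixing dynamics.
#'
#' The analytical segment (where analytes elute and data are acquired) must be
#' non-decreasing in %B. A trailing wash/re-equilibration block, which
#' typically ramps to high organic and back down, can be declared via
#' `washStart`: breakpoints at `time >= washStart` are exempt from the
#' monotonicity check and are carried through optimization verbatim.
#'
#' @slot time numeric, strictly increasing breakpoint times in minutes.
#' @slot percentB numeric in `[0, 100]`, same length as `time`.
#' @slot label character scalar, free-text description.
#' @slot washStart numeric scalar; time at which the wash block starts,
#'   `NA` when the whole program is analytical.
#'
#' @seealso [GradientProgram()], [percentBAt()], [timeAtPercentB()]
#' @exportClass GradientProgram
setClass("GradientProgram",
  representation(time = "numeric", percentB = "numeric",
                 label = "character", washStart = "numeric"),
  prototype(label = "gradient", washStart = NA_real_))

setValidity("GradientProgram", function(object) {
  msg <- character()
  t <- object@time; b <- object@percentB
  if (length(t) < 2L) msg <- c(msg, "need at least 2 breakpoints")
  if (length(t) != length(b)) msg <- c(msg, "time and percentB lengths differ")
  if (anyNA(t) || anyNA(b)) msg <- c(msg, "breakpoints must be finite")
  else {
    if (any(t < 0)) msg <- c(msg, "times must be >= 0")
    if (any(diff(t) <= 0)) msg <- c(msg, "times must be strictly increasing")
    if (any(b < 0 | b > 100)) msg <- c(msg, "percentB must be in [0, 100]")
    ana <- if (is.na(object@washStart)) rep(TRUE, length(t)) else t <= object@washStart
    if (sum(ana) >= 2L && any(diff(b[ana]) < 0))
      msg <- c(msg, "percentB must be non-decreasing over the analytical segment")
  }
  if (length(object@label) != 1L) msg <- c(msg, "label must be a single string")
  if (length(object@washStart) != 1L) msg <- c(msg, "washStart must be a single value")
  if (length(msg)) msg else TRUE
})

#' Delay model relating MS retention time to pump-programmed composition
#'
#' Two non-negative offsets connect the MS retention-time clock to the pump
#' program. `deadVolumeDelay` is the plumbing lag: the composition observed at
#' the column/emitter at scan time `rt` was programmed `deadVolumeDelay`
#' minutes earlier. `msStartDelay` is the offset between pump-program start
#' and the MS acquisition clock zero. The effective pump time of a scan is
#' `rt + msStartDelay - deadVolumeDelay`; only this difference matters.
#'
#' @slot deadVolumeDelay numeric scalar, minutes, >= 0.
#' @slot msStartDelay numeric scalar, minutes, >= 0.
#' @exportClass DelayModel
setClass("DelayModel",
  representation(deadVolumeDelay = "numeric", msStartDelay = "numeric"),
  prototype(deadVolumeDelay = 0, msStartDelay = 0))

setValidity("DelayModel", function(object) {
  d <- c(object@deadVolumeDelay, object@msStartDelay)
  if (length(d) != 2L || anyNA(d) || any(!is.finite(d)))
    return("delays must be single finite values")
  if (any(d < 0)) return("delays must be non-negative")
  TRUE
})

#' MS/MS scan metadata for one LC-MS/MS run
#'
#' Container for per-scan acquisition metadata: retention time (minutes),
#' MS level, total ion current and precursor charge. Scans are kept sorted by
#' retention time (ties broken by scan identifier) so downstream operations
#' are deterministic. Unknown precursor charge (MS1 scans, or MS2 scans whose
#' precursor record carries no charge) is encoded as `NA`.
#'
#' @slot runId character scalar identifying the run.
#' @slot scans `data.frame` with columns `scan_id` (character), `rt` (minutes),
#'   `ms_level` (integer >= 1), `tic` (>= 0), `precursor_charge`
#'   (integer >= 1 or `NA`).
#' @slot runLength numeric scalar, acquisition duration in minutes
#'   (>= max retention time).
#' @slot metadata list, free-form provenance (e.g. filter attrition counts).
#' @seealso [ScanTable()], [readMzML()], [readScanTable()], [filterScans()]
#' @exportClass ScanTable
setClass("ScanTable",
  representation(runId = "character", scans = "data.frame",
                 runLength = "numeric", metadata = "list"),
  prototype(runId = "run", runLength = NA_real_, metadata = list()))

.scan_cols <- c("scan_id", "rt", "ms_level", "tic", "precursor_charge")

setValidity("ScanTable", function(object) {
  msg <- character()
  sc <- object@scans
  missing_cols <- setdiff(.scan_cols, names(sc))
  if (length(missing_cols))
    return(paste("scans is missing columns:", paste(missing_cols, collapse = ", ")))
  if (nrow(sc)) {
    if (anyNA(sc$rt) || any(sc$rt < 0)) msg <- c(msg, "rt must be >= 0")
    if (anyNA(sc$tic) || any(sc$tic < 0)) msg <- c(msg, "tic must be >= 0")
    if (anyNA(sc$ms_level) || any(sc$ms_level < 1)) msg <- c(msg, "ms_level must be >= 1")
    ch <- sc$precursor_charge
    if (any(!is.na(ch) & ch < 1)) msg <- c(msg, "known precursor_charge must be >= 1")
    if (is.unsorted(sc$rt)) msg <- c(msg, "scans must be sorted by rt")
    if (!is.na(object@runLength) && object@runLength < max(sc$rt))
      msg <- c(msg, "runLength must be >= last rt")
  }
  if (length(object@runId) != 1L) msg <- c(msg, "runId must be a single string")
  if (length(msg)) msg else TRUE
})

#' Parameters of the gradient optimization
#'
#' Defaults follow common practice for complex lysate fractions on Orbitrap
#' class instruments: keep the top 50% of MS/MS scans by TIC (the fraction of
#' spectra typically identifiable), exclude singly charged precursors (largely
#' chemical contaminants), and build the stepped gradient at 5-minute
#' resolution.
#'
#' @slot iPercent numeric in (0, 100]; percentage of charge-surviving MS/MS
#'   scans retained, the highest by TIC. Default 50.
#' @slot minCharge integer >= 1; scans with known precursor charge below this
#'   are excluded. Default 2.
#' @slot includeUnknownCharge logical; keep scans whose precursor charge is
#'   unknown. Default `FALSE`.
#' @slot stepIntervalMin numeric > 0; step resolution T in minutes. Default 5.
#' @slot outOfSpanPolicy `"drop"` or `"clamp"`; how scans eluting outside the
#'   declared gradient span are treated. Default `"drop"`.
#' @seealso [OptimizationParams()], [filterScans()], [buildOptimizedGradient()]
#' @exportClass OptimizationParams
setClass("OptimizationParams",
  representation(iPercent = "numeric", minCharge = "integer",
                 includeUnknownCharge = "logical", stepIntervalMin = "numeric",
                 outOfSpanPolicy = "character"),
  prototype(iPercent = 50, minCharge = 2L, includeUnknownCharge = FALSE,
            stepIntervalMin = 5, outOfSpanPolicy = "drop"))

setValidity("OptimizationParams", function(object) {
  msg <- character()
  if (!(length(object@iPercent) == 1L && is.finite(object@iPercent) &&
        object@iPercent > 0 && object@iPercent <= 100))
    msg <- c(msg, "iPercent must be a single value in (0, 100]")
  if (!(length(object@minCharge) == 1L && !is.na(object@minCharge) &&
        object@minCharge >= 1L))
    msg <- c(msg, "minCharge must be an integer >= 1")
  if (!(length(object@stepIntervalMin) == 1L && is.finite(object@stepIntervalMin) &&
        object@stepIntervalMin > 0))
    msg <- c(msg, "stepIntervalMin must be > 0")
  if (!object@outOfSpanPolicy %in% c("drop", "clamp"))
    msg <- c(msg, "outOfSpanPolicy must be 'drop' or 'clamp'")
  if (length(msg)) msg else TRUE
})

#' An optimized stepped gradient with provenance
#'
#' Result of [buildOptimizedGradient()]: the stepped program itself plus
#' everything needed to reproduce it — the number of scans that drove the
#' construction (N), the interior %B quantiles, the parameters used, the
#' standard program it replaces and the source run identifier.
#'
#' @slot program [GradientProgram-class]; the optimized stepped program.
#' @slot standard [GradientProgram-class]; the standard program it was built
#'   against.
#' @slot nUsed integer; N, the number of %B observations used.
#' @slot quantileValues numeric; the S - 1 interior %B quantiles.
#' @slot params [OptimizationParams-class] used.
#' @slot sourceRun character; run identifier of the driving acquisition.
#' @exportClass OptimizedGradient
setClass("OptimizedGradient",
  representation(program = "GradientProgram", standard = "GradientProgram",
                 nUsed = "integer", quantileValues = "numeric",
                 params = "OptimizationParams", sourceRun = "character"))

#' Elution-redistribution diagnostics for a candidate gradient
#'
#' Quantifies how evenly scans would elute under a candidate (optimized)
#' gradient compared to the standard one, using the characteristic-composition
#' elution model: a precursor elutes when the delivered composition reaches
#' the %B at which it was observed to elute on the standard gradient.
#'
#' @slot predictedRts numeric; predicted elution times (minutes) under the
#'   candidate gradient.
#' @slot binCounts integer; scans per step-interval time bin.
#' @slot ksUniform numeric; Kolmogorov-Smirnov distance of predicted elution
#'   times from the uniform distribution over the analytical window.
#' @slot comparison list with elements `predictedRts`, `binCounts`,
#'   `ksUniform` for the standard gradient.
#' @slot nExcluded integer; scans outside the candidate program's %B range,
#'   excluded from the metrics.
#' @slot window numeric(2); analytical time window the metrics refer to.
#' @slot provenance list; parameters and run metadata.
#' @seealso [uniformityReport()], [predictElution()]
#' @exportClass RedistributionReport
setClass("RedistributionReport",
  representation(predictedRts = "numeric", binCounts = "integer",
                 ksUniform = "numeric", comparison = "list",
                 nExcluded = "integer", window = "numeric",
                 provenance = "list"))

#' Specification of a synthetic LC-MS/MS run
#'
#' Describes a seeded synthetic run: how many MS/MS scans, over what duration,
#' with what retention-time distribution (emulating the hydrophobicity bias of
#' pre-fractionated samples), what two-component lognormal TIC structure
#' (an "identifiable" high-TIC component and a low-TIC noise component), and
#' what precursor charge mix. Charges are drawn independently of retention
#' time and TIC.
#'
#' @slot nScans integer >= 1; number of MS/MS scans.
#' @slot runLength numeric; acquisition duration in minutes.
#' @slot rtDistribution list; `list(kind = "uniform")`,
#'   `list(kind = "beta", shape1 =, shape2 =)` scaled to the run window, or
#'   `list(kind = "mixture", shape1 =, shape2 =, shape3 =, shape4 =, p =)`
#'   for a two-component beta mixture.
#' @slot ticModel list with `pId` (mixing fraction of the high-TIC component),
#'   `meanlogHigh`, `sdlogHigh`, `meanlogLow`, `sdlogLow`.
#' @slot chargeProbs named numeric over `c("1","2","3","4","unknown")`,
#'   summing to 1.
#' @slot nMs1 integer >= 0; number of evenly spaced MS1 survey scans to
#'   interleave.
#' @slot seed integer; RNG seed, making generation fully deterministic.
#' @seealso [syntheticRunSpec()], [generateRun()]
#' @exportClass SyntheticRunSpec
setClass("SyntheticRunSpec",
  representation(nScans = "integer", runLength = "numeric",
                 rtDistribution = "list", ticModel = "list",
                 chargeProbs = "numeric", nMs1 = "integer", seed = "integer"))

setValidity("SyntheticRunSpec", function(object) {
  msg <- character()
  if (object@nScans < 1L) msg <- c(msg, "nScans must be >= 1")
  if (!(is.finite(object@runLength) && object@runLength > 0))
    msg <- c(msg, "runLength must be > 0")
  p <- object@chargeProbs
  if (!setequal(names(p), c("1", "2", "3", "4", "unknown")))
    msg <- c(msg, "chargeProbs must be named over 1,2,3,4,unknown")
  else if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
    msg <- c(msg, "chargeProbs must be non-negative and sum to 1")
  if (!object@rtDistribution$kind %in% c("uniform", "beta", "mixture"))
    msg <- c(msg, "rtDistribution kind must be uniform, beta or mixture")
  tm <- object@ticModel
  if (!all(c("pId", "meanlogHigh", "sdlogHigh", "meanlogLow", "sdlogLow") %in% names(tm)))
    msg <- c(msg, "ticModel must name pId, meanlogHigh, sdlogHigh, meanlogLow, sdlogLow")
  else if (tm$pId < 0 || tm$pId > 1) msg <- c(msg, "pId must be in [0, 1]")
  if (object@nMs1 < 0L) msg <- c(msg, "nMs1 must be >= 0")
  if (length(msg)) msg else TRUE
})
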