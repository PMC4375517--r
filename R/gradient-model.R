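#' Solvent composition at a pump time
#'
#' Linear interpolation of a [GradientProgram-class] at one or more pump
#' times. Exact at breakpoints.
#'
#' @param g a [GradientProgram-class].
#' @param pumpTime numeric, minutes on the pump clock; every value must lie
#'   within the program's time span.
#' @return numeric, percent solvent B at each `pumpTime`.
#' @seealso [rtToPercentB()] for the delay-aware mapping from MS retention
#'   time, [timeAtPercentB()] for the inverse.
#' @export
percentBAt <- function(g, pumpTime) {
  stopifnot(is(g, "GradientProgram"))
  pumpTime <- as.numeric(pumpTime)
  lo <- g@time[1L]; hi <- g@time[length(g@time)]
  bad <- !is.na(pumpTime) & (pumpTime < lo | pumpTime > hi)
  if (any(bad))
    stop(sprintf("pump time %g min outside the program span [%g, %g]",
                 pumpTime[bad][1L], lo, hi), call. = FALSE)
  stats::approx(g@time, g@percentB, xout = pumpTime, ties = "ordered")$y
}

#' Map MS retention time to the eluting solvent composition
#'
#' Converts a scan's retention time to the percent solvent B at which its
#' precursor eluted. The composition seen at the emitter at MS time `rt` was
#' programmed at pump time `tau = rt + msStartDelay - deadVolumeDelay`; scans
#' whose effective pump time falls outside the program span (elution during
#' loading or wash) yield `NA`, the "outside" sentinel — an expected value,
#' not an error, so callers choose their own policy (see
#' [OptimizationParams()]'s `outOfSpanPolicy`).
#'
#' @param rt numeric, MS retention time(s) in minutes (>= 0).
#' @param g a [GradientProgram-class], the standard program the run used.
#' @param d a [DelayModel-class].
#' @return numeric, percent solvent B, `NA` where the scan eluted outside the
#'   program span.
#' @export
rtToPercentB <- function(rt, g, d = DelayModel()) {
  stopifnot(is(g, "GradientProgram"), is(d, "DelayModel"))
  tau <- as.numeric(rt) + d@msStartDelay - d@deadVolumeDelay
  stats::approx(g@time, g@percentB, xout = tau, ties = "ordered", rule = 1L)$y
}

#' Earliest pump time at which a program reaches a composition
#'
#' Inverts the analytical segment of a non-decreasing program: for each
#' percent-B value, the earliest pump time at which the program attains it.
#' For an isocratic (flat) stretch exactly at the queried composition the
#' stretch's start time is returned — the physical first crossing.
#'
#' @param g a [GradientProgram-class], non-decreasing over its analytical
#'   segment.
#' @param b numeric, percent solvent B; must lie within the analytical
#'   segment's %B range.
#' @return numeric, minutes on the pump clock.
#' @export
timeAtPercentB <- function(g, b) {
  stopifnot(is(g, "GradientProgram"))
  ga <- analyticalSegment(g)
  tt <- ga@time; bb <- ga@percentB
  b <- as.numeric(b)
  out <- numeric(length(b))
  for (q in seq_along(b)) {
    if (is.na(b[q]) || b[q] < bb[1L] || b[q] > bb[length(bb)])
      stop(sprintf("percent B %g outside the program's range [%g, %g]",
                   b[q], bb[1L], bb[length(bb)]), call. = FALSE)
    k <- which(bb >= b[q])[1L]
    out[q] <- if (k == 1L) tt[1L] else
      tt[k - 1L] + (b[q] - bb[k - 1L]) / (bb[k] - bb[k - 1L]) * (tt[k] - tt[k - 1L])
  }
  out
}

#' Analytical segment of a gradient program
#'
#' Drops any declared wash/re-equilibration breakpoints (`washStart`),
#' returning the portion of the program over which analytes elute and
#' optimization operates.
#'
#' @param g a [GradientProgram-class].
#' @return A [GradientProgram-class] restricted to `time <= washStart`
#'   (the whole program when no wash is declared).
#' @export
analyticalSegment <- function(g) {
  stopifnot(is(g, "GradientProgram"))
  if (is.na(g@washStart)) return(g)
  keep <- g@time <= g@washStart
  if (sum(keep) < 2L)
    stop("analytical segment has fewer than 2 breakpoints", call. = FALSE)
  GradientProgram(g@time[keep], g@percentB[keep], label = g@label)
}

.analytical_duration <- function(g) {
  ga <- analyticalSegment(g)
  ga@time[length(ga@time)] - ga@time[1L]
}

#' Read or parse a gradient declaration
#'
#' `readGradient()` reads a two-column tab-separated declaration with header
#' `time_min<TAB>percent_b`. `parseGradient()` parses the compact shorthand
#' `"0:0,60:40"` (comma-separated `time:percentB` pairs) used on the command
#' line.
#'
#' @param path path to a TSV gradient declaration.
#' @param label program label; defaults to the file name or the string form.
#' @param washStart optional wash start time (minutes), see
#'   [GradientProgram()].
#' @return A [GradientProgram-class].
#' @export
readGradient <- function(path, label = basename(path), washStart = NA_real_) {
  if (!file.exists(path))
    stop("gradient declaration not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("time_min", "percent_b")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("gradient declaration ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  GradientProgram(df$time_min, df$percent_b, label = label,
                  washStart = washStart)
}

#' @rdname readGradient
#' @param spec shorthand string, e.g. `"0:0,60:40"`.
#' @export
parseGradient <- function(spec, label = spec, washStart = NA_real_) {
  pairs <- strsplit(strsplit(spec, ",", fixed = TRUE)[[1L]], ":", fixed = TRUE)
  if (!length(pairs) || any(lengths(pairs) != 2L))
    stop("cannot parse gradient shorthand '", spec,
         "'; expected time:percentB pairs like '0:0,60:40'", call. = FALSE)
  m <- suppressWarnings(vapply(pairs, as.numeric, numeric(2L)))
  if (anyNA(m))
    stop("non-numeric value in gradient shorthand '", spec, "'", call. = FALSE)
  GradientProgram(m[1L, ], m[2L, ], label = label, washStart = washStart)
}
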