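#' @rdname ScanTable-class
#' @param x,object an object.
#' @export
setGeneric("scans", function(x) standardGeneric("scans"))

#' @rdname ScanTable-class
#' @export
setGeneric("runId", function(x) standardGeneric("runId"))

#' @rdname ScanTable-class
#' @export
setGeneric("runLength", function(x) standardGeneric("runLength"))

#' @rdname GradientProgram-class
#' @param x an object.
#' @export
setGeneric("breakpoints", function(x) standardGeneric("breakpoints"))

#' @rdname OptimizedGradient-class
#' @param x an object.
#' @export
setGeneric("program", function(x) standardGeneric("program"))

#' @rdname OptimizedGradient-class
#' @export
setGeneric("nUsed", function(x) standardGeneric("nUsed"))

#' @rdname OptimizedGradient-class
#' @export
setGeneric("quantileValues", function(x) standardGeneric("quantileValues"))

#' @rdname OptimizedGradient-class
#' @export
setGeneric("optimizationParams", function(x) standardGeneric("optimizationParams"))

#' @rdname RedistributionReport-class
#' @param x an object.
#' @export
setGeneric("ksUniform", function(x) standardGeneric("ksUniform"))

#' @rdname RedistributionReport-class
#' @export
setGeneric("binCounts", function(x) standardGeneric("binCounts"))

#' @rdname RedistributionReport-class
#' @export
setGeneric("predictedRts", function(x) standardGeneric("predictedRts"))
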