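#' @rdname applyClock
#' @export
setGeneric("applyClock", function(clock, betas, ...)
  standardGeneric("applyClock"))

#' @rdname maskProbes
#' @export
setGeneric("maskProbes", function(x, probes, ...)
  standardGeneric("maskProbes"))

#' Per-sample DNA methylation age in years
#'
#' @param x a \linkS4class{ClockAges} object.
#' @return named numeric vector of DNAm ages (years), one per sample.
#' @seealso \code{\link{applyClock}}
#' @export
setGeneric("dnamAge", function(x) standardGeneric("dnamAge"))

#' Per-sample transformed score (linear predictor)
#'
#' The clock's linear predictor before the inverse age transform: for
#' \code{"horvath"} clocks this is on the transformed-age scale, for
#' \code{"identity"} clocks it equals the DNAm age.
#'
#' @param x a \linkS4class{ClockAges} object.
#' @return named numeric vector, one value per sample.
#' @export
setGeneric("transformedScore", function(x) standardGeneric("transformedScore"))

#' @rdname ClockDefinition-accessors
#' @export
setGeneric("clockName", function(x) standardGeneric("clockName"))

#' @rdname ClockDefinition-accessors
#' @export
setGeneric("clockWeights", function(x) standardGeneric("clockWeights"))

#' @rdname ClockDefinition-accessors
#' @export
setGeneric("clockIntercept", function(x) standardGeneric("clockIntercept"))

#' @rdname ClockDefinition-accessors
#' @export
setGeneric("clockProbes", function(x) standardGeneric("clockProbes"))

#' @rdname ClockDefinition-accessors
#' @export
setGeneric("clockSize", function(x) standardGeneric("clockSize"))

#' @rdname ClockDefinition-accessors
#' @export
setGeneric("clockTransform", function(x) standardGeneric("clockTransform"))

#' @rdname BetaMatrix-accessors
#' @export
setGeneric("betaValues", function(x) standardGeneric("betaValues"))

#' @rdname BetaMatrix-accessors
#' @export
setGeneric("probeIDs", function(x) standardGeneric("probeIDs"))

#' @rdname BetaMatrix-accessors
#' @export
setGeneric("sampleIDs", function(x) standardGeneric("sampleIDs"))

#' @rdname BetaMatrix-accessors
#' @export
setGeneric("sampleAnnotation", function(x) standardGeneric("sampleAnnotation"))
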