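#' Construct a clock definition
#'
#' @param name label for the clock.
#' @param weights named numeric vector of per-probe coefficients (names are
#'   probe IDs, treated as opaque case-sensitive strings).
#' @param intercept intercept of the linear predictor; transformed-age units
#'   for \code{"horvath"} clocks, years for \code{"identity"} clocks.
#' @param transform \code{"horvath"} (log-linear age transform applied to the
#'   score) or \code{"identity"}.
#' @param adultAge knee of the age transform in years; only used when
#'   \code{transform = "horvath"}.
#' @return a \linkS4class{ClockDefinition}.
#' @examples
#' toy <- ClockDefinition("toy", c(p1 = 1, p2 = -0.5),
#'                        intercept = 0.5, transform = "identity")
#' clockSize(toy)
#' @export
ClockDefinition <- function(name, weights, intercept = 0,
                            transform = c("horvath", "identity"),
                            adultAge = 20) {
  transform <- match.arg(transform)
  new("ClockDefinition",
      name = as.character(name),
      intercept = as.numeric(intercept),
      weights = weights,
      transform = transform,
      adultAge = as.numeric(adultAge))
}

#' Accessors for ClockDefinition objects
#'
#' @param x a \linkS4class{ClockDefinition}.
#' @return \code{clockName}: the label; \code{clockWeights}: the named
#'   coefficient vector; \code{clockIntercept}: the intercept;
#'   \code{clockProbes}: the probe IDs; \code{clockSize}: the number of
#'   probes; \code{clockTransform}: \code{"horvath"} or \code{"identity"}.
#' @name ClockDefinition-accessors
NULL

#' @rdname ClockDefinition-accessors
setMethod("clockName", "ClockDefinition", function(x) x@name)

#' @rdname ClockDefinition-accessors
setMethod("clockWeights", "ClockDefinition", function(x) x@weights)

#' @rdname ClockDefinition-accessors
setMethod("clockIntercept", "ClockDefinition", function(x) x@intercept)

#' @rdname ClockDefinition-accessors
setMethod("clockProbes", "ClockDefinition", function(x) names(x@weights))

#' @rdname ClockDefinition-accessors
setMethod("clockSize", "ClockDefinition", function(x) length(x@weights))

#' @rdname ClockDefinition-accessors
setMethod("clockTransform", "ClockDefinition", function(x) x@transform)

setMethod("show", "ClockDefinition", function(object) {
  cat("ClockDefinition \"", object@name, "\"\n", sep = "")
  cat("  probes:    ", length(object@weights), "\n", sep = "")
  cat("  intercept: ", format(object@intercept), "\n", sep = "")
  cat("  transform: ", object@transform,
      if (identical(object@transform, "horvath"))
        paste0(" (adultAge = ", format(object@adultAge), ")") else "",
      "\n", sep = "")
})

#' Compare a clock's probe set against an array manifest
#'
#' Lists the clock CpGs absent from a platform manifest -- e.g. the 17 of the
#' 353 Horvath-clock CpGs (4.8\%) and 6 of the 71 Hannum-clock CpGs (8.5\%)
#' that the Illumina EPIC (850k) manifest dropped relative to the 450k
#' design.
#'
#' @param clock a \linkS4class{ClockDefinition}.
#' @param manifestProbeIDs character vector of probe IDs present on the
#'   platform.
#' @return list with elements \code{clock} (name), \code{clockSize},
#'   \code{missingProbes} (IDs absent from the manifest), \code{nMissing} and
#'   \code{fraction} (\code{nMissing / clockSize}).
#' @examples
#' clk <- ClockDefinition("toy", c(a = 1, b = 2, c = 3), transform = "identity")
#' diffClockManifest(clk, c("a", "c"))
#' @export
diffClockManifest <- function(clock, manifestProbeIDs) {
  stopifnot(is(clock, "ClockDefinition"))
  manifestProbeIDs <- as.character(manifestProbeIDs)
  if (!length(manifestProbeIDs))
    stop("the manifest probe set must be non-empty", call. = FALSE)
  missing <- setdiff(clockProbes(clock), manifestProbeIDs)
  list(clock = clockName(clock),
       clockSize = clockSize(clock),
       missingProbes = missing,
       nMissing = length(missing),
       fraction = length(missing) / clockSize(clock))
}
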