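#' The log-linear age transform of the Horvath clock
#'
#' Chronological age is mapped to the scale on which the Horvath clock is
#' linear:
#' \deqn{F(a) = \log(a + 1) - \log(A + 1) \quad (a \le A)}
#' \deqn{F(a) = (a - A)/(A + 1) \quad (a > A)}
#' where \eqn{A} is \code{adultAge}.  The transform is continuous and
#' strictly increasing, with \eqn{F(A) = 0}; it compresses the fast
#' methylation dynamics of development (logarithmic below the knee) and is
#' linear through adulthood.  Natural logarithms throughout.
#'
#' @param age chronological age(s) in years; must be non-negative.
#' @param adultAge knee of the transform in years (default 20, the
#'   conventional cutoff).
#' @return transformed age(s), same length as \code{age}.
#' @examples
#' transformAge(20)            # 0 at the knee
#' transformAge(41)            # (41 - 20) / 21 = 1
#' transformAge(0)             # -log(21)
#' @seealso \code{\link{inverseTransformAge}}
#' @export
transformAge <- function(age, adultAge = 20) {
  .checkAdultAge(adultAge)
  if (!is.numeric(age))
    stop("'age' must be numeric", call. = FALSE)
  if (any(age < 0, na.rm = TRUE))
    stop("chronological ages must be non-negative", call. = FALSE)
  ifelse(age <= adultAge,
         log(age + 1) - log(adultAge + 1),
         (age - adultAge) / (adultAge + 1))
}

#' Inverse of the log-linear age transform
#'
#' Maps a transformed score back to years:
#' \eqn{(A + 1)e^{m} - 1} for \eqn{m \le 0} and \eqn{A + m(A + 1)} for
#' \eqn{m > 0}.  Defined on all reals (large negative scores map towards
#' \eqn{-1}), and inverts \code{\link{transformAge}} exactly on
#' non-negative ages.
#'
#' @param score transformed score(s).
#' @param adultAge knee of the transform in years (default 20).
#' @return age(s) in years.
#' @examples
#' inverseTransformAge(0)      # 20
#' inverseTransformAge(1)      # 41
#' inverseTransformAge(transformAge(7.5))  # 7.5
#' @export
inverseTransformAge <- function(score, adultAge = 20) {
  .checkAdultAge(adultAge)
  if (!is.numeric(score))
    stop("'score' must be numeric", call. = FALSE)
  ifelse(score <= 0,
         (adultAge + 1) * exp(score) - 1,
         adultAge + score * (adultAge + 1))
}

.checkAdultAge <- function(adultAge) {
  if (!is.numeric(adultAge) || length(adultAge) != 1L || is.na(adultAge) ||
      adultAge <= 0)
    stop("'adultAge' must be a single positive number", call. = FALSE)
  invisible(TRUE)
}
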