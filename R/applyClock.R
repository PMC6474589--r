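#' Compute DNA methylation age for every sample
#'
#' Scores a beta matrix with a linear clock: for each sample the transformed
#' score is \eqn{intercept + \sum_j w_j \beta_j} over all clock probes, and
#' the DNAm age is the inverse age transform of that score (the identity for
#' \code{"identity"} clocks).  Clock probes that are absent from the matrix,
#' or present with missing cells, are resolved by the imputation policy
#' before scoring; with \code{policy = NULL} any missing probe is a hard
#' error.  The computation is deterministic given the inputs and policy, and
#' invariant to probe and sample ordering.
#'
#' @param clock a \linkS4class{ClockDefinition}.
#' @param betas a \linkS4class{BetaMatrix}; at least one clock probe must
#'   overlap it unless the policy can synthesise every probe
#'   (reference-mean or constant).
#' @param policy an \linkS4class{ImputationPolicy}, or \code{NULL} for no
#'   imputation.
#' @param ... unused.
#' @return a \linkS4class{ClockAges} with one row per sample, recording the
#'   DNAm age, the transformed score, and how many probes were imputed per
#'   sample (the central provenance when comparing across platforms).
#' @examples
#' m <- matrix(c(0.8, 0.4), 2, 1, dimnames = list(c("p1", "p2"), "s1"))
#' clk <- ClockDefinition("toy", c(p1 = 1, p2 = -0.5), intercept = 0.5,
#'                        transform = "identity")
#' dnamAge(applyClock(clk, BetaMatrix(m)))   # 0.5 + 0.8 - 0.2 = 1.1
#' @rdname applyClock
#' @export
setMethod("applyClock", c("ClockDefinition", "BetaMatrix"),
          function(clock, betas, policy = NULL, ...) {
  w <- clockWeights(clock)
  probes <- names(w)
  b <- assay(betas, "beta")
  present <- intersect(probes, rownames(b))

  canSynthesise <- !is.null(policy) &&
    policy@method %in% c("reference_mean", "constant")
  if (!length(present) && !canSynthesise)
    stop("no clock probe overlaps the beta matrix and the imputation ",
         "policy cannot synthesise absent probes", call. = FALSE)

  sub <- matrix(NA_real_, length(probes), ncol(b),
                dimnames = list(probes, colnames(b)))
  sub[present, ] <- b[present, , drop = FALSE]
  missBefore <- is.na(sub)

  policyLabel <- "none"
  if (any(missBefore)) {
    if (is.null(policy))
      stop("missing clock probe(s) and no imputation policy: ",
           paste(head(probes[rowSums(missBefore) > 0L], 10L), collapse = ", "),
           call. = FALSE)
    policyLabel <- policy@method
    sub <- .applyImputation(sub, policy)
    still <- rownames(sub)[rowSums(is.na(sub)) > 0L]
    if (length(still))
      stop("probe(s) still missing after '", policy@method, "' imputation: ",
           paste(head(still, 10L), collapse = ", "), call. = FALSE)
  }

  score <- clock@intercept + as.vector(crossprod(sub[probes, , drop = FALSE], w))
  age <- if (identical(clock@transform, "horvath"))
    inverseTransformAge(score, clock@adultAge) else score

  ## every probe entering the score is "used"; imputed ones are counted so
  ## n_probes_used - n_probes_imputed = probes observed for that sample
  nImp <- colSums(missBefore)
  res <- data.frame(
    sample_id = colnames(b),
    dnam_age = age,
    transformed_score = score,
    n_probes_used = as.integer(length(probes)),
    n_probes_imputed = as.integer(nImp),
    row.names = NULL, stringsAsFactors = FALSE)

  new("ClockAges",
      results = res,
      clockName = clockName(clock),
      imputationPolicy = policyLabel,
      probesImputed = setdiff(probes, rownames(b)))
})

#' @rdname dnamAge
setMethod("dnamAge", "ClockAges", function(x)
  setNames(x@results$dnam_age, x@results$sample_id))

#' @rdname transformedScore
setMethod("transformedScore", "ClockAges", function(x)
  setNames(x@results$transformed_score, x@results$sample_id))

setMethod("show", "ClockAges", function(object) {
  r <- object@results
  cat("ClockAges: ", nrow(r), " samples scored with clock \"",
      object@clockName, "\"\n", sep = "")
  cat("  DNAm age: ", sprintf("%.2f", mean(r$dnam_age)), " +/- ",
      sprintf("%.2f", stats::sd(r$dnam_age)), " y\n", sep = "")
  cat("  imputation: ", object@imputationPolicy, sep = "")
  if (length(object@probesImputed))
    cat(" (", length(object@probesImputed), " absent probe(s) filled)",
        sep = "")
  cat("\n")
})

#' Coerce ClockAges to a data frame
#'
#' @param x a \linkS4class{ClockAges}.
#' @param ... unused.
#' @return the per-sample results data frame.
#' @export
as.data.frame.ClockAges <- function(x, ...) x@results

setMethod("as.data.frame", "ClockAges", as.data.frame.ClockAges)
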