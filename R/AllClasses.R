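## S4 class definitions.  Validity functions enforce the domain invariants:
## beta values live in [0, 1], probe/sample identifiers are unique, and each
## imputation method carries the parameters it needs.

#' ClockDefinition: a named linear DNA methylation age clock
#'
#' A clock is a set of per-CpG weights, an intercept, and an output
#' transform.  With \code{transform = "identity"} the linear predictor is the
#' DNAm age in years (Hannum-style).  With \code{transform = "horvath"} the
#' linear predictor is on the transformed-age scale and is mapped back to
#' years through \code{\link{inverseTransformAge}} with the clock's
#' \code{adultAge} parameter.
#'
#' Coefficients are deliberately not embedded in the package: published clock
#' tables are loaded with \code{\link{readClock}}, and fully synthetic clocks
#' are produced by \code{\link{constructConsistentClock}}.
#'
#' @slot name single string labelling the clock.
#' @slot intercept intercept of the linear predictor (transformed-age units
#'   for \code{"horvath"} clocks, years for \code{"identity"} clocks).
#' @slot weights named numeric vector of per-probe coefficients; names are
#'   probe IDs and must be unique.
#' @slot transform \code{"identity"} or \code{"horvath"}.
#' @slot adultAge positive knee of the age transform in years (only used by
#'   \code{"horvath"} clocks; 20 by convention).
#'
#' @seealso \code{\link{ClockDefinition}} (constructor),
#'   \code{\link{applyClock}}, \code{\link{diffClockManifest}}
#' @name ClockDefinition-class
#' @rdname ClockDefinition-class
#' @exportClass ClockDefinition
setClass("ClockDefinition",
  slots = c(
    name      = "character",
    intercept = "numeric",
    weights   = "numeric",
    transform = "character",
    adultAge  = "numeric"
  )
)

setValidity("ClockDefinition", function(object) {
  msg <- character()
  if (length(object@name) != 1L || is.na(object@name) || !nzchar(object@name))
    msg <- c(msg, "'name' must be a single non-empty string")
  w <- object@weights
  if (length(w) < 1L)
    msg <- c(msg, "a clock needs at least one probe weight")
  nm <- names(w)
  if (is.null(nm) || anyNA(nm) || any(!nzchar(nm))) {
    msg <- c(msg, "weights must be named by probe ID")
  } else if (anyDuplicated(nm)) {
    msg <- c(msg, "probe IDs in 'weights' must be unique")
  }
  if (length(w) && (anyNA(w) || any(!is.finite(w))))
    msg <- c(msg, "weights must be finite")
  if (length(object@intercept) != 1L || !is.finite(object@intercept))
    msg <- c(msg, "'intercept' must be a single finite number")
  if (length(object@transform) != 1L ||
      !object@transform %in% c("identity", "horvath"))
    msg <- c(msg, "'transform' must be \"identity\" or \"horvath\"")
  if (identical(object@transform, "horvath") &&
      (length(object@adultAge) != 1L || !is.finite(object@adultAge) ||
       object@adultAge <= 0))
    msg <- c(msg, "'adultAge' must be a single positive number for the horvath transform")
  if (length(msg)) msg else TRUE
})

#' BetaMatrix: probes-by-samples methylation fractions
#'
#' Thin \linkS4class{SummarizedExperiment} subclass holding one assay named
#' \code{"beta"} (probes in rows, samples in columns, entries in [0, 1] or
#' \code{NA}).  Per-sample annotation (chronological age in years, sex,
#' platform, dataset label) lives in \code{colData}.
#'
#' @seealso \code{\link{BetaMatrix}} (constructor),
#'   \code{\link{readBetaMatrix}}, \code{\link{maskProbes}}
#' @name BetaMatrix-class
#' @rdname BetaMatrix-class
#' @exportClass BetaMatrix
setClass("BetaMatrix", contains = "SummarizedExperiment")

setValidity("BetaMatrix", function(object) {
  msg <- character()
  if (!"beta" %in% assayNames(object))
    return("a 'beta' assay is required")
  b <- assay(object, "beta")
  if (!is.numeric(b))
    msg <- c(msg, "beta values must be numeric")
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "probe IDs (rownames) must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "sample IDs (colnames) must be present and unique")
  obs <- b[!is.na(b)]
  if (length(obs) && (min(obs) < 0 || max(obs) > 1))
    msg <- c(msg, "non-missing beta values must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' ImputationPolicy: how to resolve missing clock probes before scoring
#'
#' @slot method one of \code{"reference_mean"}, \code{"cohort_mean"},
#'   \code{"knn"}, \code{"constant"}, \code{"none"}.
#' @slot k number of neighbours (kNN only).
#' @slot constantValue fill value in [0, 1] (constant only).
#' @slot referenceMeans named numeric vector of per-probe reference mean
#'   betas (reference_mean only).
#'
#' @seealso \code{\link{imputationPolicy}} (constructor),
#'   \code{\link{applyClock}}
#' @name ImputationPolicy-class
#' @rdname ImputationPolicy-class
#' @exportClass ImputationPolicy
setClass("ImputationPolicy",
  slots = c(
    method        = "character",
    k             = "numeric",
    constantValue = "numeric",
    referenceMeans = "numeric"
  )
)

setValidity("ImputationPolicy", function(object) {
  msg <- character()
  methods <- c("reference_mean", "cohort_mean", "knn", "constant", "none")
  if (length(object@method) != 1L || !object@method %in% methods)
    msg <- c(msg, paste0("'method' must be one of: ",
                         paste(methods, collapse = ", ")))
  if (identical(object@method, "knn") &&
      (length(object@k) != 1L || is.na(object@k) || object@k < 1 ||
       object@k != floor(object@k)))
    msg <- c(msg, "'k' must be a positive integer for method \"knn\"")
  if (identical(object@method, "constant") &&
      (length(object@constantValue) != 1L || is.na(object@constantValue) ||
       object@constantValue < 0 || object@constantValue > 1))
    msg <- c(msg, "'constantValue' must be a single value in [0, 1] for method \"constant\"")
  if (identical(object@method, "reference_mean")) {
    rm <- object@referenceMeans
    if (!length(rm) || is.null(names(rm)) || anyDuplicated(names(rm)))
      msg <- c(msg, "'referenceMeans' must be a non-empty vector uniquely named by probe ID")
    else if (anyNA(rm) || any(rm < 0 | rm > 1))
      msg <- c(msg, "'referenceMeans' values must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' ClockAges: per-sample DNA methylation ages with provenance
#'
#' Result of \code{\link{applyClock}}.  The \code{results} data frame has one
#' row per sample with columns \code{sample_id}, \code{dnam_age} (years),
#' \code{transformed_score} (the linear predictor before the inverse age
#' transform), \code{n_probes_used} and \code{n_probes_imputed}.  Imputed
#' probes count towards \code{n_probes_used}; the imputation policy and any
#' fully absent probes that were filled are recorded so the central confound
#' of cross-array scoring stays visible.
#'
#' @slot results per-sample data frame (see description).
#' @slot clockName name of the clock applied.
#' @slot imputationPolicy label of the policy used (\code{"none"} when no
#'   probe needed filling).
#' @slot probesImputed probe IDs that were absent from the input matrix and
#'   supplied by imputation.
#'
#' @seealso \code{\link{dnamAge}}, \code{\link{transformedScore}}
#' @name ClockAges-class
#' @rdname ClockAges-class
#' @exportClass ClockAges
setClass("ClockAges",
  slots = c(
    results          = "data.frame",
    clockName        = "character",
    imputationPolicy = "character",
    probesImputed    = "character"
  )
)

setValidity("ClockAges", function(object) {
  need <- c("sample_id", "dnam_age", "transformed_score",
            "n_probes_used", "n_probes_imputed")
  if (!all(need %in% names(object@results)))
    return(paste0("'results' must have columns: ", paste(need, collapse = ", ")))
  if (anyDuplicated(object@results$sample_id))
    return("duplicate sample IDs in 'results'")
  TRUE
})

#' RegressionFit: an ordinary least squares line with inference
#'
#' Simple-regression container used by the comparison analyses: intercept and
#' slope estimates with standard errors and two-sided 95% confidence
#' intervals (estimate +/- t[0.975, df] * SE), residuals, and sizes.
#'
#' @slot estimate named numeric: \code{intercept}, \code{slope}.
#' @slot se standard errors, same names.
#' @slot ci 2 x 2 matrix of confidence limits (rows intercept/slope, columns
#'   lower/upper).
#' @slot n number of observations used.
#' @slot df residual degrees of freedom (n - 2).
#' @slot residuals fitted residuals, named by sample where names were
#'   available.
#' @slot term name of the predictor variable.
#'
#' @seealso \code{\link{fitOLS}}, \code{\link{stratifiedClockRegression}},
#'   \code{\link{compareSlopes}}
#' @name RegressionFit-class
#' @rdname RegressionFit-class
#' @exportClass RegressionFit
setClass("RegressionFit",
  slots = c(
    estimate  = "numeric",
    se        = "numeric",
    ci        = "matrix",
    n         = "integer",
    df        = "integer",
    residuals = "numeric",
    term      = "character"
  )
)

#' ComparisonReport: paired full-versus-reduced deviation summary
#'
#' Result of \code{\link{pairedDeviationSummary}}.  The deviation is defined
#' as full minus reduced DNAm age, per sample.  Summaries are reported
#' overall, per dataset, and per closed-open chronological age bin
#' ([0, w), [w, 2w), ...).
#'
#' @slot overall one-row data frame: n, mean/SD of the deviation, paired
#'   t statistic and p value, Pearson correlation of full vs reduced DNAm age
#'   and of each with chronological age (NA where ages are unavailable).
#' @slot byDataset per-dataset deviation mean/SD/n.
#' @slot byAgeBin per-age-bin deviation mean/SD/n (samples with missing age
#'   are excluded from bins but kept in the overall summary).
#' @slot deviations per-sample table (sample_id, age, dataset, full, reduced,
#'   deviation) backing the summaries.
#' @slot binWidth bin width in years.
#'
#' @name ComparisonReport-class
#' @rdname ComparisonReport-class
#' @exportClass ComparisonReport
setClass("ComparisonReport",
  slots = c(
    overall    = "data.frame",
    byDataset  = "data.frame",
    byAgeBin   = "data.frame",
    deviations = "data.frame",
    binWidth   = "numeric"
  )
)

#' GenerativeSpec: parameters of the synthetic methylation cohort model
#'
#' The generative model produces beta values
#' \deqn{\beta_{ij} = \mathrm{clip}(\mu_j + s_j T_j(a_i) + \varepsilon_{ij}),
#'   \quad \varepsilon \sim N(0, \sigma^2)}
#' where \eqn{T_j(a) = F(a)} is the log-linear age transform for ordinary
#' probes and \eqn{T_j(a) = F(\min(a, A))} for probes in
#' \code{developmentalProbes} -- CpGs whose methylation changes during
#' development and is stable in adults.  Ages are uniform on
#' \code{ageRange} or resampled from \code{agePool}.  Values are clipped to
#' [0.001, 0.999]; the seed fully determines the output.
#'
#' @slot nSamples number of samples.
#' @slot ageRange length-2 numeric, uniform age range in years.
#' @slot agePool optional numeric pool of ages to resample from (overrides
#'   \code{ageRange} when non-empty).
#' @slot nProbes number of probes.
#' @slot probeIDs probe identifiers.
#' @slot mu per-probe baselines in (0, 1), named by probe.
#' @slot slopes per-probe age slopes on the transformed-age scale, named.
#' @slot noiseSD additive Gaussian noise SD on the beta scale.
#' @slot adultAge knee of the age transform in years.
#' @slot droppedProbes probe IDs absent from the emulated reduced platform.
#' @slot developmentalProbes probe IDs with saturating trajectories.
#' @slot seed integer seed.
#'
#' @seealso \code{\link{generativeSpec}}, \code{\link{generateCohort}},
#'   \code{\link{constructConsistentClock}}
#' @name GenerativeSpec-class
#' @rdname GenerativeSpec-class
#' @exportClass GenerativeSpec
setClass("GenerativeSpec",
  slots = c(
    nSamples  = "integer",
    ageRange  = "numeric",
    agePool   = "numeric",
    nProbes   = "integer",
    probeIDs  = "character",
    mu        = "numeric",
    slopes    = "numeric",
    noiseSD   = "numeric",
    adultAge  = "numeric",
    droppedProbes       = "character",
    developmentalProbes = "character",
    seed      = "integer"
  )
)

setValidity("GenerativeSpec", function(object) {
  msg <- character()
  if (object@nSamples < 1L) msg <- c(msg, "'nSamples' must be >= 1")
  if (length(object@ageRange) != 2L || anyNA(object@ageRange) ||
      object@ageRange[1] < 0 || diff(object@ageRange) < 0)
    msg <- c(msg, "'ageRange' must be an increasing pair of non-negative ages")
  if (length(object@agePool) && any(object@agePool < 0, na.rm = TRUE))
    msg <- c(msg, "'agePool' ages must be non-negative")
  n <- object@nProbes
  if (length(object@probeIDs) != n || anyDuplicated(object@probeIDs))
    msg <- c(msg, "'probeIDs' must be 'nProbes' unique identifiers")
  if (length(object@mu) != n || anyNA(object@mu) ||
      any(object@mu <= 0 | object@mu >= 1))
    msg <- c(msg, "'mu' must be length 'nProbes' with values in (0, 1)")
  if (length(object@slopes) != n || anyNA(object@slopes))
    msg <- c(msg, "'slopes' must be length 'nProbes' and non-missing")
  if (length(object@noiseSD) != 1L || is.na(object@noiseSD) || object@noiseSD < 0)
    msg <- c(msg, "'noiseSD' must be a single non-negative number")
  if (length(object@adultAge) != 1L || is.na(object@adultAge) || object@adultAge <= 0)
    msg <- c(msg, "'adultAge' must be a single positive number")
  if (!all(object@droppedProbes %in% object@probeIDs))
    msg <- c(msg, "'droppedProbes' must be a subset of 'probeIDs'")
  if (!all(object@developmentalProbes %in% object@probeIDs))
    msg <- c(msg, "'developmentalProbes' must be a subset of 'probeIDs'")
  if (length(object@seed) != 1L || is.na(object@seed))
    msg <- c(msg, "'seed' must be a single integer")
  if (length(msg)) msg else TRUE
})
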