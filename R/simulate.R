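## Synthetic methylation cohorts with analytically consistent clocks.
##
## The generative model ties every probe to the transformed-age scale, so a
## clock whose weights are proportional to the generative slopes recovers
## chronological age exactly on noiseless data.  This gives closed-form
## oracles for the whole masking/imputation pipeline: the transformed-score
## deviation between a full and a masked-then-imputed matrix is exactly
## sum_dropped w_j (beta_ij - ref_j).

## Evaluate expressions under a local RNG state so generation is fully
## determined by the given seed and does not disturb the caller's stream.
.withSeed <- function(seed, expr) {
  hasSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (hasSeed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (hasSeed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Construct a generative specification
#'
#' Defines the synthetic cohort model (see
#' \linkS4class{GenerativeSpec}).  When \code{mu} or \code{slopes} are not
#' supplied they are drawn deterministically from \code{seed}: baselines
#' uniform on (0.35, 0.65) and slope magnitudes uniform on (0.01, 0.06) with
#' random sign -- amplitudes that keep noiseless trajectories inside (0, 1)
#' across ages 0--101 so the clipping bound is never active by default.
#'
#' @param nSamples number of samples (default 1000).
#' @param ageRange uniform age range in years (default \code{c(0, 100)},
#'   spanning newborns to centenarians so both sides of the age-transform
#'   knee are exercised).
#' @param agePool optional vector of ages to resample from instead of the
#'   uniform range.
#' @param nProbes number of probes (default 353, the Horvath clock size).
#' @param mu optional per-probe baselines in (0, 1).
#' @param slopes optional per-probe slopes on the transformed-age scale.
#' @param noiseSD additive Gaussian noise SD on the beta scale
#'   (default 0.01).
#' @param adultAge knee of the age transform (default 20).
#' @param droppedProbes probe IDs absent from the emulated reduced platform.
#' @param developmentalProbes probe IDs whose trajectory saturates at
#'   \code{adultAge} (methylation change confined to development).
#' @param probeIDs optional explicit probe identifiers.
#' @param seed integer seed; fully determines the spec and any cohort
#'   generated from it.
#' @return a \linkS4class{GenerativeSpec}.
#' @examples
#' sp <- generativeSpec(nSamples = 20, nProbes = 10, seed = 1)
#' sp
#' @export
generativeSpec <- function(nSamples = 1000, ageRange = c(0, 100),
                           agePool = numeric(0), nProbes = 353,
                           mu = NULL, slopes = NULL, noiseSD = 0.01,
                           adultAge = 20, droppedProbes = character(0),
                           developmentalProbes = character(0),
                           probeIDs = NULL, seed = 1) {
  nProbes <- as.integer(nProbes)
  if (is.null(probeIDs))
    probeIDs <- sprintf("syn%05d", seq_len(nProbes))
  drawn <- .withSeed(seed, {
    m <- if (is.null(mu)) runif(nProbes, 0.35, 0.65) else mu
    s <- if (is.null(slopes))
      runif(nProbes, 0.01, 0.06) * sample(c(-1, 1), nProbes, replace = TRUE)
    else slopes
    list(mu = m, slopes = s)
  })
  mu <- setNames(as.numeric(drawn$mu), probeIDs)
  slopes <- setNames(as.numeric(drawn$slopes), probeIDs)
  new("GenerativeSpec",
      nSamples = as.integer(nSamples),
      ageRange = as.numeric(ageRange),
      agePool = as.numeric(agePool),
      nProbes = nProbes,
      probeIDs = as.character(probeIDs),
      mu = mu, slopes = slopes,
      noiseSD = as.numeric(noiseSD),
      adultAge = as.numeric(adultAge),
      droppedProbes = as.character(droppedProbes),
      developmentalProbes = as.character(developmentalProbes),
      seed = as.integer(seed))
}

setMethod("show", "GenerativeSpec", function(object) {
  cat("GenerativeSpec: ", object@nSamples, " samples x ", object@nProbes,
      " probes (seed ", object@seed, ")\n", sep = "")
  if (length(object@agePool))
    cat("  ages resampled from a pool of ", length(object@agePool), "\n",
        sep = "")
  else
    cat("  ages ~ U[", object@ageRange[1], ", ", object@ageRange[2], "] y\n",
        sep = "")
  cat("  noise SD ", object@noiseSD, ", adultAge ", object@adultAge, "\n",
      sep = "")
  if (length(object@droppedProbes))
    cat("  dropped probes: ", length(object@droppedProbes),
        " (", length(object@developmentalProbes), " developmental)\n",
        sep = "")
})

## Per-probe trajectory matrix T (probes x samples): F(age) for ordinary
## probes, F(min(age, adultAge)) for developmental ones.
.trajectoryMatrix <- function(spec, ages) {
  Fa <- transformAge(ages, spec@adultAge)
  Tm <- matrix(rep(Fa, each = spec@nProbes), spec@nProbes, length(ages),
               dimnames = list(spec@probeIDs, NULL))
  dev <- spec@probeIDs %in% spec@developmentalProbes
  if (any(dev))
    Tm[dev, ] <- pmin(Tm[dev, , drop = FALSE], 0)
  Tm
}

#' Generate a synthetic cohort
#'
#' Draws ages, sexes and beta values from the generative model
#' \eqn{\beta_{ij} = \mathrm{clip}(\mu_j + s_j T_j(a_i) + \varepsilon_{ij})}
#' with clipping to [0.001, 0.999].  Bit-identical across runs for a fixed
#' spec.
#'
#' @param spec a \linkS4class{GenerativeSpec}.
#' @return a \linkS4class{BetaMatrix} whose annotation carries the true
#'   chronological ages, a random sex, and \code{platform = "synthetic"}.
#' @examples
#' bm <- generateCohort(generativeSpec(nSamples = 5, nProbes = 8, seed = 42))
#' sampleAnnotation(bm)
#' @export
generateCohort <- function(spec) {
  stopifnot(is(spec, "GenerativeSpec"))
  validObject(spec)
  n <- spec@nSamples
  out <- .withSeed(spec@seed, {
    ages <- if (length(spec@agePool))
      sample(spec@agePool, n, replace = TRUE)
    else
      runif(n, spec@ageRange[1], spec@ageRange[2])
    sex <- ifelse(rbinom(n, 1L, 0.5) == 1L, "female", "male")
    eps <- matrix(rnorm(spec@nProbes * n, sd = spec@noiseSD), spec@nProbes, n)
    list(ages = ages, sex = sex, eps = eps)
  })
  Tm <- .trajectoryMatrix(spec, out$ages)
  vals <- spec@mu + spec@slopes * Tm + out$eps
  outside <- vals < 0.001 | vals > 0.999
  if (all(outside))
    stop("generative parameters drive every beta value out of (0, 1)",
         call. = FALSE)
  vals[vals < 0.001] <- 0.001
  vals[vals > 0.999] <- 0.999
  sampleIDs <- sprintf("sample_%04d", seq_len(n))
  dimnames(vals) <- list(spec@probeIDs, sampleIDs)
  ann <- data.frame(sample_id = sampleIDs, age = out$ages, sex = out$sex,
                    platform = "synthetic", dataset = "synthetic",
                    stringsAsFactors = FALSE)
  BetaMatrix(vals, annotation = ann)
}

#' Construct a clock exactly consistent with a generative spec
#'
#' Closed-form clock over a probe subset: weights
#' \eqn{w_j = \sigma_j s_j / \sum_k \sigma_k s_k^2} (signs
#' \eqn{\sigma_j = -1} for probes in \code{negativeProbes}, else +1) so that
#' \eqn{\sum_j w_j s_j = 1}, and intercept \eqn{-\sum_j w_j \mu_j}.  On
#' noiseless data from a spec without developmental probes,
#' \code{\link{applyClock}} then returns chronological age exactly (within
#' clipping); under noise the transformed-score error variance is
#' \eqn{\sigma^2 \sum_j w_j^2}.  When the subset contains developmental
#' probes the clock is exact below \code{adultAge} and attenuated by their
#' weight fraction above it.
#'
#' @param spec a \linkS4class{GenerativeSpec}.
#' @param probeSubset probe IDs forming the clock (default: all probes).
#' @param negativeProbes subset of \code{probeSubset} given
#'   opposite-sign weights, allowing a dropped set with negative signal
#'   fraction (sign-varying deviation profiles).
#' @param name clock label.
#' @return a \linkS4class{ClockDefinition} with the spec's
#'   \code{adultAge} and the \code{"horvath"} transform.
#' @export
constructConsistentClock <- function(spec, probeSubset = NULL,
                                     negativeProbes = character(0),
                                     name = "synthetic_consistent") {
  stopifnot(is(spec, "GenerativeSpec"))
  if (is.null(probeSubset)) probeSubset <- spec@probeIDs
  probeSubset <- as.character(probeSubset)
  if (!all(probeSubset %in% spec@probeIDs))
    stop("'probeSubset' must be a subset of the spec's probes", call. = FALSE)
  s <- spec@slopes[probeSubset]
  if (sum(s^2) == 0)
    stop("all generative slopes are zero on the subset; no clock exists",
         call. = FALSE)
  sgn <- ifelse(probeSubset %in% negativeProbes, -1, 1)
  S <- sum(sgn * s^2)
  if (S == 0)
    stop("signed slope normaliser is zero; choose a different sign pattern",
         call. = FALSE)
  w <- setNames(sgn * s / S, probeSubset)
  intercept <- -sum(w * spec@mu[probeSubset])
  ClockDefinition(name, w, intercept = intercept, transform = "horvath",
                  adultAge = spec@adultAge)
}

#' Split a cohort into full and reduced platform versions
#'
#' The reduced version lacks the dropped probes, emulating data from an
#' array whose manifest does not include them; the full version is returned
#' unmodified.
#'
#' @param betas a \linkS4class{BetaMatrix}.
#' @param droppedProbeIDs probe IDs absent from the reduced platform.
#' @return list with elements \code{full} and \code{reduced}.
#' @export
emulatePlatforms <- function(betas, droppedProbeIDs) {
  list(full = betas, reduced = maskProbes(betas, droppedProbeIDs))
}

#' Population mean of the transformed-age trajectory
#'
#' Closed-form expectation of the age transform \eqn{F} (or its saturating
#' variant \eqn{F(\min(a, A))}) over a uniform age distribution on
#' [\code{lo}, \code{hi}] -- the quantity needed to compute population
#' reference means analytically.
#'
#' @param lo,hi age range in years (\code{lo == hi} gives the point value).
#' @param adultAge knee of the transform.
#' @param saturating if \code{TRUE}, use the developmental trajectory that
#'   is constant above \code{adultAge}.
#' @return a single number.
#' @export
meanTransformedAge <- function(lo, hi, adultAge = 20, saturating = FALSE) {
  .checkAdultAge(adultAge)
  if (lo < 0 || hi < lo) stop("need 0 <= lo <= hi", call. = FALSE)
  A <- adultAge
  if (lo == hi)
    return(if (saturating) min(transformAge(lo, A), 0) else transformAge(lo, A))
  ## integral of log(a+1) is (a+1)(log(a+1) - 1)
  ilog <- function(a) (a + 1) * (log(a + 1) - 1)
  total <- 0
  u <- min(hi, A)
  if (lo < A)
    total <- total + (ilog(u) - ilog(lo)) - log(A + 1) * (u - lo)
  l2 <- max(lo, A)
  if (hi > A && !saturating)
    total <- total + ((hi - A)^2 - (l2 - A)^2) / (2 * (A + 1))
  total / (hi - lo)
}

#' Analytic population reference means for a generative spec
#'
#' Per-probe expected beta over an age distribution: the baseline plus the
#' slope times the expected trajectory.  These are the exact analogues of
#' "gold standard cohort" means used by reference-mean imputation.
#'
#' @param spec a \linkS4class{GenerativeSpec}.
#' @param referenceAges \code{NULL} to integrate over the spec's own age
#'   distribution, or a numeric vector of ages defining the reference cohort
#'   (e.g. \code{0} for a newborn panel).
#' @return named numeric vector of reference mean betas.
#' @export
populationReferenceMeans <- function(spec, referenceAges = NULL) {
  stopifnot(is(spec, "GenerativeSpec"))
  dev <- spec@probeIDs %in% spec@developmentalProbes
  if (is.null(referenceAges)) {
    if (length(spec@agePool)) {
      Fa <- transformAge(spec@agePool, spec@adultAge)
      eT <- ifelse(dev, mean(pmin(Fa, 0)), mean(Fa))
    } else {
      eF <- meanTransformedAge(spec@ageRange[1], spec@ageRange[2],
                               spec@adultAge, saturating = FALSE)
      eG <- meanTransformedAge(spec@ageRange[1], spec@ageRange[2],
                               spec@adultAge, saturating = TRUE)
      eT <- ifelse(dev, eG, eF)
    }
  } else {
    Fa <- transformAge(referenceAges, spec@adultAge)
    eT <- ifelse(dev, mean(pmin(Fa, 0)), mean(Fa))
  }
  rm <- spec@mu + spec@slopes * eT
  pmin(pmax(rm, 0), 1)
}

#' Set up a probe-masking simulation study
#'
#' Assembles the full study used to emulate cross-array clock bias: a
#' generative spec whose dropped probes carry a prescribed fraction of the
#' clock's signal, the exactly consistent clock, analytic reference means
#' for imputation, and the full/reduced platform pair.
#'
#' With \code{droppedPattern = "developmental"} (the default, Horvath-like
#' behaviour) the dropped probes' methylation saturates at \code{adultAge},
#' so mean-imputing them biases adult scores by a constant and the
#' full-minus-reduced deviation rises through development and is flat in
#' adulthood.  With \code{"linear"} (Hannum-like behaviour) the dropped
#' probes keep tracking transformed age, and imputation at mixed-age
#' population means yields a deviation that changes sign across the age
#' range.
#'
#' @param seed integer seed determining everything.
#' @param nSamples,nProbes,noiseSD,adultAge,ageRange passed to
#'   \code{\link{generativeSpec}}.
#' @param nDropped number of probes absent from the reduced platform
#'   (default 17, the Horvath/EPIC count; use 6 for the Hannum analogue).
#' @param droppedSignal fraction of the clock's signal carried by the
#'   dropped probes (default 0.05, mirroring 17 of 353 probes); the dropped
#'   slopes are rescaled so the fraction is exact.
#' @param droppedPattern \code{"developmental"} or \code{"linear"} (see
#'   details).
#' @param reference \code{"population"} (reference panel spanning the study
#'   age range; default) or \code{"newborn"} (age-0 panel, which produces
#'   multi-year adult underestimation for developmental dropped probes,
#'   the magnitude scale reported for real 450k-versus-EPIC comparisons).
#' @param negativeDropped if \code{TRUE}, the dropped probes get
#'   opposite-sign clock weights so their signal fraction is negative.
#' @return list with components \code{spec}, \code{clock}, \code{dropped}
#'   (probe IDs), \code{referenceMeans}, \code{cohort}, \code{full},
#'   \code{reduced} and \code{droppedSignal} (the realised signed fraction).
#' @examples
#' st <- simulateMaskingStudy(seed = 1, nSamples = 50, nProbes = 40,
#'                            nDropped = 4)
#' st$clock
#' @export
simulateMaskingStudy <- function(seed = 1, nSamples = 1000, nProbes = 353,
                                 nDropped = 17, droppedSignal = 0.05,
                                 noiseSD = 0.01, adultAge = 20,
                                 ageRange = c(0, 100),
                                 droppedPattern = c("developmental", "linear"),
                                 reference = c("population", "newborn"),
                                 negativeDropped = FALSE) {
  droppedPattern <- match.arg(droppedPattern)
  reference <- match.arg(reference)
  if (nDropped < 1 || nDropped >= nProbes)
    stop("'nDropped' must be in [1, nProbes - 1]", call. = FALSE)
  if (droppedSignal <= 0 || droppedSignal >= 1)
    stop("'droppedSignal' must be in (0, 1)", call. = FALSE)

  base <- generativeSpec(nSamples = nSamples, ageRange = ageRange,
                         nProbes = nProbes, noiseSD = noiseSD,
                         adultAge = adultAge, seed = seed)
  dropped <- .withSeed(seed + 1L, sample(base@probeIDs, nDropped))

  ## rescale dropped slopes so the dropped set carries exactly the requested
  ## signal fraction |rho| = |sum_d w s| of the consistent clock
  s <- base@slopes
  isDrop <- names(s) %in% dropped
  sumDrop <- sum(s[isDrop]^2)
  sumKeep <- sum(s[!isDrop]^2)
  rho <- droppedSignal
  scale2 <- if (negativeDropped)
    rho * sumKeep / ((1 + rho) * sumDrop)
  else
    rho * sumKeep / ((1 - rho) * sumDrop)
  s[isDrop] <- s[isDrop] * sqrt(scale2)

  spec <- generativeSpec(
    nSamples = nSamples, ageRange = ageRange, nProbes = nProbes,
    mu = base@mu, slopes = s, noiseSD = noiseSD, adultAge = adultAge,
    droppedProbes = dropped,
    developmentalProbes = if (identical(droppedPattern, "developmental"))
      dropped else character(0),
    probeIDs = base@probeIDs, seed = seed)

  clock <- constructConsistentClock(
    spec, negativeProbes = if (negativeDropped) dropped else character(0))
  refMeans <- populationReferenceMeans(
    spec, referenceAges = if (identical(reference, "newborn")) 0 else NULL)

  cohort <- generateCohort(spec)
  platforms <- emulatePlatforms(cohort, dropped)
  w <- clockWeights(clock)
  list(spec = spec, clock = clock, dropped = dropped,
       referenceMeans = refMeans, cohort = cohort,
       full = platforms$full, reduced = platforms$reduced,
       droppedSignal = sum(w[dropped] * spec@slopes[dropped]))
}

#' Run the full-versus-reduced masking analysis
#'
#' Scores the full and reduced matrices with the same clock (reference-mean
#' imputation of the absent probes on the reduced side), then produces the
#' paired deviation summary, age-stratified regressions of each DNAm-age
#' version on chronological age with slope- and intercept-equality tests,
#' the per-stratum intercept shift (reduced minus full), and per-stratum
#' regressions of the deviation itself on age.
#'
#' @param full,reduced \linkS4class{BetaMatrix} pair (same samples; the
#'   reduced one lacks the masked probes).
#' @param clock a \linkS4class{ClockDefinition}.
#' @param referenceMeans named vector of reference mean betas used to impute
#'   the absent probes (ignored when \code{policy} is supplied).
#' @param policy optional \linkS4class{ImputationPolicy} overriding the
#'   default reference-mean policy.
#' @param cutoff age-stratification cutoff in years (default 20).
#' @param binWidth age bin width for the deviation summary (default 5).
#' @return list with components \code{fullAges}, \code{reducedAges}
#'   (\linkS4class{ClockAges}), \code{report}
#'   (\linkS4class{ComparisonReport}), \code{fullFits}, \code{reducedFits},
#'   \code{deviationFits} (per-stratum \linkS4class{RegressionFit} lists),
#'   \code{slopeTests}, \code{interceptTests} (per-stratum equality tests)
#'   and \code{interceptShift} (reduced minus full, per stratum).
#' @export
runMaskingAnalysis <- function(full, reduced, clock, referenceMeans = NULL,
                               policy = NULL, cutoff = 20, binWidth = 5) {
  stopifnot(is(full, "BetaMatrix"), is(reduced, "BetaMatrix"),
            is(clock, "ClockDefinition"))
  if (is.null(policy) && !is.null(referenceMeans))
    policy <- imputationPolicy("reference_mean",
                               referenceMeans = referenceMeans)
  fullAges <- applyClock(clock, full, policy = policy)
  reducedAges <- applyClock(clock, reduced, policy = policy)
  ann <- sampleAnnotation(full)
  report <- pairedDeviationSummary(fullAges, reducedAges, annotation = ann,
                                   binWidth = binWidth)

  fa <- dnamAge(fullAges)
  ra <- dnamAge(reducedAges)[names(fa)]
  chron <- ann$age[match(names(fa), ann$sample_id)]

  fullFits <- stratifiedClockRegression(fa, chron, cutoff = cutoff)
  reducedFits <- stratifiedClockRegression(ra, chron, cutoff = cutoff)
  deviationFits <- stratifiedClockRegression(fa - ra, chron, cutoff = cutoff)

  strata <- intersect(names(fullFits), names(reducedFits))
  slopeTests <- lapply(setNames(strata, strata), function(s)
    compareSlopes(fullFits[[s]], reducedFits[[s]], term = "slope"))
  interceptTests <- lapply(setNames(strata, strata), function(s)
    compareSlopes(fullFits[[s]], reducedFits[[s]], term = "intercept"))
  interceptShift <- vapply(strata, function(s)
    reducedFits[[s]]@estimate[["intercept"]] -
      fullFits[[s]]@estimate[["intercept"]], numeric(1))

  list(fullAges = fullAges, reducedAges = reducedAges, report = report,
       fullFits = fullFits, reducedFits = reducedFits,
       deviationFits = deviationFits,
       slopeTests = slopeTests, interceptTests = interceptTests,
       interceptShift = interceptShift)
}
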