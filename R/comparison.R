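#' Ordinary least squares fit of y on x
#'
#' Thin wrapper around \code{\link[stats]{lm}} that returns the
#' \linkS4class{RegressionFit} container used throughout the comparison
#' analyses, with 95\% confidence intervals
#' \eqn{\hat\beta \pm t_{0.975, n-2} \cdot SE}.
#'
#' @param x predictor values.
#' @param y response values.
#' @param term label for the predictor (used in printing).
#' @return a \linkS4class{RegressionFit}.
#' @examples
#' fitOLS(1:10, 2 * (1:10) + 3)
#' @export
fitOLS <- function(x, y, term = "x") {
  if (length(x) != length(y))
    stop("'x' and 'y' must have the same length", call. = FALSE)
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L)
    stop("at least 3 complete observations are required", call. = FALSE)
  if (length(unique(x)) < 2L)
    stop("predictor is constant", call. = FALSE)
  fit <- lm(y ~ x)
  est <- setNames(coef(fit), c("intercept", "slope"))
  se <- setNames(sqrt(diag(vcov(fit))), c("intercept", "slope"))
  df <- n - 2L
  tq <- qt(0.975, df)
  ci <- cbind(lower = est - tq * se, upper = est + tq * se)
  rownames(ci) <- c("intercept", "slope")
  resid <- residuals(fit)
  nm <- names(y)
  if (!is.null(nm)) names(resid) <- nm
  new("RegressionFit", estimate = est, se = se, ci = ci,
      n = as.integer(n), df = as.integer(df),
      residuals = resid, term = as.character(term))
}

setMethod("show", "RegressionFit", function(object) {
  ci <- object@ci
  cat("RegressionFit (n = ", object@n, "): y ~ ", object@term, "\n", sep = "")
  cat(sprintf("  intercept: %8.4f (95%% CI %8.4f, %8.4f)\n",
              object@estimate[["intercept"]], ci["intercept", 1], ci["intercept", 2]))
  cat(sprintf("  slope:     %8.4f (95%% CI %8.4f, %8.4f)\n",
              object@estimate[["slope"]], ci["slope", 1], ci["slope", 2]))
})

#' @describeIn RegressionFit-class estimates (intercept, slope).
#' @param object a \linkS4class{RegressionFit}.
#' @export
setMethod("coef", "RegressionFit", function(object) object@estimate)

#' @describeIn RegressionFit-class fitted residuals.
#' @export
setMethod("residuals", "RegressionFit", function(object) object@residuals)

#' Paired deviation summary of full versus reduced DNAm ages
#'
#' Per-sample deviation is defined as full minus reduced DNAm age.  Reports
#' the mean and SD of the deviation overall, per dataset, and per closed-open
#' chronological age bin ([0, w), [w, 2w), ...), a paired t test of the
#' deviation, the Pearson correlation between full and reduced DNAm age, and
#' each version's correlation with chronological age.  Samples with missing
#' age stay in the overall and per-dataset summaries but are excluded from
#' age bins and age correlations.
#'
#' @param full,reduced \linkS4class{ClockAges} for the same sample set,
#'   scored from the full and the probe-masked matrix respectively.
#' @param annotation optional data frame with columns \code{sample_id},
#'   \code{age} and (optionally) \code{dataset}; defaults to no age
#'   information.
#' @param binWidth age bin width in years (default 5).
#' @return a \linkS4class{ComparisonReport}.
#' @export
pairedDeviationSummary <- function(full, reduced, annotation = NULL,
                                   binWidth = 5) {
  stopifnot(is(full, "ClockAges"), is(reduced, "ClockAges"))
  if (!is.numeric(binWidth) || length(binWidth) != 1L || binWidth <= 0)
    stop("'binWidth' must be a single positive number", call. = FALSE)
  fa <- dnamAge(full)
  ra <- dnamAge(reduced)
  if (!setequal(names(fa), names(ra)))
    stop("'full' and 'reduced' must cover the same samples", call. = FALSE)
  ra <- ra[names(fa)]

  age <- rep(NA_real_, length(fa))
  dataset <- rep(NA_character_, length(fa))
  if (!is.null(annotation)) {
    annotation <- as.data.frame(annotation)
    if (!"sample_id" %in% names(annotation))
      stop("annotation needs a 'sample_id' column", call. = FALSE)
    idx <- match(names(fa), annotation$sample_id)
    if ("age" %in% names(annotation)) age <- as.numeric(annotation$age[idx])
    if ("dataset" %in% names(annotation))
      dataset <- as.character(annotation$dataset[idx])
  }

  dev <- fa - ra
  devTab <- data.frame(sample_id = names(fa), age = age, dataset = dataset,
                       full = as.numeric(fa), reduced = as.numeric(ra),
                       deviation = as.numeric(dev),
                       row.names = NULL, stringsAsFactors = FALSE)

  tt <- if (stats::sd(dev) > 0) {
    ht <- t.test(dev)
    c(statistic = unname(ht$statistic), p.value = ht$p.value)
  } else {
    c(statistic = NA_real_, p.value = NA_real_)
  }
  corFR <- if (stats::sd(fa) > 0 && stats::sd(ra) > 0) cor(fa, ra) else 1
  okAge <- !is.na(age)
  corFA <- if (sum(okAge) >= 3) cor(fa[okAge], age[okAge]) else NA_real_
  corRA <- if (sum(okAge) >= 3) cor(ra[okAge], age[okAge]) else NA_real_

  overall <- data.frame(
    n = length(dev),
    mean_deviation = mean(dev),
    sd_deviation = stats::sd(dev),
    t_statistic = tt[["statistic"]],
    p_value = tt[["p.value"]],
    cor_full_reduced = corFR,
    cor_full_age = corFA,
    cor_reduced_age = corRA,
    row.names = NULL)

  byDataset <- .groupSummary(devTab$deviation, devTab$dataset, "dataset")
  bins <- ifelse(okAge, floor(age / binWidth), NA)
  binLab <- ifelse(is.na(bins), NA_character_,
                   sprintf("[%g,%g)", bins * binWidth, (bins + 1) * binWidth))
  byAgeBin <- .groupSummary(devTab$deviation[okAge],
                            binLab[okAge], "age_bin")
  if (nrow(byAgeBin)) {
    lo <- as.numeric(sub("\\[", "", sapply(strsplit(byAgeBin$age_bin, ","),
                                           `[`, 1L)))
    byAgeBin <- byAgeBin[order(lo), , drop = FALSE]
    rownames(byAgeBin) <- NULL
  }

  new("ComparisonReport", overall = overall, byDataset = byDataset,
      byAgeBin = byAgeBin, deviations = devTab, binWidth = binWidth)
}

.groupSummary <- function(values, groups, label) {
  keep <- !is.na(groups)
  if (!any(keep)) {
    out <- data.frame(g = character(0), n = integer(0),
                      mean_deviation = numeric(0), sd_deviation = numeric(0))
    names(out)[1L] <- label
    return(out)
  }
  values <- values[keep]; groups <- groups[keep]
  sp <- split(values, groups)
  out <- data.frame(
    g = names(sp),
    n = vapply(sp, length, integer(1)),
    mean_deviation = vapply(sp, mean, numeric(1)),
    sd_deviation = vapply(sp, stats::sd, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  names(out)[1L] <- label
  out
}

setMethod("show", "ComparisonReport", function(object) {
  o <- object@overall
  cat("ComparisonReport (full - reduced DNAm age, n = ", o$n, ")\n", sep = "")
  cat(sprintf("  deviation: %.3f +/- %.3f y", o$mean_deviation, o$sd_deviation))
  if (!is.na(o$p_value))
    cat(sprintf("  (paired t = %.2f, p = %.3g)", o$t_statistic, o$p_value))
  cat("\n")
  cat(sprintf("  cor(full, reduced) = %.4f\n", o$cor_full_reduced))
  if (!is.na(o$cor_full_age))
    cat(sprintf("  cor with age: full %.3f, reduced %.3f\n",
                o$cor_full_age, o$cor_reduced_age))
  if (nrow(object@byAgeBin)) {
    cat("  age bins (width ", object@binWidth, " y): ",
        nrow(object@byAgeBin), "\n", sep = "")
  }
})

#' Age-stratified regression of DNAm age on chronological age
#'
#' Fits separate OLS regressions of DNAm age on chronological age among
#' samples below and at-or-above the cutoff -- the stratification used to
#' study how probe masking distorts the clock differently in development
#' versus adulthood.  Strata with fewer than \code{minN} aged samples are
#' omitted with a warning; samples with missing age are excluded.
#'
#' @param dnamAges numeric vector of DNAm ages (optionally named by sample).
#' @param chronAges chronological ages, same length/order.
#' @param cutoff stratification cutoff in years (default 20, the knee of the
#'   age transform); the upper stratum is inclusive (age >= cutoff).
#' @param minN minimum stratum size (default 3).
#' @return named list with elements \code{below} and \code{above}, each a
#'   \linkS4class{RegressionFit} (absent if the stratum was omitted).
#' @export
stratifiedClockRegression <- function(dnamAges, chronAges, cutoff = 20,
                                      minN = 3L) {
  if (length(dnamAges) != length(chronAges))
    stop("'dnamAges' and 'chronAges' must have the same length", call. = FALSE)
  ok <- complete.cases(dnamAges, chronAges)
  strata <- list(below = ok & chronAges < cutoff,
                 above = ok & chronAges >= cutoff)
  out <- list()
  for (s in names(strata)) {
    idx <- which(strata[[s]])
    if (length(idx) < minN) {
      warning("stratum '", s, "' has fewer than ", minN,
              " aged samples; omitted", call. = FALSE)
      next
    }
    out[[s]] <- fitOLS(chronAges[idx], dnamAges[idx], term = "chronological_age")
  }
  out
}

#' Test equality of two regression coefficients
#'
#' Compares the slopes (default) or intercepts of two independent OLS fits
#' with the statistic
#' \deqn{t = (b_1 - b_2) / \sqrt{SE_1^2 + SE_2^2}}
#' on \eqn{n_1 + n_2 - 4} degrees of freedom, two-sided.  Identical
#' coefficients give \eqn{t = 0, p = 1} even when both fits are noiseless.
#'
#' @param fitA,fitB \linkS4class{RegressionFit} objects.
#' @param term \code{"slope"} or \code{"intercept"}.
#' @return list with \code{statistic}, \code{df}, \code{p.value} and
#'   \code{difference} (A minus B).
#' @export
compareSlopes <- function(fitA, fitB, term = c("slope", "intercept")) {
  stopifnot(is(fitA, "RegressionFit"), is(fitB, "RegressionFit"))
  term <- match.arg(term)
  d <- fitA@estimate[[term]] - fitB@estimate[[term]]
  seD <- sqrt(fitA@se[[term]]^2 + fitB@se[[term]]^2)
  df <- fitA@n + fitB@n - 4L
  if (d == 0) {
    t <- 0; p <- 1
  } else if (seD == 0) {
    t <- sign(d) * Inf; p <- 0
  } else {
    t <- d / seD
    p <- 2 * pt(-abs(t), df)
  }
  list(statistic = t, df = df, p.value = p, difference = d)
}

#' Age-acceleration residuals
#'
#' Residuals from regressing DNAm age on chronological age (the
#' conventional direction, \code{"dnam_on_age"}), or chronological age on
#' DNAm age (\code{"age_on_dnam"}).  Positive values under the default mean
#' epigenetically older than expected for the chronological age.  Samples
#' with missing age are excluded; residuals sum to zero by OLS construction.
#'
#' @param dnamAges numeric vector of DNAm ages, optionally named by sample.
#' @param chronAges chronological ages, same length/order.
#' @param direction which variable is regressed on which (see above).
#' @return named numeric vector of residuals for the samples used.
#' @export
ageAcceleration <- function(dnamAges, chronAges,
                            direction = c("dnam_on_age", "age_on_dnam")) {
  direction <- match.arg(direction)
  if (length(dnamAges) != length(chronAges))
    stop("'dnamAges' and 'chronAges' must have the same length", call. = FALSE)
  ok <- complete.cases(dnamAges, chronAges)
  d <- dnamAges[ok]; a <- chronAges[ok]
  fit <- if (identical(direction, "dnam_on_age"))
    fitOLS(a, d, term = "chronological_age")
  else
    fitOLS(d, a, term = "dnam_age")
  r <- fit@residuals
  if (!is.null(names(dnamAges))) names(r) <- names(dnamAges)[ok]
  r
}

#' Regress age acceleration on a covariate for both clock versions
#'
#' Fits acceleration ~ covariate separately for the accelerations derived
#' from the full and the reduced data, and tests whether the covariate
#' effect differs between versions via \code{\link{compareSlopes}} -- the
#' analysis used to check that probe masking does not distort associations
#' (e.g. with sex).
#'
#' @param accelFull,accelReduced named numeric vectors of age-acceleration
#'   residuals from the full and reduced data; they are aligned on the
#'   shared sample names (or positionally when unnamed).
#' @param covariate per-sample covariate, aligned with \code{accelFull}:
#'   numeric, or a two-level factor/character (converted to a 0/1 indicator
#'   against \code{reference}).
#' @param reference reference level for a categorical covariate (default:
#'   first sorted level).
#' @return list with \code{full} and \code{reduced}
#'   (\linkS4class{RegressionFit}s of acceleration on the covariate) and
#'   \code{comparison} (the slope-equality test).
#' @export
accelerationCovariateRegression <- function(accelFull, accelReduced,
                                            covariate, reference = NULL) {
  if (!is.null(names(accelFull)) && !is.null(names(accelReduced))) {
    shared <- intersect(names(accelFull), names(accelReduced))
    if (length(shared) < 3L)
      stop("fewer than 3 samples shared between versions", call. = FALSE)
    if (!is.null(names(covariate))) covariate <- covariate[shared]
    accelFull <- accelFull[shared]
    accelReduced <- accelReduced[shared]
  } else if (length(accelFull) != length(accelReduced)) {
    stop("unnamed acceleration vectors must have equal length", call. = FALSE)
  }
  if (length(covariate) != length(accelFull))
    stop("'covariate' must align with the acceleration vectors", call. = FALSE)

  if (is.character(covariate) || is.factor(covariate)) {
    lev <- sort(unique(as.character(covariate[!is.na(covariate)])))
    if (length(lev) != 2L)
      stop("categorical covariate must have exactly 2 observed levels",
           call. = FALSE)
    if (is.null(reference)) reference <- lev[1L]
    if (!reference %in% lev)
      stop("'reference' is not a level of the covariate", call. = FALSE)
    covariate <- as.numeric(as.character(covariate) != reference)
  }
  if (length(unique(covariate[!is.na(covariate)])) < 2L)
    stop("covariate is constant", call. = FALSE)

  fitF <- fitOLS(covariate, accelFull, term = "covariate")
  fitR <- fitOLS(covariate, accelReduced, term = "covariate")
  list(full = fitF, reduced = fitR,
       comparison = compareSlopes(fitF, fitR))
}

#' Age-adjusted DNAm-age offset between two platforms
#'
#' Regresses DNAm age on a platform indicator plus chronological age; the
#' indicator coefficient is the adjusted mean DNAm-age difference of the
#' non-reference platform relative to the reference -- the model used to ask
#' whether an 850k cohort is systematically offset from a 450k cohort after
#' accounting for age.
#'
#' @param dnamAges numeric DNAm ages across both cohorts.
#' @param platform per-sample platform labels; exactly two distinct labels
#'   must be present.
#' @param chronAges chronological ages (samples with missing age are
#'   excluded).
#' @param referencePlatform label serving as the reference (default: first
#'   sorted label).
#' @return list with \code{offset} (years), \code{se}, \code{ci}
#'   (95\% limits), \code{p.value}, \code{n}, \code{platform} (the
#'   non-reference label) and \code{referencePlatform}.
#' @export
platformOffsetRegression <- function(dnamAges, platform, chronAges,
                                     referencePlatform = NULL) {
  if (length(dnamAges) != length(platform) ||
      length(dnamAges) != length(chronAges))
    stop("input vectors must have the same length", call. = FALSE)
  ok <- complete.cases(dnamAges, platform, chronAges)
  y <- dnamAges[ok]; pl <- as.character(platform[ok]); a <- chronAges[ok]
  labs <- sort(unique(pl))
  if (length(labs) != 2L)
    stop("exactly two platform labels are required (got ",
         length(labs), ")", call. = FALSE)
  if (is.null(referencePlatform)) referencePlatform <- labs[1L]
  if (!referencePlatform %in% labs)
    stop("'referencePlatform' is not among the platform labels", call. = FALSE)
  other <- setdiff(labs, referencePlatform)
  ind <- as.numeric(pl == other)
  fit <- lm(y ~ ind + a)
  est <- coef(fit)[["ind"]]
  se <- sqrt(diag(vcov(fit)))[["ind"]]
  df <- fit$df.residual
  tq <- qt(0.975, df)
  p <- 2 * pt(-abs(est / se), df)
  list(offset = est, se = se,
       ci = c(lower = est - tq * se, upper = est + tq * se),
       p.value = p, n = length(y),
       platform = other, referencePlatform = referencePlatform)
}
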