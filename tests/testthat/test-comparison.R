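## Minimal ClockAges builder for comparison tests.
mkAges <- function(ages, ids = sprintf("s%02d", seq_along(ages))) {
  new("ClockAges",
      results = data.frame(sample_id = ids, dnam_age = ages,
                           transformed_score = ages,
                           n_probes_used = 1L, n_probes_imputed = 0L,
                           stringsAsFactors = FALSE),
      clockName = "test", imputationPolicy = "none",
      probesImputed = character(0))
}

test_that("paired deviation summary reproduces hand arithmetic", {
  full <- mkAges(c(10, 20, 30))
  red <- mkAges(c(8, 17, 27))
  rep <- pairedDeviationSummary(full, red)
  expect_equal(rep@overall$mean_deviation, 8 / 3, tolerance = 1e-12)
  expect_equal(rep@overall$sd_deviation, sqrt(1 / 3), tolerance = 1e-10)
  ## identical inputs: zero deviation, correlation 1, no t statistic
  same <- pairedDeviationSummary(full, full)
  expect_equal(same@overall$mean_deviation, 0)
  expect_equal(same@overall$sd_deviation, 0)
  expect_equal(same@overall$cor_full_reduced, 1)
  expect_true(is.na(same@overall$p_value))
  ## sample mismatch is a hard error
  expect_error(pairedDeviationSummary(full, mkAges(1:3, c("a", "b", "c"))),
               "same samples")
})

test_that("age bins are closed-open and samples without age stay overall", {
  full <- mkAges(c(10, 20, 30, 40, 50))
  red <- mkAges(c(9, 18, 28, 38, 48))
  ann <- data.frame(sample_id = sprintf("s%02d", 1:5),
                    age = c(2, 4.999, 5, 9.9, NA),
                    dataset = c("d1", "d1", "d2", "d2", "d2"))
  rep <- pairedDeviationSummary(full, red, annotation = ann, binWidth = 5)
  expect_identical(rep@overall$n, 5L)          # NA-age sample kept overall
  expect_identical(rep@byAgeBin$age_bin, c("[0,5)", "[5,10)"))
  expect_identical(rep@byAgeBin$n, c(2L, 2L))  # 4.999 in [0,5), 5 in [5,10)
  expect_identical(sort(rep@byDataset$dataset), c("d1", "d2"))
  expect_identical(rep@byDataset$n[rep@byDataset$dataset == "d2"], 3L)
})

test_that("OLS fits agree with the closed-form normal equations", {
  set.seed(31)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    x <- rnorm(n, sd = runif(1, 0.5, 10))
    y <- runif(1, -2, 2) + runif(1, -3, 3) * x + rnorm(n)
    fit <- fitOLS(x, y)
    want <- olsClosedForm(x, y)
    expect_equal(unname(fit@estimate), want$estimate, tolerance = 1e-8)
    expect_equal(unname(fit@se), want$se, tolerance = 1e-8)
    expect_equal(unname(fit@residuals), want$residuals, tolerance = 1e-8)
  }
})

test_that("stratified regression recovers exact lines and drops small strata", {
  ages <- c(seq(2, 18, by = 2), seq(25, 95, by = 5))
  ## identity clock: slope 1, intercept 0 in both strata (suppress the
  ## perfect-fit chatter from summary.lm on noiseless data)
  fits <- suppressWarnings(stratifiedClockRegression(ages, ages, cutoff = 20))
  for (s in c("below", "above")) {
    expect_equal(unname(fits[[s]]@estimate), c(0, 1), tolerance = 1e-10)
  }
  ## noiseless affine clock recovered exactly in the adult stratum
  dn <- 0.85 * ages + 7
  fits2 <- suppressWarnings(stratifiedClockRegression(dn, ages, cutoff = 20))
  expect_equal(unname(fits2$above@estimate), c(7, 0.85), tolerance = 1e-10)
  expect_identical(fits2$above@n, length(ages[ages >= 20]))
  ## a stratum below the minimum size is omitted with a warning
  suppressWarnings(                     # perfect-fit chatter on exact line
    expect_warning(
      one <- stratifiedClockRegression(dn[ages >= 20], ages[ages >= 20],
                                       cutoff = 20),
      "below"))
  expect_named(one, "above")
})

test_that("slope comparison reproduces the two-fit t statistic", {
  mkFit <- function(slope, se, n) {
    new("RegressionFit",
        estimate = c(intercept = 0, slope = slope),
        se = c(intercept = 0.1, slope = se),
        ci = matrix(0, 2, 2, dimnames = list(c("intercept", "slope"),
                                             c("lower", "upper"))),
        n = as.integer(n), df = as.integer(n - 2),
        residuals = numeric(0), term = "x")
  }
  ## normal-approximation arithmetic: t = 0.4 / sqrt(0.02) = 2.828
  cmp <- compareSlopes(mkFit(1.0, 0.1, 1000), mkFit(0.6, 0.1, 1000))
  expect_equal(cmp$statistic, 0.4 / sqrt(0.02), tolerance = 1e-10)
  expect_equal(cmp$p.value, 2 * pnorm(-0.4 / sqrt(0.02)), tolerance = 0.02)
  ## identical fits: t = 0, p = 1
  f <- mkFit(0.8, 0.05, 50)
  expect_identical(compareSlopes(f, f)$statistic, 0)
  expect_identical(compareSlopes(f, f)$p.value, 1)
  ## equal slopes from independent noiseless lines: p = 1 despite zero SE
  a <- suppressWarnings(fitOLS(1:10, 2 * (1:10) + 1))
  b <- suppressWarnings(fitOLS(1:10, 2 * (1:10) - 4))
  expect_identical(compareSlopes(a, b)$p.value, 1)
  ## intercept comparison picks up the 5-year offset between those lines
  expect_lt(compareSlopes(a, b, term = "intercept")$p.value, 1e-10)
})

test_that("age acceleration residuals match a hand-computed OLS fit", {
  ages <- c(30, 40, 50, 60, 70)
  dn <- c(33, 39, 55, 58, 76)
  want <- olsClosedForm(ages, dn)$residuals
  got <- ageAcceleration(dn, ages, direction = "dnam_on_age")
  expect_equal(unname(got), want, tolerance = 1e-10)
  expect_lt(abs(sum(got)), 1e-9)          # OLS residuals sum to zero
  ## perfect clock: all residuals zero
  expect_equal(unname(suppressWarnings(ageAcceleration(ages, ages))),
               rep(0, 5), tolerance = 1e-10)
  ## reversed direction regresses age on DNAm age
  wantRev <- olsClosedForm(dn, ages)$residuals
  expect_equal(unname(ageAcceleration(dn, ages, direction = "age_on_dnam")),
               wantRev, tolerance = 1e-10)
})

test_that("acceleration-covariate regression compares versions correctly", {
  set.seed(41)
  n <- 60
  ids <- sprintf("s%02d", 1:n)
  sex <- rep(c("male", "female"), length.out = n)
  acc <- setNames(rnorm(n), ids)
  ## identical accelerations: identical slopes, comparison p = 1
  same <- accelerationCovariateRegression(acc, acc, sex, reference = "male")
  expect_identical(same$comparison$p.value, 1)
  ## constant offset is absorbed by the intercept: p = 1 again
  off <- accelerationCovariateRegression(acc, acc - 3.2, sex,
                                         reference = "male")
  expect_equal(off$full@estimate[["slope"]], off$reduced@estimate[["slope"]],
               tolerance = 1e-12)
  expect_equal(off$comparison$p.value, 1, tolerance = 1e-9)
  expect_error(accelerationCovariateRegression(acc, acc, rep("f", n)),
               "2 observed levels|constant")
})

test_that("covariate CIs cover a null effect at roughly nominal rate", {
  ## simulation oracle: zero true sex effect, 95% CI should cover 0
  nCover <- 0
  nSeeds <- 200
  set.seed(99)
  for (rep in seq_len(nSeeds)) {
    n <- 500
    sex <- rbinom(n, 1, 0.5)
    accF <- rnorm(n)
    accR <- accF + rnorm(n, sd = 0.1)
    res <- accelerationCovariateRegression(accF, accR, sex)
    ci <- res$full@ci["slope", ]
    if (ci[1] <= 0 && ci[2] >= 0) nCover <- nCover + 1
  }
  expect_gte(nCover / nSeeds, 0.93)
})

test_that("platform offset regression recovers exact and null offsets", {
  ages <- seq(25, 85, by = 5)
  yA <- 0.8 * ages + 5
  yB <- 0.8 * ages + 5 - 4          # platform B shifted down 4 years
  res <- suppressWarnings(
    platformOffsetRegression(c(yA, yB),
                             rep(c("450k", "850k"), each = length(ages)),
                             c(ages, ages),
                             referencePlatform = "450k"))
  expect_equal(res$offset, -4, tolerance = 1e-10)
  expect_identical(res$platform, "850k")
  expect_error(platformOffsetRegression(yA, rep("450k", length(yA)), ages),
               "two platform")
  ## identical distributions: offset near 0 relative to its SE (sim oracle)
  nOK <- 0
  nSeeds <- 200
  for (seed in seq_len(nSeeds)) {
    set.seed(1000 + seed)
    a1 <- runif(150, 20, 90); a2 <- runif(150, 20, 90)
    y1 <- 0.9 * a1 + rnorm(150, sd = 3)
    y2 <- 0.9 * a2 + rnorm(150, sd = 3)
    r <- platformOffsetRegression(c(y1, y2),
                                  rep(c("A", "B"), each = 150),
                                  c(a1, a2), referencePlatform = "A")
    if (abs(r$offset) < 2 * r$se) nOK <- nOK + 1
  }
  expect_gte(nOK / nSeeds, 0.93)
})

test_that("stratified fits recover generative slopes under noise", {
  ## simulation oracle: slope estimates within 2 SE of truth in >= 95% of seeds
  nSeeds <- 200
  hitsY <- hitsO <- 0
  for (seed in seq_len(nSeeds)) {
    set.seed(2000 + seed)
    agesY <- runif(500, 0, 19.99)
    agesO <- runif(500, 20, 100)
    dn <- c(1.02 * agesY - 0.3, 0.85 * agesO + 7) + rnorm(1000, sd = 3)
    fits <- stratifiedClockRegression(dn, c(agesY, agesO), cutoff = 20)
    if (abs(fits$below@estimate[["slope"]] - 1.02) <=
          2 * fits$below@se[["slope"]]) hitsY <- hitsY + 1
    if (abs(fits$above@estimate[["slope"]] - 0.85) <=
          2 * fits$above@se[["slope"]]) hitsO <- hitsO + 1
  }
  ## nominal 2-SE coverage is ~95%; allow Monte Carlo slack
  expect_gte(hitsY / nSeeds, 0.93)
  expect_gte(hitsO / nSeeds, 0.93)
})
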