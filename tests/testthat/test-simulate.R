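test_that("cohort generation is deterministic and respects the model", {
  sp <- generativeSpec(nSamples = 25, nProbes = 30, seed = 7)
  a <- generateCohort(sp)
  b <- generateCohort(sp)
  expect_identical(betaValues(a), betaValues(b))
  expect_identical(sampleAnnotation(a), sampleAnnotation(b))
  ## a different seed changes the draw
  expect_false(identical(
    betaValues(generateCohort(generativeSpec(nSamples = 25, nProbes = 30,
                                             seed = 8))),
    betaValues(a)))
})

test_that("noiseless betas equal mu + slope * F(age) exactly", {
  sp <- generativeSpec(nSamples = 15, nProbes = 12, noiseSD = 0, seed = 3)
  bm <- generateCohort(sp)
  ages <- sampleAnnotation(bm)$age
  want <- outer(sp@slopes, oracleTransform(ages, sp@adultAge)) + sp@mu
  dimnames(want) <- dimnames(betaValues(bm))
  expect_equal(betaValues(bm), want, tolerance = 1e-12)
  ## zero slopes and zero noise: every probe constant at its baseline
  sp0 <- generativeSpec(nSamples = 10, nProbes = 5, noiseSD = 0,
                        slopes = rep(0, 5), seed = 4)
  b0 <- betaValues(generateCohort(sp0))
  expect_equal(b0, matrix(sp0@mu, 5, 10, dimnames = dimnames(b0)),
               tolerance = 1e-12)
})

test_that("developmental probes saturate at the adult-age knee", {
  ids <- sprintf("p%02d", 1:6)
  sp <- generativeSpec(nSamples = 12, nProbes = 6, noiseSD = 0,
                       agePool = c(5, 20, 50, 90),
                       developmentalProbes = ids[1:2],
                       probeIDs = ids, seed = 5)
  bm <- generateCohort(sp)
  ages <- sampleAnnotation(bm)$age
  adult <- ages >= 20
  b <- betaValues(bm)
  ## developmental probes are flat across adult ages...
  for (p in ids[1:2])
    expect_equal(b[p, adult], setNames(rep(sp@mu[[p]], sum(adult)),
                                       colnames(b)[adult]),
                 tolerance = 1e-12)
  ## ...ordinary probes keep tracking transformed age
  expect_gt(stats::sd(b[ids[3], adult]), 0)
})

test_that("the consistent clock has the stated closed form", {
  sp <- generativeSpec(nSamples = 5, nProbes = 9, seed = 17)
  clk <- constructConsistentClock(sp)
  s <- sp@slopes
  expect_equal(unname(clockWeights(clk)), unname(s / sum(s^2)),
               tolerance = 1e-12)
  expect_equal(sum(clockWeights(clk) * s), 1, tolerance = 1e-12)
  expect_equal(clockIntercept(clk), -sum(clockWeights(clk) * sp@mu),
               tolerance = 1e-12)
  ## single-probe subset: w = 1/s, intercept = -mu/s
  one <- constructConsistentClock(sp, probeSubset = sp@probeIDs[4])
  p <- sp@probeIDs[4]
  expect_equal(unname(clockWeights(one)), 1 / s[[p]], tolerance = 1e-12)
  expect_equal(clockIntercept(one), -sp@mu[[p]] / s[[p]], tolerance = 1e-12)
  ## all-zero slopes cannot support a clock
  spz <- generativeSpec(nSamples = 5, nProbes = 3, slopes = rep(0, 3),
                        seed = 1)
  expect_error(constructConsistentClock(spz), "zero")
})

test_that("dropping probes and mean-imputing at mu attenuates the score by rho", {
  ## noiseless algebra: masked-then-imputed score = (1 - rho) * F(age)
  sp <- generativeSpec(nSamples = 30, nProbes = 40, noiseSD = 0, seed = 23)
  clk <- constructConsistentClock(sp)
  w <- clockWeights(clk)
  dropped <- sp@probeIDs[1:5]
  rho <- sum(w[dropped] * sp@slopes[dropped])
  cohort <- generateCohort(sp)
  pl <- emulatePlatforms(cohort, dropped)
  expect_identical(nrow(pl$reduced), 35L)
  expect_identical(nrow(pl$full), 40L)
  pol <- imputationPolicy("reference_mean", referenceMeans = sp@mu[dropped])
  red <- transformedScore(applyClock(clk, pl$reduced, policy = pol))
  ages <- sampleAnnotation(cohort)$age
  expect_equal(unname(red), (1 - rho) * oracleTransform(ages, sp@adultAge),
               tolerance = 1e-9)
})

test_that("platform emulation reproduces the clock-size bookkeeping", {
  sp353 <- generativeSpec(nSamples = 3, nProbes = 353, seed = 2)
  pl <- emulatePlatforms(generateCohort(sp353), sp353@probeIDs[1:17])
  expect_identical(nrow(pl$reduced), 336L)
  sp71 <- generativeSpec(nSamples = 3, nProbes = 71, seed = 2)
  pl71 <- emulatePlatforms(generateCohort(sp71), sp71@probeIDs[1:6])
  expect_identical(nrow(pl71$reduced), 65L)
  ## dropping nothing: full equals reduced
  plN <- emulatePlatforms(pl$full, character(0))
  expect_identical(betaValues(plN$full), betaValues(plN$reduced))
})

test_that("meanTransformedAge agrees with numerical integration", {
  Fsat <- function(a) pmin(oracleTransform(a), 0)
  for (rng in list(c(0, 100), c(0, 20), c(30, 80), c(5, 45))) {
    wantF <- integrate(oracleTransform, rng[1], rng[2],
                       rel.tol = 1e-12)$value / diff(rng)
    wantG <- integrate(Fsat, rng[1], rng[2],
                       rel.tol = 1e-12)$value / diff(rng)
    expect_equal(meanTransformedAge(rng[1], rng[2]), wantF, tolerance = 1e-9)
    expect_equal(meanTransformedAge(rng[1], rng[2], saturating = TRUE),
                 wantG, tolerance = 1e-9)
  }
  expect_equal(meanTransformedAge(0, 0), -log(21), tolerance = 1e-12)
})

test_that("the masking study carries the requested signal fraction", {
  st <- simulateMaskingStudy(seed = 3, nSamples = 50, nProbes = 60,
                             nDropped = 6, droppedSignal = 0.08)
  expect_equal(st$droppedSignal, 0.08, tolerance = 1e-10)
  expect_identical(length(st$dropped), 6L)
  expect_identical(nrow(st$reduced), 54L)
  ## negative-signal variant flips the dropped fraction's sign
  stn <- simulateMaskingStudy(seed = 3, nSamples = 50, nProbes = 60,
                              nDropped = 6, droppedSignal = 0.08,
                              droppedPattern = "linear",
                              negativeDropped = TRUE)
  expect_equal(stn$droppedSignal, -0.08, tolerance = 1e-10)
  ## the clock stays exactly consistent even with negative weights
  spn <- stn$spec
  spn@noiseSD <- 0
  noiseless <- generateCohort(spn)
  ages <- dnamAge(applyClock(stn$clock, noiseless))
  expect_lt(max(abs(ages - sampleAnnotation(noiseless)$age)), 1e-6)
})

test_that("deviation SD follows the closed form sigma * sqrt(sum w_d^2)", {
  ## among samples well above the knee both scores sit on the linear branch,
  ## so SD(full - reduced DNAm age) = (A + 1) * sigma * sqrt(sum_d w_j^2)
  ratios <- numeric(0)
  for (seed in 1:40) {
    st <- simulateMaskingStudy(seed = seed, nSamples = 300, nProbes = 60,
                               nDropped = 8, noiseSD = 0.02,
                               ageRange = c(30, 100))
    pol <- imputationPolicy("reference_mean",
                            referenceMeans = st$referenceMeans)
    fa <- dnamAge(applyClock(st$clock, st$full, policy = pol))
    ra <- dnamAge(applyClock(st$clock, st$reduced, policy = pol))
    w <- clockWeights(st$clock)[st$dropped]
    want <- 21 * 0.02 * sqrt(sum(w^2))
    ratios <- c(ratios, stats::sd(fa - ra) / want)
  }
  expect_lt(abs(mean(ratios) - 1), 0.15)
  ## and it scales up with sigma
  st2 <- simulateMaskingStudy(seed = 1, nSamples = 300, nProbes = 60,
                              nDropped = 8, noiseSD = 0.04,
                              ageRange = c(30, 100))
  pol2 <- imputationPolicy("reference_mean",
                           referenceMeans = st2$referenceMeans)
  fa2 <- dnamAge(applyClock(st2$clock, st2$full, policy = pol2))
  ra2 <- dnamAge(applyClock(st2$clock, st2$reduced, policy = pol2))
  st1 <- simulateMaskingStudy(seed = 1, nSamples = 300, nProbes = 60,
                              nDropped = 8, noiseSD = 0.02,
                              ageRange = c(30, 100))
  fa1 <- dnamAge(applyClock(st1$clock, st1$full, policy = pol2))
  ra1 <- dnamAge(applyClock(st1$clock, st1$reduced, policy = pol2))
  expect_gt(stats::sd(fa2 - ra2), stats::sd(fa1 - ra1))
})

test_that("full and reduced DNAm ages stay highly correlated", {
  st <- simulateMaskingStudy(seed = 11, nSamples = 500)
  an <- runMaskingAnalysis(st$full, st$reduced, st$clock,
                           referenceMeans = st$referenceMeans)
  expect_gt(an$report@overall$cor_full_reduced, 0.98)
})
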