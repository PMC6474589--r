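makeBetas <- function(values) BetaMatrix(values)

test_that("ClockDefinition enforces its invariants", {
  clk <- ClockDefinition("toy", c(p1 = 0.2, p2 = -0.1), intercept = 1.5)
  expect_s4_class(clk, "ClockDefinition")
  expect_identical(clockSize(clk), 2L)
  expect_identical(clockProbes(clk), c("p1", "p2"))
  expect_identical(clockIntercept(clk), 1.5)
  expect_error(ClockDefinition("bad", numeric(0)), "at least one")
  expect_error(ClockDefinition("bad", c(1, 2)), "named")
  expect_error(ClockDefinition("bad", c(p = 1, p = 2)), "unique")
  expect_error(ClockDefinition("bad", c(p = 1), transform = "horvath",
                               adultAge = 0), "adultAge")
})

test_that("applyClock reproduces hand-computed scores", {
  ## all-zero weights: score is the intercept, inverse transform of 0 is 20
  null <- ClockDefinition("null", c(a = 0, b = 0), intercept = 0,
                          transform = "horvath", adultAge = 20)
  m <- matrix(runif(6), 2, 3, dimnames = list(c("a", "b"), c("s1", "s2", "s3")))
  expect_equal(unname(dnamAge(applyClock(null, makeBetas(m)))),
               rep(20, 3))

  ## identity clock by hand: 0.5 + 1.0*0.8 + (-0.5)*0.4 = 1.1
  toy <- ClockDefinition("toy", c(p1 = 1, p2 = -0.5), intercept = 0.5,
                         transform = "identity")
  tm <- matrix(c(0.8, 0.4), 2, 1, dimnames = list(c("p1", "p2"), "s1"))
  res <- applyClock(toy, makeBetas(tm))
  expect_equal(unname(dnamAge(res)), 1.1, tolerance = 1e-12)
  expect_equal(unname(transformedScore(res)), 1.1, tolerance = 1e-12)
  expect_identical(res@results$n_probes_used, 2L)
  expect_identical(res@results$n_probes_imputed, 0L)
})

test_that("a consistent synthetic clock recovers chronological age exactly", {
  sp <- generativeSpec(nSamples = 40, nProbes = 353, noiseSD = 0, seed = 11)
  clk <- constructConsistentClock(sp)
  cohort <- generateCohort(sp)
  ages <- dnamAge(applyClock(clk, cohort))
  chron <- sampleAnnotation(cohort)$age
  expect_lt(max(abs(ages - chron)), 1e-6)
})

test_that("applyClock is linear in the betas for identity clocks", {
  set.seed(5)
  clk <- ClockDefinition("lin", setNames(rnorm(6), paste0("p", 1:6)),
                         intercept = 0.3, transform = "identity")
  mk <- function() matrix(runif(6 * 4), 6, 4,
                          dimnames = list(paste0("p", 1:6), paste0("s", 1:4)))
  a <- mk(); b <- mk()
  lam <- 0.3
  sa <- transformedScore(applyClock(clk, makeBetas(a)))
  sb <- transformedScore(applyClock(clk, makeBetas(b)))
  sc <- transformedScore(applyClock(clk, makeBetas(lam * a + (1 - lam) * b)))
  expect_equal(sc, lam * sa + (1 - lam) * sb, tolerance = 1e-12)
})

test_that("applyClock is invariant to probe and sample ordering", {
  set.seed(9)
  clk <- ClockDefinition("ord", setNames(rnorm(8), paste0("p", 1:8)),
                         intercept = -0.2, transform = "horvath")
  m <- matrix(runif(8 * 5), 8, 5,
              dimnames = list(paste0("p", 1:8), paste0("s", 1:5)))
  ref <- dnamAge(applyClock(clk, makeBetas(m)))
  shuf <- m[sample(8), sample(5)]
  got <- dnamAge(applyClock(clk, makeBetas(shuf)))
  expect_equal(got[names(ref)], ref, tolerance = 1e-12)
})

test_that("applyClock fails loudly when probes cannot be resolved", {
  clk <- ClockDefinition("c", c(p1 = 1, p2 = 1), transform = "identity")
  m <- matrix(0.5, 1, 2, dimnames = list("p1", c("s1", "s2")))
  expect_error(applyClock(clk, makeBetas(m)), "p2")
  ## no overlap at all and no synthesising policy
  m2 <- matrix(0.5, 1, 1, dimnames = list("q9", "s1"))
  expect_error(applyClock(clk, makeBetas(m2), policy = imputationPolicy("knn")),
               "no clock probe")
  ## but reference-mean imputation can synthesise every probe
  got <- applyClock(clk, makeBetas(m2),
                    policy = imputationPolicy("reference_mean",
                      referenceMeans = c(p1 = 0.2, p2 = 0.3)))
  expect_equal(unname(dnamAge(got)), 0.5, tolerance = 1e-12)
  expect_identical(got@results$n_probes_imputed, 2L)
})

test_that("maskProbes drops listed probes and nothing else", {
  m <- randomBetaMatrix(10, 4, seed = 2)
  bm <- makeBetas(m)
  masked <- maskProbes(bm, c("cg002", "cg007"))
  expect_identical(nrow(masked), 8L)
  expect_identical(sampleIDs(masked), sampleIDs(bm))
  expect_identical(betaValues(masked), m[setdiff(rownames(m), c("cg002", "cg007")), ])
  ## input untouched; empty drop list is the identity
  expect_identical(nrow(bm), 10L)
  expect_identical(betaValues(maskProbes(bm, character(0))), m)
  expect_warning(maskProbes(bm, c("cg001", "nope")), "not present")
  expect_error(maskProbes(bm, rownames(m)), "every probe")
})

test_that("diffClockManifest counts missing clock probes", {
  clk <- ClockDefinition("c", c(a = 1, b = 2, c = 3, d = 4),
                         transform = "identity")
  d <- diffClockManifest(clk, c("a", "c", "x", "y"))
  expect_identical(sort(d$missingProbes), c("b", "d"))
  expect_identical(d$nMissing, 2L)
  expect_equal(d$fraction, 0.5)
  ## complete manifest: nothing missing
  d2 <- diffClockManifest(clk, letters[1:4])
  expect_identical(d2$nMissing, 0L)
  expect_error(diffClockManifest(clk, character(0)), "non-empty")
})

test_that("BetaMatrix validates and clips input", {
  m <- matrix(c(0.5, 1 + 1e-8, -1e-8, 0.2), 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  bm <- BetaMatrix(m)
  expect_true(all(betaValues(bm) >= 0 & betaValues(bm) <= 1))
  m[1, 1] <- 1.2
  expect_error(BetaMatrix(m), "out of \\[0, 1\\]")
  m2 <- matrix(0.5, 2, 1, dimnames = list(c("a", "a"), "s"))
  expect_error(BetaMatrix(m2), "duplicate probe")
})
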