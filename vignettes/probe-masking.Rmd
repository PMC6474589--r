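---
title: "Epigenetic clocks across array generations: models, imputation and the probe-masking analysis"
author: "dnamclock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Epigenetic clocks across array generations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnamclock)
```

## The model

A linear DNA methylation age clock scores a sample from its CpG beta values
$\beta_j \in [0,1]$ as

$$m = c + \sum_j w_j \beta_j,$$

with per-probe weights $w_j$ and intercept $c$.  Hannum-style clocks read
$m$ directly as age in years.  Horvath-style clocks interpret $m$ on a
transformed-age scale and invert

$$F(a) = \begin{cases}\log(a+1) - \log(A+1), & a \le A\\
(a - A)/(A+1), & a > A\end{cases}$$

to report years, where $A$ (`adultAge`, 20 y by default and configurable)
is the knee separating the logarithmic developmental regime — methylation
at clock CpGs changes rapidly in childhood — from the linear adult regime.
Natural logarithms are used throughout, following the convention of the
published calculator.  `inverseTransformAge()` is defined on all reals
(large negative scores approach $-1$ y), and round-trips `transformAge()`
to $10^{-9}$ over ages 0–150 (verified in the test suite).

Clock coefficients are *data*, not code: `readClock()` accepts the simple
`probe_id,weight` layout or the published supplements' column names, with
the intercept carried as an `(Intercept)` row.  A missing intercept is an
error for Horvath-style clocks (the inverse transform makes the intercept
load-bearing) and a warned default of 0 for identity clocks.

## Missing probes and imputation

When a manifest lacks clock CpGs — the EPIC (850k) design omits 17 of the
353 Horvath and 6 of the 71 Hannum probes — scoring requires imputation.
`applyClock()` makes the policy explicit (`imputationPolicy()`):

* `reference_mean` — substitute a probe's mean beta in a reference ("gold
  standard") cohort, the documented behaviour of the online Horvath
  calculator.  This is the default policy in the masking analyses because
  it is the only method that can resolve a probe absent from *every*
  sample.  Which imputation the online calculator applied to any given
  public run is not documented beyond "automatic"; treating it as
  reference-mean is an assumption, and the policy label is carried in the
  `ClockAges` provenance and CLI logs for that reason.
* `knn` — the Hannum-style workflow: for a probe row with missing cells,
  the $k$ nearest *fully observed* probe rows (Euclidean distance over the
  target's observed columns) supply the fill as their unweighted
  column mean.  Defaults: $k = 10$ (the conventional default of kNN
  microarray imputation); distances across probe rows, not samples,
  matching the orientation of the published workflow (neither the $k$, the
  metric, nor the orientation of the original is documented — these are
  declared assumptions).  Determinism: distance ties break by probe-ID
  byte order.  Restricting the neighbour pool to fully observed rows makes
  the limit case exact: with $k$ equal to the number of complete rows the
  fill is the per-column mean of all complete rows.  A row with no
  observed cell has no distance basis and is escalated as unresolved.
* `cohort_mean` — per-probe observed mean; cannot resolve fully absent
  probes.
* `constant` — a fixed fill value.

Probes *present* in the matrix but `NA` are treated identically to absent
probes under the chosen policy.  Anything still missing after imputation is
a hard error naming the probes — silent zero-filling is the failure mode
this interface exists to prevent.

## The masking identity

For any sample $i$, masking a probe set $D$ and reference-mean-imputing it
changes the transformed score by exactly

$$m_i^{\mathrm{full}} - m_i^{\mathrm{reduced}}
  = \sum_{j \in D} w_j\,(\beta_{ij} - \mathrm{ref}_j).$$

This identity is the analytic backbone of the whole deviation analysis: it
holds for arbitrary data and reference values, and the acceptance tests
verify it to $10^{-10}$ end to end through `maskProbes()` and
`applyClock()`.  On the years scale the identity maps through the inverse
transform, so a *constant* score offset appears as a deviation that grows
roughly in proportion to $(a+1)$ through development and is a constant
$(A+1)$-scaled offset in adults.

## The synthetic cohort generator

`generateCohort()` draws

$$\beta_{ij} = \mathrm{clip}_{[0.001,\,0.999]}\!\left(\mu_j + s_j\,
  T_j(a_i) + \varepsilon_{ij}\right),\qquad
  \varepsilon_{ij} \sim N(0, \sigma^2)\ \text{i.i.d.},$$

with ages uniform on a range (default 0–100 y, exercising both transform
regimes) or resampled from a supplied pool, and the seed fully determining
the output.  $T_j = F$ for ordinary probes.  Probes may instead be marked
*developmental*, with $T_j(a) = F(\min(a, A))$: their methylation changes
through development and plateaus in adults.  This extension is what lets
the generator reproduce the empirically observed cross-array behaviour of
the Horvath clock — an adult deviation that is *flat* in age.  If every
dropped probe kept tracking $F$ linearly, the masking identity above would
force the adult deviation to grow linearly at exactly the dropped signal
fraction per year, which is not the structure reported for real arrays;
probes whose dynamics are developmental, combined with an imputation
reference that does not match the cohort's adult plateau, produce the
constant adult offset instead.

`constructConsistentClock()` closes the loop: weights $w_j \propto s_j$
normalised so $\sum_j w_j s_j = 1$, intercept $-\sum_j w_j \mu_j$.  On
noiseless data the clock returns chronological age exactly (machine
precision; verified), and under noise the score error variance is
$\sigma^2 \sum_j w_j^2$.  An optional sign flip on a probe subset yields a
clock that is still exactly consistent while giving the dropped set a
*negative* signal fraction.

### Default study conditions

`simulateMaskingStudy()` assembles the full experiment.  Defaults: 1000
samples, ages U[0, 100], 353 probes with 17 dropped, dropped-signal
fraction $\rho = 0.05$ (the dropped slopes are rescaled so the fraction is
exact), noise SD $\sigma = 0.01$ on the beta scale, dropped probes
developmental, and imputation reference means computed analytically as the
population expectation $\mu_j + s_j\,\mathbb{E}[T_j]$ over the study age
distribution (`populationReferenceMeans()`, via the closed form in
`meanTransformedAge()`).

Two deliberate design choices deserve explanation:

* **Reference panel.** The default reference is a mixed-age population
  panel — the realistic description of the cohorts from which imputation
  references are actually derived.  Under it the adult deviation is a
  constant $(A+1)\rho\,|\mathbb{E}[F(\min(a,A))]| \approx 0.18$ y at the
  defaults.  A `reference = "newborn"` panel instead maximises the
  mismatch between the imputed value and the adult plateau and yields an
  adult underestimation of several years, the magnitude reported for real
  450k-vs-EPIC comparisons.  We did not make the multi-year offset the
  default: a constant adult offset $D$ forces the reduced transformed
  score below zero for chronological ages in $[A,\,A + D/(1-\rho)]$, and
  the inverse-transform curvature on that interval induces a small but —
  at $\sigma = 0.01$ — statistically detectable positive deviation slope
  just above the cutoff, contaminating the "flat in adults" structure the
  study is designed to exhibit cleanly.  The structural conclusions
  (slopes differ below the cutoff, a pure intercept shift above it) are
  identical under both panels; only the offset magnitude changes.
* **Hannum-like profile.** With `droppedPattern = "linear"` the dropped
  probes keep tracking $F$, and population-mean imputation produces a
  deviation $\propto \rho\,(F(a) - \bar F)$ that is *negative* in the
  young and *positive* in the old — the sign-varying misestimation profile
  characteristic of the 71-CpG clock, whose CpGs track age-varying blood
  cell composition.  `negativeDropped = TRUE` additionally flips the
  dropped set's signal fraction's sign.

What the generator deliberately does **not** emulate: probe-type (I/II)
chemistry differences, batch and normalisation effects, cell-composition
structure, or beta-distributed (heteroscedastic, boundary-inflated) noise —
noise is Gaussian-additive with clipping.  Passing tests therefore certify
the *arithmetic and statistical machinery* (scoring, imputation, masking
algebra, regressions) and the qualitative bias structure, not the
biological magnitude of any real-array offset; dataset-level numbers from
public GEO cohorts require the original multi-gigabyte downloads and are
out of desk scope.

## Comparison statistics

The deviation is defined throughout as full minus reduced DNAm age.
`pairedDeviationSummary()` bins it into closed-open 5-year age bins
(configurable), reports per-dataset and overall means/SDs, a paired
t test, and Pearson correlations (two-sided tests, $\alpha = 0.05$, no
multiplicity correction — single planned contrasts).  Samples lacking
chronological age stay in the paired summaries but drop out of age bins,
age-stratified regressions and correlations with age.

`stratifiedClockRegression()` fits OLS within the $<$ cutoff and
$\ge$ cutoff strata (cutoff 20 y by default, matching the transform knee;
upper stratum inclusive; strata under 3 aged samples are omitted with a
warning).  Coefficient equality between fits uses
$t = (b_1 - b_2)/\sqrt{SE_1^2 + SE_2^2}$ with $n_1 + n_2 - 4$ degrees of
freedom (`compareSlopes()`, which also serves intercepts — the adult-
stratum comparison of interest is an intercept shift).  Zero difference is
reported as $p = 1$ even for noiseless fits, where the statistic would
otherwise be 0/0.

`ageAcceleration()` defaults to residuals of DNAm age on chronological age
(the conventional direction); the literal inverse — age regressed on DNAm
age — appears in parts of the literature and is available as
`direction = "age_on_dnam"` rather than silently assumed.
`platformOffsetRegression()` estimates the age-adjusted mean DNAm-age
difference between exactly two platforms from the indicator coefficient of
`dnam ~ platform + age`.

All regressions are ordinary `stats::lm` fits repackaged with
$\pm t_{0.975,\,n-2}\,SE$ confidence intervals; the test suite checks them
against hand-solved normal equations to $10^{-8}$.

## Numerical choices and degenerate inputs

* Beta values outside $[0,1]$ by more than $10^{-6}$ are rejected; within
  tolerance they are clipped (public series matrices occasionally carry
  rounding spill).  `NA` cells parse as missing, never zero.
* Probe identifiers are opaque case-sensitive strings; no `cg` pattern is
  enforced, so synthetic IDs work everywhere.
* Text writers emit the shortest decimal that round-trips the double
  exactly, so write/read cycles are value-identical; the per-sample
  DNAm-age CSV intentionally rounds to 4 decimals (JSON summaries keep
  full precision).
* kNN with $k$ exceeding the candidate pool uses all candidates with a
  warning; masking every probe, constant covariates, single-platform
  offset models, and unresolvable probes are hard errors.
* Generated betas are clipped to $[0.001, 0.999]$; parameters that would
  clip *every* value are rejected.  The default amplitude ranges
  ($\mu_j \sim U(0.35, 0.65)$, $|s_j| \sim U(0.01, 0.06)$) keep noiseless
  trajectories strictly inside the bounds over ages 0–101 so clipping
  never actually engages and the analytic oracles hold exactly.

## Problem sizes used in validation

The shipped tests and the acceptance script run entirely on synthetic
data: cohorts of 1000 samples by 353 probes for the headline pipeline
(50 independent seeds for the structural recovery check), 200-seed
simulation batches for coverage and noise-scaling properties, and small
(10 by 6) matrices for exhaustive kNN enumeration.  These sizes were
chosen to make Monte Carlo conclusions stable while keeping a full
validation run in the order of seconds.

## Known limitations

* No re-training of clocks (no elastic net), no BMIQ/quantile
  normalisation, no idat-level preprocessing or QC — inputs are
  already-extracted beta matrices.
* Reference means ship only as user data or are computed from a designated
  cohort; the package bundles no biological constants beyond the
  EPIC-missing probe ID lists.
* The comparison layer pools or stratifies; there are no mixed-effects or
  dataset-random-effect models.
* Cross-platform conclusions drawn from the generator transfer to real
  arrays only insofar as the linear-clock-plus-imputation mechanism is the
  dominant source of inter-array deviation.
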