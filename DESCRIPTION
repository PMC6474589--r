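Package: dnamclock
Title: DNA Methylation Age Clocks and Cross-Array Probe-Masking Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Represents linear DNA-methylation age ("epigenetic clock")
    predictors -- Horvath-style clocks with the log-linear age transform and
    Hannum-style identity clocks -- as configurable data objects, and computes
    DNA methylation age from probe-by-sample beta-value matrices with
    configurable imputation (reference-mean, cohort-mean, k-nearest-neighbour,
    constant) of clock CpGs that are missing or absent. Quantifies the bias
    introduced when clock probes are absent from a microarray manifest, such as
    the Horvath and Hannum clock CpGs dropped from the Illumina MethylationEPIC
    (850k) design: probe-set diffing against a manifest, probe masking,
    paired full-versus-reduced deviation summaries, age-stratified regressions
    with slope- and intercept-equality tests, age-acceleration residuals, and
    adjusted cross-platform offset estimation. A synthetic-cohort generator
    with analytically consistent clocks provides exact oracles for every
    pipeline stage, so the full analysis is testable without array downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
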