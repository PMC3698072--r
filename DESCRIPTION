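Package: cytosig
Title: Sex-Stratified Cytokine Signature Classification for
    Exercise-Challenge Immune Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Implements a replication pipeline for sex-stratified analysis of
    plasma cytokine panels measured across a graded exercise challenge
    (rest, peak effort, recovery) in Gulf War Illness, Chronic Fatigue
    Syndrome and healthy-control cohorts.  Provides multiplex-immunoassay
    polynomial calibration, imputation/log2/z-score preprocessing,
    univariate group comparisons (pooled t on log2 data, Wilcoxon rank-sum,
    one-way ANOVA), two-class linear discriminant classification with
    pooled or diagonal covariance, partial-F stepwise variable selection,
    random-subset ensemble feature ranking, leave-one-out cross-validation
    with the five standard performance rates, and a synthetic correlated
    log-normal cohort generator so the whole workflow is testable without
    subject-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    MASS,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
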