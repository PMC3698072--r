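---
title: "Cytokine signature classification: models, choices and limits"
author: "cytosig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cytokine signature classification: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytosig)
```

`cytosig` replicates a sex-stratified cytokine classification workflow
for exercise-challenge immune profiling: 16 plasma cytokines measured at
rest (T0), peak effort (T1) and 4 h recovery (T2) in healthy, GWI and
CFS groups of both sexes, screened univariately and combined into linear
discriminant classifiers by two marker-selection strategies. This
vignette explains the models, the tunable parameters and why their
defaults are what they are, what the synthetic cohort generator does and
does not emulate, and the numerical choices that matter.

## From assay signal to feature matrix

Multiplex chemiluminescent panels are calibrated per cytokine by a
degree-2 polynomial of the signal, fit by least squares
(`fit_standard_curve()`); the "second-order" model is read as powers of
one signal variable. Predicted concentrations below zero are clipped to
0 and flagged rather than propagated as negative masses, which keeps the
later log2 transform definable while preserving the information that the
curve extrapolated; signals outside the standards' range are likewise
flagged. Assay repeatability is summarized as the mean coefficient of
variability across replicate sets (`assay_cv()`); typical values for
this panel class are ~0.20 inter-assay and ~0.09 intra-assay. Optional
per-cytokine detection limits convert sub-limit measurements to missing.

Panels are plain subjects × features tables with features named
`CYTOKINE_Tk` (e.g. `IL-10_T2`), explicit missingness masks (never
sentinel numbers), and deterministic cytokine-major column order.

## Preprocessing

The chain is impute → log2 → z-score (`preprocess_matrix()`):

- **Imputation constant** 0.0001 pg/mL, the replication value; by
  default it is inserted on the concentration scale (so it maps to
  log2(0.0001) ≈ −13.29, far below any observed value — imputed cells
  act as "very low", not "typical"). Whether the original imputation
  happened before or after the transform is not recoverable, so
  `impute_stage = "after_log"` is available.
- **z-scoring** uses the sample (n−1) SD; the population variant is a
  flag since the convention of the original software is unknown. The
  operation is idempotent and errors on constant features (the pipeline
  drops those first, since a constant carries no class information and
  has no z-score).
- Standardization is fit once on the full comparison cohort, matching a
  one-shot preprocessing description; `scale_in_fold = TRUE` refits it
  inside each LOOCV training fold for a leakage-free variant. Both modes
  are tested; on the synthetic template their assignments agree for all
  or nearly all subjects, because the held-out observation moves the
  full-cohort column means and SDs only slightly.

## Univariate screening

Per feature: group means/SEs on the raw scale, a pooled-variance t test
on log2 values (read of "standard parametric t test"; Welch by flag) and
a confirmatory Wilcoxon rank-sum on raw values — exact null distribution
when the pooled sample is ≤ 20 without ties, otherwise the normal
approximation with mid-rank tie correction and continuity correction.
No multiplicity correction is applied, mirroring the replication target,
but a Benjamini–Hochberg column is one flag away for reuse. A one-way
ANOVA (`one_way_anova()`) covers cohort descriptors.

## The discriminant model and its decision rule

For groups *I* and *J* the score is *s(x) = B₀ + x·B* with
*B = Σ⁻¹(μ_J − μ_I)* and *B₀* absorbing the midpoint and log prior
ratio; *s(x) ≥ 0* assigns *J*. The tie (a score of exactly 0) goes to
*J*, the orientation flip of the strict published rule "assign *I* when
0 < B₀ + x·B"; the convention is fixed by checking that the published
tables' five rates reproduce from their own confusion matrices with the
second-listed group as positive class.

- **Covariance**: `pooled_full` inverts the pooled within-group
  covariance; `diagonal` zeroes between-feature covariances, the
  stabilizing correction used when co-expressed markers are selected
  together. A singular pooled estimate falls back to a logged ridge of
  `1e-8 · trace/p` (or errors, by option); the diagonal mode instead
  rejects zero-variance features by name.
- **Priors** default to equal: the stratified group sizes are of
  comparable order and the original choice is unrecoverable;
  proportional priors are a flag and the intercept shifts by exactly the
  log prior ratio.
- **Standardized canonical coefficients** scale *B* to unit pooled
  within-group score variance, then multiply by each feature's pooled
  within-group SD. This makes a single-marker model exactly ±1.00 and
  lets correlated multi-marker models exceed 1 in magnitude — both
  patterns visible in the published tables; plain coefficient × SD
  scaling reproduces neither. The quantity is invariant to affine
  rescaling of any feature.
- Singleton classes are tolerated inside training folds (they contribute
  zero within-class scatter); at least 3 subjects keep the pooled
  estimate defined. This is required for LOOCV on the smallest strata.

**Evaluation** is leave-one-out cross-validation only — each subject is
assigned by a model refit without it — tallied into a 2×2 confusion
matrix from which accuracy, sensitivity, specificity, PPV and NPV are
computed (positive class = second-listed group; empty denominators yield
flagged `NA`s, not errors). Rates are reported at full precision and
half-up-rounded to 2 decimals for table comparison, since banker's
rounding would turn 0.865 into 0.86. By default LOOCV refits
coefficients on a fixed marker set; whether the original procedure also
re-ran selection per fold is ambiguous, so `reselect = TRUE` provides
the full-reselection variant for sensitivity analysis.

## Marker selection

**Stepwise partial-F** (`stepwise()`): the partial F of a candidate
given the current set is computed via OLS on a ±1 group indicator — the
classical stepwise-discriminant/regression equivalence — as
`F = (RSS_red − RSS_full)/(RSS_full/(n − k − 2))` on F(1, n − k − 2).
Entry takes the smallest p below 0.05 (ties: larger F, then feature
order); after each entry, included features with revised p above 0.10
are removed, largest first. `p_enter ≤ p_remove` prevents
enter/remove cycling, with a `max_steps` guard for adversarial
correlated designs. An empty result is a valid "no model" outcome and
renders as an NA table row. Rank-deficient candidates report F = 0,
p = 1 (ineligible) rather than erroring, so exact duplicates of selected
markers are silently skipped.

**Random-subset ensemble** (`ensemble_rank()`): "all possible subsets"
is implemented as described operationally — 500 seeded random draws of 5
features from the 48 candidates, duplicates across iterations allowed —
with an exhaustive mode for ≤ 20 features that serves as the test
oracle. Each subset is a diagonal-covariance discriminant scored by
LOOCV; a subset "passes" at accuracy ≥ 0.80. Frequencies are reported
over passing models (the published phrasing); a flag switches the
denominator to all models for diagnostics. Ties in the ranking break by
feature order so reports are reproducible. The ensemble loop uses an
algebraically identical fast LOOCV path (leave-one-out updates of
per-class sums and sums of squares); its agreement with the generic
fold-by-fold path is itself tested.

## The synthetic cohort generator

`study_template()` mirrors the target cohort: strata of 21/20/12 males
and 9/10/10 females (HC/GWI/CFS), 48 features. Each subject's log2
concentration vector is multivariate normal — baseline + stratum effect,
covariance D·R·D — exponentiated base 2, with cells masked completely at
random (2% by default). A log2-scale Gaussian is the natural choice
because the analysis pipeline itself log2-transforms before parametric
testing. The correlation recipe is a Kronecker product of a time-point
factor (r = 0.5 within a cytokine across phases) and a cytokine factor
(r = 0.1 across cytokines, with IL-1b ~ TNFb raised to 0.81, the
strongly co-expressed pair the analysis must cope with); the product
structure guarantees positive semi-definiteness, which ad-hoc block
matrices violate easily, and any hand-written matrix is eigenvalue
checked at spec construction.

Effect patterns are *plausible, not estimated*: illness and sex shifts
of 0.5–1.8 log2 units on IL-23/IL-10/IL-2/IL-17/IL-5/IL-13 features,
placed so that each stratified comparison is separable to roughly the
accuracy range the published tables report (0.7–0.9), including a
female-CFS stratum whose markers (IL-17 at peak effort, IL-10 at
recovery) are co-expressed enough that stepwise truncation struggles and
the ensemble is needed — the scenario the second selection method exists
for. Baselines (1–60 pg/mL scale) and SDs (1.2 log2 units ≈ 2.3-fold
spread) are ordinary plasma-cytokine magnitudes, with a mild myokine
bump at peak effort.

What the generator deliberately does **not** emulate: assay-level noise
and plate effects (concentrations are drawn directly), informative or
detection-limit missingness (masking is MCAR), longitudinal
autocorrelation beyond the correlation matrix, endocrine covariates, and
heavy tails (a contamination option exists for robustness work).
Passing tests therefore demonstrate that the *pipeline* recovers planted
structure under the design's sample sizes and correlation levels — not
that the original biological findings are correct, which would require
the original subjects.

## Numerical and testing choices

- Generation is a pure function of the spec, seed included; every
  stochastic operation takes or logs an explicit seed and reruns are
  byte-identical (tested on the JSON reports).
- Round-trip panel I/O writes 17 significant digits, so
  `read_panel(write_panel(p))` is bit-exact.
- Null LOOCV accuracy is checked against chance with a band of
  0.5 ± 0.06 at n = 15/15: leave-one-out discriminants are slightly
  pessimistic under the null (the held-out subject is excluded from its
  own class mean, biasing its score away), an O(1/n) effect the band
  must accommodate on top of Monte-Carlo error.
- Monte-Carlo tolerances elsewhere are sized at ~3 standard errors of
  the quantity under test (binomial SEs for rates, `sd/sqrt(2n)` for SD
  estimates), and oracle comparisons (normal-equations fits, Horner
  evaluation, enumeration of rank assignments or subsets, closed-form
  Bayes rule, `MASS::lda`) are exact to stated numerical tolerances.
- Problem sizes in the test-suite simulations (e.g. 20 seeds × 500
  ensemble iterations, 100 stepwise seeds, 1,000 null draws) are chosen
  to keep each property's Monte-Carlo error well inside its assertion
  band while the whole suite stays interactive (~1 minute).

## Known limitations

Only two-class linear discriminants are provided (no QDA, no >2-class
problems, no probability calibration or ROC analysis); stepwise
inference is the classical descriptive procedure, with no selective
inference correction; the calibration module fits polynomials, not
4PL/5PL logistic curves; and the ensemble's passing threshold is a fixed
configuration value, not tuned by nested cross-validation. These match
the replication scope; extensions would sit behind the same module
surfaces.
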