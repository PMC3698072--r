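# Synthetic exercise-challenge cytokine cohorts: multivariate log-normal
# concentrations with stratum-specific mean shifts, within-stratum feature
# correlation and missing-at-random cells, so every pipeline stage is
# testable without subject-level data.

#' Build a block correlation matrix for panel features
#'
#' Hand-writable correlation recipe with guaranteed positive
#' semi-definiteness: the feature correlation is the Kronecker product of
#' a cytokine factor (exchangeable at `within_timepoint`, with optional
#' strongly co-expressed cytokine pairs such as r = 0.81) and a time-point
#' factor (exchangeable at `within_cytokine`).  Resulting entries: same
#' cytokine across time points = `within_cytokine`; different cytokines at
#' the same time point = `within_timepoint` (or the pair value); different
#' cytokine and time point = the product of the two.
#'
#' @param features character vector of feature names ("CYTOKINE_Tk"),
#'   cytokine-major ordered as produced by [feature_keys()].
#' @param within_cytokine correlation between time points of the same
#'   cytokine (default 0.5).
#' @param within_timepoint correlation between different cytokines at the
#'   same time point (default 0).
#' @param cytokine_pairs list of `list(cytokine_a, cytokine_b, r)` entries
#'   for co-expressed cytokines.
#' @return correlation matrix (unit diagonal, symmetric), feature x
#'   feature.
#' @export
block_correlation <- function(features, within_cytokine = 0.5,
                              within_timepoint = 0,
                              cytokine_pairs = list()) {
  info <- parse_feature_keys(features)
  cytos <- unique(info$cytokine)
  tps <- unique(info$time_point)
  # cytokine-major layout (feature_keys order) means cytokine factor
  # varies slowest: R = C %x% T
  expected <- as.vector(t(outer(cytos, tps, paste, sep = "_")))
  if (!identical(features, expected)) {
    stop("features must be complete and cytokine-major ordered (see feature_keys())")
  }
  C <- matrix(within_timepoint, length(cytos), length(cytos),
              dimnames = list(cytos, cytos))
  diag(C) <- 1
  for (pr in cytokine_pairs) {
    C[pr[[1]], pr[[2]]] <- C[pr[[2]], pr[[1]]] <- pr[[3]]
  }
  T_ <- matrix(within_cytokine, length(tps), length(tps))
  diag(T_) <- 1
  R <- kronecker(C, T_)
  dimnames(R) <- list(features, features)
  R
}

#' Specification of a synthetic cohort
#'
#' Ground-truth recipe: stratum sizes per (sex, diagnosis), baseline
#' log2-scale means and SDs per feature, per-stratum additive log2 shifts,
#' a within-stratum correlation matrix, a missing-cell rate and a seed.
#' Generation draws each subject's 48-vector from a multivariate normal on
#' the log2 scale (mean = baseline + stratum effect, covariance
#' `D R D`), exponentiates base 2 to concentrations, and masks cells
#' completely at random.
#'
#' @param strata data frame with columns `sex`, `diagnosis`, `n`.
#' @param features feature names (defaults to the 48 study keys).
#' @param baseline named numeric vector of log2 means per feature.
#' @param sds named numeric vector of log2 SDs per feature (default 1).
#' @param effects matrix of additive log2 shifts, rows named
#'   "sex.diagnosis", columns = features; missing rows mean no shift.
#' @param correlation feature correlation matrix (default identity);
#'   must be symmetric positive semi-definite with unit diagonal.
#' @param missing_rate probability a cell is masked (default 0).
#' @param seed integer seed; generation is a pure function of the spec.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(strata, features = feature_keys(),
                           baseline = NULL, sds = NULL, effects = NULL,
                           correlation = NULL, missing_rate = 0,
                           seed = 1L) {
  stopifnot(is.data.frame(strata),
            all(c("sex", "diagnosis", "n") %in% names(strata)))
  if (any(strata$n < 0)) stop("group sizes must be >= 0")
  if (missing_rate < 0 || missing_rate > 1) stop("missing_rate must be in [0, 1]")
  p <- length(features)
  if (is.null(baseline)) baseline <- stats::setNames(rep(3, p), features)
  if (is.null(sds)) sds <- stats::setNames(rep(1, p), features)
  baseline <- baseline[features]; sds <- sds[features]
  if (anyNA(baseline) || anyNA(sds)) stop("baseline/sds must cover every feature")
  if (any(sds <= 0)) stop("log2 SDs must be positive")
  keys <- paste(strata$sex, strata$diagnosis, sep = ".")
  if (is.null(effects)) {
    effects <- matrix(0, length(keys), p, dimnames = list(keys, features))
  } else {
    eff <- matrix(0, length(keys), p, dimnames = list(keys, features))
    for (k in intersect(rownames(effects), keys)) {
      cols <- intersect(colnames(effects), features)
      eff[k, cols] <- effects[k, cols]
    }
    effects <- eff
  }
  if (is.null(correlation)) {
    correlation <- diag(p)
    dimnames(correlation) <- list(features, features)
  }
  if (!isTRUE(all.equal(correlation, t(correlation))) ||
      !isTRUE(all.equal(unname(diag(correlation)), rep(1, p)))) {
    stop("correlation must be symmetric with unit diagonal")
  }
  ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop(sprintf("correlation matrix is not positive semi-definite (smallest eigenvalue %.3g)",
                 min(ev)))
  }
  structure(list(strata = strata, features = features, baseline = baseline,
                 sds = sds, effects = effects, correlation = correlation,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic cohort from a spec
#'
#' @param spec a [synthetic_spec()].
#' @return list with `panel` (a `cytokine_panel`) and `truth` (the effect
#'   matrix, per-feature log2 SDs and the list of informative features —
#'   those whose effect differs across any pair of strata).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  p <- length(spec$features)
  D <- diag(spec$sds, p)
  Sigma <- D %*% spec$correlation %*% D
  vals <- NULL; sexes <- character(0); diags <- character(0); ids <- character(0)
  for (r in seq_len(nrow(spec$strata))) {
    n <- spec$strata$n[r]
    if (n == 0) next
    key <- paste(spec$strata$sex[r], spec$strata$diagnosis[r], sep = ".")
    mu <- spec$baseline + spec$effects[key, ]
    Z <- MASS::mvrnorm(n, mu = mu, Sigma = Sigma)
    if (n == 1) Z <- matrix(Z, nrow = 1)
    vals <- rbind(vals, 2^Z)
    sexes <- c(sexes, rep(spec$strata$sex[r], n))
    diags <- c(diags, rep(spec$strata$diagnosis[r], n))
    ids <- c(ids, sprintf("%s_%s_%02d", spec$strata$sex[r],
                          spec$strata$diagnosis[r], seq_len(n)))
  }
  colnames(vals) <- spec$features
  rownames(vals) <- ids
  mask <- matrix(stats::runif(length(vals)) < spec$missing_rate,
                 nrow(vals), ncol(vals), dimnames = dimnames(vals))
  informative <- spec$features[apply(spec$effects, 2, function(col) {
    max(col) - min(col) > 0
  })]
  panel <- cytokine_panel(vals, sex = sexes, diagnosis = diags,
                          subject_id = ids, missing_mask = mask)
  list(panel = panel,
       truth = list(effects = spec$effects, sds = spec$sds,
                    informative = informative, seed = spec$seed))
}

#' Study-sized synthetic cohort template
#'
#' A `synthetic_spec` mirroring the study's stratum sizes (male HC/GWI/CFS
#' 21/20/12; female 9/10/10; 82 subjects, 48 features) with a documented
#' *plausible* effect pattern — synthetic by construction, not the study's
#' estimated effects: illness shifts on IL-23/IL-10/IL-2/IL-17/IL-5
#' features and a female-elevated IL-23/IL-12 sex contrast; moderate
#' within-cytokine correlation across time points and one strongly
#' co-expressed pair (IL-1b_T0 ~ TNFb_T0, r = 0.81); 2% missing cells.
#'
#' @param seed integer seed (default 1).
#' @param missing_rate fraction of masked cells (default 0.02).
#' @return a `synthetic_spec`.
#' @export
study_template <- function(seed = 1L, missing_rate = 0.02) {
  strata <- data.frame(
    sex = rep(c("male", "female"), each = 3),
    diagnosis = rep(c("HC", "GWI", "CFS"), 2),
    n = c(21L, 20L, 12L, 9L, 10L, 10L),
    stringsAsFactors = FALSE
  )
  feats <- feature_keys()
  # plausible resting plasma levels, log2 pg/mL (roughly 1-60 pg/mL)
  base_cyto <- c("IL-1a" = 2.0, "IL-1b" = 1.5, "IL-2" = 2.5, "IL-4" = 1.0,
                 "IL-5" = 1.5, "IL-6" = 2.0, "IL-8" = 3.5, "IL-10" = 2.5,
                 "IL-12p70" = 2.0, "IL-13" = 2.5, "IL-15" = 2.0,
                 "IL-17" = 2.5, "IL-23" = 4.0, "IFNg" = 3.0, "TNFa" = 3.0,
                 "TNFb" = 2.0)
  info <- parse_feature_keys(feats)
  baseline <- stats::setNames(base_cyto[info$cytokine], feats)
  # mild exercise response on myokines at peak effort
  myo <- info$cytokine %in% c("IL-6", "IL-8", "IL-10", "IL-15") &
    info$time_point == "T1"
  baseline[myo] <- baseline[myo] + 0.5
  sds <- stats::setNames(rep(1.2, length(feats)), feats)
  shift <- function(...) {
    v <- stats::setNames(rep(0, length(feats)), feats)
    args <- list(...)
    for (nm in names(args)) v[nm] <- args[[nm]]
    v
  }
  effects <- rbind(
    # females run higher IL-23 (all phases) and IL-12 post exercise
    "female.HC" = shift("IL-23_T0" = 1.2, "IL-23_T1" = 1.2, "IL-23_T2" = 1.2,
                        "IL-12p70_T2" = 1.0),
    "female.GWI" = shift("IL-23_T0" = 0.6, "IL-23_T1" = 0.6,
                         "IL-5_T1" = 1.2, "IL-17_T1" = -1.0,
                         "IL-8_T1" = 0.8),
    "female.CFS" = shift("IL-23_T0" = 1.2, "IL-23_T1" = 1.2, "IL-23_T2" = 1.2,
                         "IL-12p70_T2" = 1.0,
                         "IL-17_T1" = 1.6, "IL-10_T2" = -1.8,
                         "IL-5_T2" = -1.2, "IL-4_T1" = -1.0),
    "male.GWI" = shift("IL-13_T0" = 1.0, "IL-10_T0" = -1.0, "IL-23_T0" = 0.5,
                       "IL-13_T2" = 1.0, "IL-10_T2" = -0.8, "IL-1b_T2" = -0.6),
    "male.CFS" = shift("IL-23_T0" = 1.0, "IL-23_T2" = 1.0,
                       "IL-2_T1" = 1.2, "IL-2_T2" = 1.0, "IL-10_T1" = -1.0)
  )
  R <- block_correlation(feats, within_cytokine = 0.5, within_timepoint = 0.1,
                         cytokine_pairs = list(list("IL-1b", "TNFb", 0.81)))
  synthetic_spec(strata, features = feats, baseline = baseline, sds = sds,
                 effects = effects, correlation = R,
                 missing_rate = missing_rate, seed = seed)
}
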