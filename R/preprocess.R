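# Preprocessing chain used before regression/classification:
# impute missing cells with a small non-zero constant, log2 transform,
# z-score each feature.

#' Impute missing cells with a constant
#'
#' Replaces masked cells with a small positive constant (study value
#' 0.0001 pg/mL) so that every profile can enter the regression
#' calculations; all other cells are unchanged and the mask is kept for
#' provenance.
#'
#' @param X numeric matrix (may contain `NA` at masked cells).
#' @param mask logical matrix of missing cells; defaults to `is.na(X)`.
#' @param impute_value positive constant (default 1e-4).
#' @return numeric matrix with attribute `imputed` (the mask).
#' @export
impute_missing <- function(X, mask = is.na(X), impute_value = 1e-4) {
  X <- as.matrix(X)
  mask <- as.matrix(mask)
  if (!identical(dim(mask), dim(X))) stop("mask must match X in shape")
  if (!is.numeric(impute_value) || impute_value <= 0) {
    stop("impute_value must be a positive number")
  }
  X[mask] <- impute_value
  structure(X, imputed = mask)
}

#' Elementwise log2 transform
#'
#' @param X numeric matrix, all entries strictly positive (impute first).
#' @return `log2(X)`.
#' @export
log2_transform <- function(X) {
  X <- as.matrix(X)
  bad <- which(is.na(X) | X <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    rn <- rownames(X)[bad[1, 1]] %||% bad[1, 1]
    cn <- colnames(X)[bad[1, 2]] %||% bad[1, 2]
    stop(sprintf("non-positive or missing entry at (%s, %s): impute before log2",
                 rn, cn))
  }
  log2(X)
}

#' Column-wise z-score standardization
#'
#' Centers each feature to mean 0 and scales to unit variance.  The scale
#' uses the sample (n-1) standard deviation by default; the population (n)
#' variant is available since the source software convention is not
#' recoverable.
#'
#' @param X numeric matrix.
#' @param sd_type `"sample"` (n-1, default) or `"population"` (n).
#' @param center,scale optional fixed parameters (e.g. from a training
#'   fold); both must be supplied together.
#' @return standardized matrix with attributes `center` and `scale`.
#' @export
zscore <- function(X, sd_type = c("sample", "population"),
                   center = NULL, scale = NULL) {
  X <- as.matrix(X)
  sd_type <- match.arg(sd_type)
  if (is.null(center) != is.null(scale)) {
    stop("supply center and scale together or not at all")
  }
  if (is.null(center)) {
    center <- colMeans(X)
    scale <- apply(X, 2, stats::sd)
    if (sd_type == "population") {
      scale <- scale * sqrt((nrow(X) - 1) / nrow(X))
    }
    zero <- which(!is.finite(scale) | scale == 0)
    if (length(zero)) {
      stop("zero-variance feature(s): ",
           paste(colnames(X)[zero] %||% zero, collapse = ", "))
    }
  }
  out <- sweep(sweep(X, 2, center, `-`), 2, scale, `/`)
  structure(out, center = center, scale = scale)
}

#' Full preprocessing chain for a cohort matrix
#'
#' Applies impute -> log2 -> z-score (imputation on the concentration scale
#' by default, configurable to the log2 scale).  Deterministic: identical
#' inputs give bit-identical outputs.
#'
#' @param X numeric concentration matrix.
#' @param mask logical missingness matrix (default `is.na(X)`).
#' @param impute_value imputation constant (default 1e-4 pg/mL).
#' @param impute_stage `"before_log"` (default; the constant is a
#'   concentration, so 1e-4 maps to log2(1e-4) = -13.29) or `"after_log"`
#'   (the constant is inserted on the log2 scale).
#' @param standardize apply the z-score step (default TRUE).
#' @param sd_type passed to [zscore()].
#' @return preprocessed matrix.
#' @export
preprocess_matrix <- function(X, mask = is.na(X), impute_value = 1e-4,
                              impute_stage = c("before_log", "after_log"),
                              standardize = TRUE,
                              sd_type = "sample") {
  impute_stage <- match.arg(impute_stage)
  if (impute_stage == "before_log") {
    out <- log2_transform(impute_missing(X, mask, impute_value))
  } else {
    Xs <- as.matrix(X)
    Xs[as.matrix(mask)] <- 1  # placeholder > 0; overwritten below
    out <- log2_transform(Xs)
    out[as.matrix(mask)] <- impute_value
  }
  if (standardize) out <- zscore(out, sd_type = sd_type)
  out
}
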