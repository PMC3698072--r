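# Multiplex-assay calibration: per-cytokine polynomial standard curves
# mapping chemiluminescent signal to predicted concentration, plus assay
# coefficient-of-variability summaries.

#' Fit a polynomial standard curve
#'
#' Least-squares fit of concentration on powers 1..`degree` of the assay
#' signal, `Y_p = b0 + b1*X + ... + bk*X^k` (study degree k = 2).  The
#' "X_1 ... X_k" of the calibration model are powers of the single signal
#' variable, i.e. univariate polynomial regression.
#'
#' @param signal numeric vector of measured signals for the standards.
#' @param concentration numeric vector of known concentrations (pg/mL).
#' @param degree polynomial degree k >= 1 (default 2).
#' @param cytokine optional cytokine label carried on the curve.
#' @return object of class `standard_curve`: coefficients `b0..bk`,
#'   `degree`, `fit_range` (signal range of the standards), `residuals`,
#'   `fitted`, and a `monotone_increasing` flag (whether the fitted
#'   derivative stays positive across `fit_range`; a `FALSE` value is a
#'   curve-quality warning, signalled at fit time).
#' @export
#' @examples
#' s <- 0:4
#' fit_standard_curve(s, 2 + 3 * s + 0.5 * s^2)$coefficients
fit_standard_curve <- function(signal, concentration, degree = 2L,
                               cytokine = NA_character_) {
  stopifnot(length(signal) == length(concentration), degree >= 1)
  if (anyNA(signal) || anyNA(concentration)) stop("standards must be complete")
  if (length(unique(signal)) == 1L) {
    stop("all standard signals are identical: singular design")
  }
  if (length(unique(signal)) < degree + 1L) {
    stop(sprintf("need at least %d distinct signal values for degree %d (got %d)",
                 degree + 1L, degree, length(unique(signal))))
  }
  fit <- stats::lm(concentration ~ stats::poly(signal, degree, raw = TRUE))
  b <- unname(coef(fit))
  names(b) <- paste0("b", 0:degree)
  fit_range <- range(signal)
  # derivative sign check over a grid of the fitted range
  grid <- seq(fit_range[1], fit_range[2], length.out = 201L)
  dcoef <- b[-1] * seq_len(degree)
  deriv <- rowSums(outer(grid, seq_len(degree) - 1L, `^`) *
                     rep(dcoef, each = length(grid)))
  mono <- all(deriv > 0)
  if (!mono) {
    warning(sprintf("standard curve%s is not monotone increasing across its fit range",
                    if (is.na(cytokine)) "" else paste0(" for ", cytokine)))
  }
  structure(list(cytokine = cytokine, degree = as.integer(degree),
                 coefficients = b, fit_range = fit_range,
                 fitted = unname(stats::fitted(fit)),
                 residuals = unname(stats::residuals(fit)),
                 monotone_increasing = mono),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("<standard_curve>%s degree %d\n",
              if (is.na(x$cytokine)) "" else paste0(" ", x$cytokine),
              x$degree))
  print(signif(x$coefficients, 6))
  invisible(x)
}

#' Predict concentration from assay signal
#'
#' Evaluates the calibration polynomial.  Negative predictions are clipped
#' to 0 (keeping downstream log transforms definable) and flagged; signals
#' outside the standards' range are flagged as extrapolated.  Flags never
#' raise errors.
#'
#' @param curve a [fit_standard_curve()] result.
#' @param signal numeric vector of signals.
#' @return numeric vector of predicted concentrations with logical
#'   attributes `clipped` and `extrapolated` (one flag per signal).
#' @export
predict_concentration <- function(curve, signal) {
  stopifnot(inherits(curve, "standard_curve"))
  b <- curve$coefficients
  # Horner-free direct power sum; the test suite checks against Horner
  yp <- rowSums(outer(signal, 0:curve$degree, `^`) *
                  rep(b, each = length(signal)))
  clipped <- yp < 0
  yp[clipped] <- 0
  extrapolated <- signal < curve$fit_range[1] | signal > curve$fit_range[2]
  structure(yp, clipped = clipped, extrapolated = extrapolated)
}

#' Assay coefficient of variability
#'
#' CV per replicate set (sample standard deviation / mean) and their
#' average, the summary used for inter-assay (study value 0.20) and
#' intra-assay (0.09) repeatability.
#'
#' @param replicate_sets list of numeric vectors, each a set of replicate
#'   concentration measurements (length >= 2, positive mean).
#' @return list with `cv` (per-set CVs) and `mean_cv`.
#' @export
#' @examples
#' assay_cv(list(c(10, 10, 10), c(8, 12)))
assay_cv <- function(replicate_sets) {
  stopifnot(is.list(replicate_sets), length(replicate_sets) >= 1)
  cvs <- vapply(seq_along(replicate_sets), function(i) {
    x <- replicate_sets[[i]]
    if (length(x) < 2L) stop("replicate set ", i, " has fewer than 2 values")
    m <- mean(x)
    if (m <= 0) stop("replicate set ", i, " has non-positive mean")
    stats::sd(x) / m
  }, numeric(1))
  list(cv = cvs, mean_cv = mean(cvs))
}

#' Apply detection limits to a panel
#'
#' Concentrations below a cytokine's lower detection limit become missing
#' (mask set), mirroring assay reporting practice.  Limits are optional
#' configuration; cytokines without a limit are left untouched.
#'
#' @param panel a `cytokine_panel`.
#' @param limits named numeric vector of lower limits (pg/mL) by cytokine.
#' @return the panel with sub-limit cells marked missing.
#' @export
apply_detection_limits <- function(panel, limits) {
  stopifnot(inherits(panel, "cytokine_panel"))
  if (!length(limits)) return(panel)
  finfo <- panel_features(panel)
  vals <- panel$values
  mask <- panel$missing
  for (cy in intersect(names(limits), unique(finfo$cytokine))) {
    cols <- finfo$feature[finfo$cytokine == cy]
    below <- !mask[, cols, drop = FALSE] &
      vals[, cols, drop = FALSE] < limits[[cy]]
    mask[, cols][below] <- TRUE
    vals[, cols][below] <- NA_real_
  }
  cytokine_panel(vals, sex = panel$subjects$sex,
                 diagnosis = panel$subjects$diagnosis,
                 subject_id = panel$subjects$subject_id,
                 missing_mask = mask)
}
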