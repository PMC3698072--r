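# Two-class linear discriminant classification with the study's decision
# rule, pooled-full or diagonal covariance, SPSS-style standardized
# canonical coefficients, leave-one-out cross-validation and the five
# performance rates.
#
# Decision rule: the fitted score is s(x) = B0 + x.B with
# B = Sigma^-1 (mu_J - mu_I) and B0 absorbing the midpoint and the log
# prior ratio.  A subject is assigned to group J (the second-listed,
# "positive" group) when s(x) >= 0 and to group I when s(x) < 0; a score of
# exactly 0 goes to group J, the orientation flip of the strict rule
# "assign to I if 0 < B0 + x.B".

#' Fit a two-class linear discriminant model
#'
#' @param X numeric matrix, subjects x features (preprocessed).
#' @param y two-level factor (second level = group J, the positive class)
#'   or 0/1 vector.
#' @param covariance_mode `"pooled_full"` (pooled within-group covariance)
#'   or `"diagonal"` (between-feature covariances zeroed, the correction
#'   used when markers are strongly co-expressed).
#' @param priors `"equal"` (default) or `"proportional"` to group sizes.
#' @param on_singular in pooled mode, `"ridge"` (default) adds a logged
#'   ridge of `1e-8 * trace/p` to a singular pooled covariance;
#'   `"error"` stops and suggests diagonal mode instead.
#' @return object of class `cyto_lda`: `features`, `groups` (I, J),
#'   `B0`, `B` (aligned to features), `standardized` (standardized
#'   canonical coefficients), `covariance_mode`, `priors`, group means and
#'   the within-group covariance used.
#' @export
fit_lda <- function(X, y,
                    covariance_mode = c("pooled_full", "diagonal"),
                    priors = c("equal", "proportional"),
                    on_singular = c("ridge", "error")) {
  covariance_mode <- match.arg(covariance_mode)
  priors <- match.arg(priors)
  on_singular <- match.arg(on_singular)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  y <- as_two_groups(y)
  gI <- levels(y)[1]; gJ <- levels(y)[2]
  nI <- sum(y == gI); nJ <- sum(y == gJ)
  # singleton classes are tolerated (they arise in small LOOCV folds and
  # contribute zero within-class scatter); at least 3 subjects overall keep
  # the pooled covariance estimable
  if (nI < 1L || nJ < 1L || nI + nJ < 3L) {
    stop("need both classes non-empty and at least 3 subjects")
  }
  XI <- X[y == gI, , drop = FALSE]
  XJ <- X[y == gJ, , drop = FALSE]
  muI <- colMeans(XI); muJ <- colMeans(XJ)
  p <- ncol(X)
  Sw <- (crossprod(sweep(XI, 2, muI)) + crossprod(sweep(XJ, 2, muJ))) /
    (nI + nJ - 2)
  if (covariance_mode == "diagonal") {
    d <- diag(Sw)
    zero <- which(d <= 0 | !is.finite(d))
    if (length(zero)) {
      stop("zero-variance feature(s) in diagonal mode: ",
           paste(colnames(X)[zero], collapse = ", "))
    }
    Suse <- diag(d, nrow = p)
    B <- (muJ - muI) / d
  } else {
    Suse <- Sw
    B <- tryCatch(solve(Sw, muJ - muI), error = function(e) NULL)
    if (is.null(B)) {
      if (on_singular == "error") {
        stop("pooled within-group covariance is singular; ",
             "use covariance_mode = 'diagonal' or the ridge fallback")
      }
      eps <- 1e-8 * sum(diag(Sw)) / p
      message(sprintf("pooled covariance singular: ridge %.3g applied", eps))
      Suse <- Sw + diag(eps, p)
      B <- solve(Suse, muJ - muI)
    }
  }
  pJ <- if (priors == "equal") 0.5 else nJ / (nI + nJ)
  B0 <- -sum(B * (muI + muJ) / 2) + log(pJ / (1 - pJ))
  dimnames(Suse) <- list(colnames(X), colnames(X))
  model <- structure(list(features = colnames(X),
                          groups = c(gI, gJ), positive = gJ,
                          B0 = unname(B0), B = unname(B),
                          covariance_mode = covariance_mode,
                          priors = priors,
                          mu = rbind(I = muI, J = muJ),
                          Sw = Suse, n = c(nI, nJ)),
                     class = "cyto_lda")
  model$standardized <- standardized_coefficients(model)
  model
}

#' @export
print.cyto_lda <- function(x, ...) {
  cat(sprintf("<cyto_lda> %s vs %s (%s covariance, %s priors)\n",
              x$groups[1], x$groups[2], x$covariance_mode, x$priors))
  print(data.frame(feature = x$features, B = x$B,
                   standardized = x$standardized))
  invisible(x)
}

#' Standardized canonical coefficients
#'
#' Discriminant coefficients placed on a comparable scale: the coefficient
#' vector is normalized so the discriminant score has unit pooled
#' within-group variance, then each entry is multiplied by its feature's
#' pooled within-group standard deviation.  A single-feature model
#' therefore always has a standardized coefficient of +-1.00, while
#' correlated multi-feature models can exceed 1 in magnitude.  Invariant to
#' affine rescaling of individual features.
#'
#' @param model a fitted `cyto_lda`.
#' @return numeric vector aligned to `model$features`.
#' @export
standardized_coefficients <- function(model) {
  stopifnot(inherits(model, "cyto_lda"))
  B <- model$B
  Sw <- model$Sw
  denom <- sqrt(drop(t(B) %*% Sw %*% B))
  if (denom == 0) return(rep(0, length(B)))
  unname((B / denom) * sqrt(diag(Sw)))
}

#' Classify observations with a fitted discriminant model
#'
#' @param object a `cyto_lda`.
#' @param newdata numeric matrix or vector on the model's feature scale.
#' @param ... unused.
#' @return factor of assigned groups with attribute `score`
#'   (`B0 + x.B`; `score >= 0` assigns group J).
#' @export
predict.cyto_lda <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$B)) {
    stop("newdata has ", ncol(newdata), " columns; model expects ",
         length(object$B))
  }
  s <- drop(object$B0 + newdata %*% object$B)
  assigned <- factor(ifelse(s >= 0, object$groups[2], object$groups[1]),
                     levels = object$groups)
  structure(assigned, score = s)
}

#' Construct a confusion matrix from counts
#'
#' Counts are indexed (true group, assigned group) with the second-listed
#' group as the positive class.
#'
#' @param counts 2x2 numeric matrix of non-negative counts.
#' @param groups character pair (group I, group J).
#' @param positive positive class label (default group J).
#' @return object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(counts, groups, positive = groups[2]) {
  counts <- as.matrix(counts)
  stopifnot(identical(dim(counts), c(2L, 2L)), all(counts >= 0),
            length(groups) == 2L, positive %in% groups)
  dimnames(counts) <- list(true = groups, assigned = groups)
  structure(list(counts = counts, groups = groups, positive = positive),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> positive class: %s\n", x$positive))
  print(x$counts)
  invisible(x)
}

# tally true/assigned factor pairs into a confusion_matrix
tally_confusion <- function(true, assigned, groups) {
  counts <- table(factor(true, levels = groups),
                  factor(assigned, levels = groups))
  confusion_matrix(unclass(counts), groups)
}

#' Leave-one-out cross-validation of a discriminant model
#'
#' Each subject is assigned by a model refit on the remaining N-1 subjects.
#' By default the feature set is fixed and only the coefficients are refit
#' per fold; `reselect = TRUE` reruns stepwise selection inside every
#' training fold (sensitivity analysis).  `scale_in_fold = TRUE` refits the
#' z-score standardization on each training fold (leakage-free variant)
#' instead of assuming `X` was standardized once on the full cohort.
#'
#' @param X numeric matrix, subjects x features.
#' @param y two-level factor / 0-1 labels (second level positive).
#' @param features columns to use (default all).
#' @param covariance_mode,priors,on_singular passed to [fit_lda()].
#' @param reselect rerun stepwise selection within each fold.
#' @param p_enter,p_remove stepwise thresholds when `reselect = TRUE`.
#' @param scale_in_fold refit standardization per training fold.
#' @return `confusion_matrix` with attribute `assigned` (per-subject
#'   assignments in input order).
#' @export
loocv <- function(X, y, features = colnames(X),
                  covariance_mode = "pooled_full", priors = "equal",
                  on_singular = "ridge",
                  reselect = FALSE, p_enter = 0.05, p_remove = 0.10,
                  scale_in_fold = FALSE) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) {
    colnames(X) <- paste0("V", seq_len(ncol(X)))
    features <- colnames(X)
  }
  y <- as_two_groups(y)
  n <- nrow(X)
  if (n < 4L) stop("LOOCV needs N >= 4")
  assigned <- character(n)
  for (i in seq_len(n)) {
    ytr <- y[-i]
    if (nlevels(droplevels(ytr)) < 2L) {
      stop("fold ", i, " leaves an empty class")
    }
    Xtr <- X[-i, , drop = FALSE]
    xte <- X[i, , drop = FALSE]
    if (scale_in_fold) {
      sc <- zscore(Xtr)
      Xtr <- sc
      xte <- zscore(xte, center = attr(sc, "center"),
                    scale = attr(sc, "scale"))
    }
    feats <- features
    if (reselect) {
      tr <- stepwise(Xtr, ytr, p_enter = p_enter, p_remove = p_remove)
      feats <- tr$selected
    }
    if (!length(feats)) {
      # no model: only the prior term remains; equal priors score 0 -> J
      pJ <- if (priors == "equal") 0.5 else mean(ytr == levels(y)[2])
      assigned[i] <- if (log(pJ / (1 - pJ)) >= 0) levels(y)[2] else levels(y)[1]
      next
    }
    fit <- fit_lda(Xtr[, feats, drop = FALSE], ytr,
                   covariance_mode = covariance_mode, priors = priors,
                   on_singular = on_singular)
    assigned[i] <- as.character(predict(fit, xte[, feats, drop = FALSE]))
  }
  cm <- tally_confusion(y, assigned, levels(y))
  attr(cm, "assigned") <- factor(assigned, levels = levels(y))
  cm
}

#' The five classification performance rates
#'
#' Accuracy (correct / total), sensitivity (correct positive / true
#' positive), specificity (correct negative / true negative), positive and
#' negative predictive values (correct positive (negative) / all assigned
#' positive (negative)), where "positive" is the confusion matrix's
#' positive class.  Rates with zero denominators are `NA` and flagged as
#' undefined rather than raising errors.
#'
#' @param cm a [confusion_matrix()].
#' @return object of class `performance_metrics`: full-precision rates,
#'   `rounded` (half-up 2 decimals, as printed in report tables) and
#'   `undefined` (names of rates with empty denominators).
#' @export
#' @examples
#' cm <- confusion_matrix(rbind(c(19, 2), c(2, 7)), c("male", "female"))
#' evaluate_metrics(cm)$rounded
evaluate_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  pos <- cm$positive
  neg <- setdiff(cm$groups, pos)
  k <- cm$counts
  tp <- k[pos, pos]; fn <- k[pos, neg]
  tn <- k[neg, neg]; fp <- k[neg, pos]
  rate <- function(num, den) if (den > 0) num / den else NA_real_
  m <- list(accuracy = rate(tp + tn, tp + tn + fp + fn),
            sensitivity = rate(tp, tp + fn),
            specificity = rate(tn, tn + fp),
            ppv = rate(tp, tp + fp),
            npv = rate(tn, tn + fn))
  structure(c(m, list(rounded = vapply(m, round_half_up, 0, digits = 2),
                      undefined = names(m)[vapply(m, is.na, TRUE)],
                      positive = pos)),
            class = "performance_metrics")
}

#' @export
print.performance_metrics <- function(x, ...) {
  cat(sprintf("accuracy %s | sensitivity %s | specificity %s | PPV %s | NPV %s (positive: %s)\n",
              fmt2(x$accuracy), fmt2(x$sensitivity), fmt2(x$specificity),
              fmt2(x$ppv), fmt2(x$npv), x$positive))
  invisible(x)
}
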