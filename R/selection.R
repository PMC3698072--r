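# Marker selection: partial-F stepwise selection (enter p < 0.05, remove
# p > 0.10) via the classical stepwise-regression equivalence on a +-1
# group indicator, and the random-subset ("all-possible-subsets") ensemble
# ranking with diagonal-covariance discriminant models.

rss_fit <- function(Xm, yv) {
  q <- qr(Xm)
  if (q$rank < ncol(Xm)) return(NULL)  # rank-deficient design
  sum(qr.resid(q, yv)^2)
}

#' Partial F statistic for one candidate feature
#'
#' The marginal contribution of `candidate` given the currently `selected`
#' features, from the reduction in residual sum of squares when the
#' candidate joins an OLS regression of a +-1 group indicator on the
#' selected set:
#' `F = (RSS_reduced - RSS_full) / (RSS_full / (n - k - 2))` with
#' `k = |selected|`, referred to F(1, n - k - 2).  With an empty selected
#' set this equals the squared pooled two-sample t statistic of the
#' candidate.
#'
#' @param X numeric matrix, subjects x features (named columns).
#' @param y two-level factor / 0-1 labels.
#' @param selected character vector of features already in the model.
#' @param candidate feature to evaluate (not in `selected`).
#' @return list with `statistic` (F), `df`, `p_value`; a rank-deficient
#'   full design reports `F = 0, p = 1` (candidate ineligible).
#' @export
partial_f <- function(X, y, selected, candidate) {
  X <- as.matrix(X)
  y <- as_two_groups(y)
  if (candidate %in% selected) stop("candidate already selected")
  n <- nrow(X)
  k <- length(selected)
  if (n <= k + 2L) stop("need n > |selected| + 2")
  yv <- ifelse(y == levels(y)[2], 1, -1)
  Xr <- cbind(1, X[, selected, drop = FALSE])
  Xf <- cbind(Xr, X[, candidate, drop = FALSE])
  rss_r <- rss_fit(Xr, yv)
  rss_f <- rss_fit(Xf, yv)
  if (is.null(rss_r) || is.null(rss_f)) {
    return(list(statistic = 0, df = c(1L, n - k - 2L), p_value = 1))
  }
  df2 <- n - k - 2L
  if (rss_f <= 0) {
    return(list(statistic = Inf, df = c(1L, df2), p_value = 0))
  }
  f <- (rss_r - rss_f) / (rss_f / df2)
  f <- max(f, 0)  # guard tiny negative from roundoff
  list(statistic = f, df = c(1L, df2),
       p_value = stats::pf(f, 1, df2, lower.tail = FALSE))
}

#' Stepwise variable selection by partial F
#'
#' Iterates entry/removal: the candidate with the smallest partial-F
#' p-value among those with `p < p_enter` is entered (ties broken by larger
#' F, then feature order); after each entry, any included feature whose
#' revised partial-F p-value exceeds `p_remove` is removed, largest p
#' first.  Stops when neither applies (or `max_steps`).  An empty final set
#' is a valid "no model" outcome.
#'
#' @param X numeric matrix with named columns.
#' @param y two-level factor / 0-1 labels.
#' @param p_enter entry threshold (study value 0.05).
#' @param p_remove removal threshold (study value 0.10); must satisfy
#'   `p_enter <= p_remove` to prevent cycling.
#' @param max_steps iteration guard (default 100).
#' @return object of class `selection_trace`: `selected` (final feature
#'   set, possibly empty), `events` (data frame: step, action, feature, F,
#'   p), `no_model` flag.
#' @export
stepwise <- function(X, y, p_enter = 0.05, p_remove = 0.10,
                     max_steps = 100L) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  y <- as_two_groups(y)
  if (!(p_enter > 0 && p_enter <= p_remove && p_remove < 1)) {
    stop("need 0 < p_enter <= p_remove < 1")
  }
  feats <- colnames(X)
  selected <- character(0)
  events <- list()
  step <- 0L
  n <- nrow(X)
  repeat {
    step <- step + 1L
    if (step > max_steps) break
    # entry scan
    cands <- setdiff(feats, selected)
    if (!length(cands) || n <= length(selected) + 2L) break
    scan <- lapply(cands, function(f) partial_f(X, y, selected, f))
    ps <- vapply(scan, `[[`, 0, "p_value")
    fs <- vapply(scan, `[[`, 0, "statistic")
    elig <- which(ps < p_enter)
    if (!length(elig)) break
    # smallest p, ties by larger F, then candidate order
    best <- elig[order(ps[elig], -fs[elig], elig)][1]
    selected <- c(selected, cands[best])
    events[[length(events) + 1L]] <-
      data.frame(step = step, action = "enter", feature = cands[best],
                 statistic = fs[best], p_value = ps[best],
                 stringsAsFactors = FALSE)
    # removal scan: revised partial F of each included feature given the rest
    repeat {
      if (length(selected) < 2L) break
      rp <- vapply(selected, function(f) {
        partial_f(X, y, setdiff(selected, f), f)$p_value
      }, 0)
      worst <- which(rp > p_remove)
      if (!length(worst)) break
      drop_i <- worst[order(-rp[worst], worst)][1]
      fdrop <- selected[drop_i]
      events[[length(events) + 1L]] <-
        data.frame(step = step, action = "remove", feature = fdrop,
                   statistic = partial_f(X, y, setdiff(selected, fdrop),
                                         fdrop)$statistic,
                   p_value = rp[drop_i], stringsAsFactors = FALSE)
      selected <- setdiff(selected, fdrop)
    }
  }
  ev <- if (length(events)) do.call(rbind, events) else
    data.frame(step = integer(0), action = character(0),
               feature = character(0), statistic = numeric(0),
               p_value = numeric(0))
  structure(list(selected = selected, events = ev,
                 no_model = length(selected) == 0L,
                 p_enter = p_enter, p_remove = p_remove),
            class = "selection_trace")
}

#' @export
print.selection_trace <- function(x, ...) {
  if (x$no_model) {
    cat("<selection_trace> no model (no feature met the entry criterion)\n")
  } else {
    cat("<selection_trace> selected:", paste(x$selected, collapse = ", "), "\n")
  }
  if (nrow(x$events)) print(x$events, row.names = FALSE)
  invisible(x)
}

# Fast LOOCV accuracy for a diagonal-covariance discriminant with equal
# priors, via leave-one-out updates of per-class sums/sums-of-squares.
# Exactly matches loocv(covariance_mode = "diagonal", priors = "equal")
# (agreement is tested); used inside the ensemble loop where hundreds of
# thousands of folds are evaluated.
loocv_diag_accuracy <- function(X, y01) {
  X <- as.matrix(X)
  n <- nrow(X)
  idxJ <- y01 == 1L
  nI <- sum(!idxJ); nJ <- sum(idxJ)
  SI <- colSums(X[!idxJ, , drop = FALSE]); QI <- colSums(X[!idxJ, , drop = FALSE]^2)
  SJ <- colSums(X[idxJ, , drop = FALSE]);  QJ <- colSums(X[idxJ, , drop = FALSE]^2)
  correct <- 0L
  for (i in seq_len(n)) {
    x <- X[i, ]
    if (idxJ[i]) {
      nJ2 <- nJ - 1L; nI2 <- nI
      mJ <- (SJ - x) / nJ2; mI <- SI / nI
      ssJ <- QJ - x^2 - nJ2 * mJ^2
      ssI <- QI - nI2 * mI^2
    } else {
      nI2 <- nI - 1L; nJ2 <- nJ
      mI <- (SI - x) / nI2; mJ <- SJ / nJ
      ssI <- QI - x^2 - nI2 * mI^2
      ssJ <- QJ - nJ2 * mJ^2
    }
    v <- (pmax(ssI, 0) + pmax(ssJ, 0)) / (nI2 + nJ2 - 2L)
    v <- pmax(v, 1e-12)
    B <- (mJ - mI) / v
    s <- sum(B * (x - (mI + mJ) / 2))
    assignedJ <- s >= 0
    if (assignedJ == idxJ[i]) correct <- correct + 1L
  }
  correct / n
}

#' Random-subset ensemble feature ranking
#'
#' The relaxation of the stepwise minimal-redundancy constraint: random
#' subsets of `subset_size` features are drawn from the candidate set
#' (duplicate subsets across iterations are allowed), each evaluated as a
#' diagonal-covariance discriminant model by leave-one-out
#' cross-validation, and features are ranked by the frequency with which
#' they appear in models whose LOOCV accuracy reaches
#' `accuracy_threshold` (study settings: 5 of 48 features, 500 iterations,
#' threshold 0.80).
#'
#' @param X numeric matrix with named columns (preprocessed).
#' @param y two-level factor / 0-1 labels.
#' @param n_iterations number of random subsets (study value 500).
#' @param subset_size features per subset (study value 5).
#' @param accuracy_threshold LOOCV accuracy cutoff for a "passing" model
#'   (study value 0.80).
#' @param seed integer seed for the subset draws (required unless
#'   `exhaustive`).
#' @param exhaustive evaluate every subset of size `subset_size` instead of
#'   sampling (allowed for <= 20 features; test oracle mode).
#' @param denominator `"passing"` (frequencies over passing models, the
#'   reported convention) or `"all"` (diagnostic).
#' @return object of class `ensemble_ranking`: `ranking` (data frame:
#'   feature, count, frequency, sorted by count, ties by feature order),
#'   `n_passing`, `n_models`, plus the configuration.  Zero passing models
#'   yields all-zero frequencies with a warning.
#' @export
ensemble_rank <- function(X, y, n_iterations = 500L, subset_size = 5L,
                          accuracy_threshold = 0.80, seed = NULL,
                          exhaustive = FALSE,
                          denominator = c("passing", "all")) {
  denominator <- match.arg(denominator)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  y <- as_two_groups(y)
  y01 <- as.integer(y) - 1L
  p <- ncol(X)
  if (subset_size > p) stop("subset_size exceeds the number of features")
  if (accuracy_threshold <= 0) stop("accuracy_threshold must be positive")
  if (exhaustive) {
    if (p > 20L) stop("exhaustive mode is limited to <= 20 features")
    subsets <- utils::combn(p, subset_size, simplify = FALSE)
  } else {
    if (n_iterations > 0L && is.null(seed)) {
      stop("a seed is required for random subset draws")
    }
    subsets <- list()
    if (n_iterations > 0L) {
      set.seed(seed)
      subsets <- replicate(n_iterations,
                           sample.int(p, subset_size), simplify = FALSE)
    }
  }
  counts <- integer(p)
  n_passing <- 0L
  for (sub in subsets) {
    acc <- loocv_diag_accuracy(X[, sub, drop = FALSE], y01)
    if (acc >= accuracy_threshold) {
      n_passing <- n_passing + 1L
      counts[sub] <- counts[sub] + 1L
    }
  }
  if (length(subsets) && n_passing == 0L) {
    warning("no subset reached the accuracy threshold; all frequencies are 0")
  }
  den <- if (denominator == "passing") max(n_passing, 1L) else
    max(length(subsets), 1L)
  ord <- order(-counts, seq_len(p))
  ranking <- data.frame(feature = colnames(X)[ord],
                        count = counts[ord],
                        frequency = counts[ord] / den,
                        stringsAsFactors = FALSE)
  structure(list(ranking = ranking, n_passing = n_passing,
                 n_models = length(subsets),
                 subset_size = subset_size,
                 accuracy_threshold = accuracy_threshold,
                 seed = if (exhaustive) NA_integer_ else seed,
                 exhaustive = exhaustive, denominator = denominator),
            class = "ensemble_ranking")
}

#' @export
print.ensemble_ranking <- function(x, ...) {
  cat(sprintf("<ensemble_ranking> %d/%d models passed accuracy >= %.2f%s\n",
              x$n_passing, x$n_models, x$accuracy_threshold,
              if (x$exhaustive) " (exhaustive)" else ""))
  print(utils::head(x$ranking, 10), row.names = FALSE)
  invisible(x)
}

#' Fit the final model on the top-ranked features
#'
#' Diagonal-covariance discriminant on the `top_k` highest-ranked features
#' of an ensemble ranking, with its LOOCV confusion matrix and the five
#' performance rates.
#'
#' @param X,y as in [ensemble_rank()].
#' @param ranking an `ensemble_ranking` (or its `ranking` data frame).
#' @param top_k number of top features to keep (>= 1).
#' @param priors passed to [fit_lda()].
#' @return list with `model` (`cyto_lda`), `features`, `confusion`
#'   (`confusion_matrix`), `metrics` (`performance_metrics`).
#' @export
build_final_model <- function(X, y, ranking, top_k, priors = "equal") {
  if (inherits(ranking, "ensemble_ranking")) ranking <- ranking$ranking
  if (top_k < 1L) stop("top_k must be at least 1")
  if (top_k > nrow(ranking)) stop("top_k exceeds the number of ranked features")
  feats <- ranking$feature[seq_len(top_k)]
  X <- as.matrix(X)
  model <- fit_lda(X[, feats, drop = FALSE], y,
                   covariance_mode = "diagonal", priors = priors)
  cm <- loocv(X, y, features = feats, covariance_mode = "diagonal",
              priors = priors)
  list(model = model, features = feats, confusion = cm,
       metrics = evaluate_metrics(cm))
}
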