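# Univariate group comparisons: pooled two-sample t test on log2-scale
# concentrations, Wilcoxon rank-sum on the raw scale (confirmatory), and
# one-way ANOVA for cohort descriptors.

#' Two-sample t test on log2-transformed concentrations
#'
#' Student (pooled-variance) two-sample t test after log2 transformation,
#' two-tailed.  "Standard parametric t test" is read classically as the
#' equal-variance form; Welch is available by flag.
#'
#' @param a,b numeric vectors of positive concentrations.
#' @param var_equal pooled variance (default TRUE); FALSE gives Welch.
#' @return list with `statistic` (t), `df`, `p_value`.
#' @export
t_test_log2 <- function(a, b, var_equal = TRUE) {
  if (length(a) < 2L || length(b) < 2L) stop("each sample needs n >= 2")
  if (any(a <= 0) || any(b <= 0)) stop("concentrations must be positive before log2")
  la <- log2(a); lb <- log2(b)
  if (var_equal && stats::var(la) == 0 && stats::var(lb) == 0) {
    if (mean(la) == mean(lb)) {
      # identical constants: no evidence against the null
      return(list(statistic = 0, df = length(a) + length(b) - 2, p_value = 1))
    }
    stop("zero pooled variance: t statistic undefined")
  }
  tt <- stats::t.test(la, lb, var.equal = var_equal)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value)
}

#' Wilcoxon rank-sum test
#'
#' Two-tailed rank-sum test on untransformed values: exact null
#' distribution when the pooled sample has at most 20 observations and no
#' ties, otherwise the normal approximation with mid-rank tie correction
#' and continuity correction.
#'
#' @param a,b numeric vectors (n >= 1 each).
#' @param exact_max pooled-size cutoff for the exact distribution (20).
#' @return list with `statistic` (Mann-Whitney W for sample `a`), `p_value`,
#'   `exact` (logical, which path was used).
#' @export
wilcoxon_ranksum <- function(a, b, exact_max = 20L) {
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  ties <- anyDuplicated(c(a, b)) > 0
  use_exact <- !ties && (length(a) + length(b)) <= exact_max
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = use_exact, correct = TRUE)
  )
  list(statistic = unname(wt$statistic), p_value = min(1, wt$p.value),
       exact = use_exact)
}

#' One-way analysis of variance
#'
#' Classical between/within mean-square F with (g-1, N-g) degrees of
#' freedom, used for cohort descriptors (age, BMI, VO2 max) across groups.
#'
#' @param groups list of >= 2 numeric vectors, each n >= 2.
#' @return list with `statistic` (F), `df` (c(g-1, N-g)), `p_value`.
#' @export
#' @examples
#' one_way_anova(list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5)))
one_way_anova <- function(groups) {
  stopifnot(is.list(groups))
  if (length(groups) < 2L) stop("need at least two groups")
  if (any(lengths(groups) < 2L)) stop("each group needs n >= 2")
  x <- unlist(groups, use.names = FALSE)
  g <- length(groups)
  N <- length(x)
  grand <- mean(x)
  ssb <- sum(lengths(groups) * (vapply(groups, mean, 0) - grand)^2)
  ssw <- sum(vapply(groups, function(v) sum((v - mean(v))^2), 0))
  df1 <- g - 1L
  df2 <- N - g
  if (ssw == 0) {
    stop("zero within-group variance: F statistic undefined")
  }
  f <- (ssb / df1) / (ssw / df2)
  list(statistic = f, df = c(df1, df2),
       p_value = stats::pf(f, df1, df2, lower.tail = FALSE))
}

#' Per-feature comparison table for one stratum
#'
#' One row per (cytokine, time point): raw-scale group means and standard
#' errors, the pooled t test p-value on log2 data and the Wilcoxon rank-sum
#' p-value on raw data, computed on observed (non-missing) values.  No
#' multiplicity adjustment is applied in the replication workflow; an
#' optional Benjamini-Hochberg column is available for reuse.
#'
#' @param panel a `cytokine_panel`.
#' @param ... comparison definition passed to [select_cohort()]
#'   (`diagnoses`/`sexes` plus filters).
#' @param adjust add `p_t_bh` / `p_w_bh` Benjamini-Hochberg columns
#'   (default FALSE).
#' @param alpha significance flag threshold (0.05).
#' @return data frame with columns `feature`, `cytokine`, `time_point`,
#'   `mean_<A>`, `se_<A>`, `mean_<B>`, `se_<B>`, `p_t`, `p_w`,
#'   `significant` (either p <= alpha).
#' @export
compare_table <- function(panel, ..., adjust = FALSE, alpha = 0.05) {
  sel <- select_cohort(panel, ...)
  A <- sel$groups[1]; B <- sel$groups[2]
  se <- function(v) stats::sd(v) / sqrt(length(v))
  rows <- lapply(seq_len(ncol(sel$X)), function(j) {
    va <- sel$X[sel$y == A, j]; va <- va[!is.na(va)]
    vb <- sel$X[sel$y == B, j]; vb <- vb[!is.na(vb)]
    pt_ <- tryCatch(t_test_log2(va, vb)$p_value, error = function(e) NA_real_)
    pw_ <- tryCatch(wilcoxon_ranksum(va, vb)$p_value,
                    error = function(e) NA_real_)
    data.frame(feature = sel$features$feature[j],
               cytokine = sel$features$cytokine[j],
               time_point = sel$features$time_point[j],
               mean_a = mean(va), se_a = se(va),
               mean_b = mean(vb), se_b = se(vb),
               p_t = pt_, p_w = pw_, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out)[names(out) == "mean_a"] <- paste0("mean_", A)
  names(out)[names(out) == "se_a"] <- paste0("se_", A)
  names(out)[names(out) == "mean_b"] <- paste0("mean_", B)
  names(out)[names(out) == "se_b"] <- paste0("se_", B)
  if (adjust) {
    out$p_t_bh <- stats::p.adjust(out$p_t, method = "BH")
    out$p_w_bh <- stats::p.adjust(out$p_w, method = "BH")
  }
  out$significant <- !is.na(out$p_t) & out$p_t <= alpha |
    !is.na(out$p_w) & out$p_w <= alpha
  out
}
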