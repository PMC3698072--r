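# shared fixture builders

# small panel: n_male_hc + n_male_gwi male subjects, optional females,
# a couple of cytokines at all three time points, log-normal values
tiny_panel <- function(n_male_hc = 3, n_male_gwi = 2, n_female_hc = 0,
                       cytokines = c("IL-2", "IL-10"), seed = 42) {
  set.seed(seed)
  feats <- feature_keys(cytokines)
  n <- n_male_hc + n_male_gwi + n_female_hc
  vals <- matrix(2^rnorm(n * length(feats), mean = 3), n, length(feats),
                 dimnames = list(sprintf("S%02d", seq_len(n)), feats))
  cytokine_panel(vals,
                 sex = c(rep("male", n_male_hc + n_male_gwi),
                         rep("female", n_female_hc)),
                 diagnosis = c(rep("HC", n_male_hc),
                               rep("GWI", n_male_gwi),
                               rep("HC", n_female_hc)))
}

# two-class Gaussian design with planted mean shifts (in units of the
# within-class SD); returns X with named columns and a 0/1-style factor
planted_design <- function(n_per_class = 20, p = 10, informative = 1:2,
                           delta = 2.5, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, sprintf("F%02d", seq_len(p))))
  y <- factor(rep(c("A", "B"), each = n_per_class), levels = c("A", "B"))
  X[y == "B", informative] <- X[y == "B", informative] + delta
  list(X = X, y = y)
}

# exact two-tailed Wilcoxon rank-sum p-value by full enumeration of all
# choose(n, n_a) rank assignments (independent oracle)
wilcoxon_exact_enum <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  n_a <- length(a)
  w_obs <- sum(r[seq_len(n_a)])
  all_w <- apply(combn(length(pooled), n_a), 2, function(idx) sum(r[idx]))
  mu <- mean(all_w)
  p <- mean(abs(all_w - mu) >= abs(w_obs - mu) - 1e-9)
  min(1, p)
}

ref_performance <- function() {
  path <- system.file("extdata", "reference_model_performance.csv",
                      package = "cytosig")
  read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}
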