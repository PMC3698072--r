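test_that("partial F at the empty model equals the squared pooled t", {
  set.seed(10)
  for (i in 1:50) {
    x <- matrix(rnorm(24), ncol = 1, dimnames = list(NULL, "f"))
    y <- factor(rep(c("I", "J"), each = 12), levels = c("I", "J"))
    if (i %% 2 == 0) x[y == "J", ] <- x[y == "J", ] + 1
    pf_res <- partial_f(x, y, character(0), "f")
    tt <- t.test(x[y == "I", 1], x[y == "J", 1], var.equal = TRUE)
    expect_equal(pf_res$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(pf_res$p_value, tt$p.value, tolerance = 1e-10)
  }
})

test_that("partial F matches a brute-force two-model OLS oracle", {
  set.seed(11)
  X <- matrix(rnorm(90), ncol = 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- factor(rep(c("I", "J"), 15), levels = c("I", "J"))
  yv <- ifelse(y == "J", 1, -1)
  n <- nrow(X)
  for (cand in c("b", "c")) {
    sel <- "a"
    res <- partial_f(X, y, sel, cand)
    # explicit normal-equations solve for both nested models
    Xr <- cbind(1, X[, sel]); Xf <- cbind(Xr, X[, cand])
    rss <- function(M) {
      beta <- solve(t(M) %*% M, t(M) %*% yv)
      sum((yv - M %*% beta)^2)
    }
    f_oracle <- (rss(Xr) - rss(Xf)) / (rss(Xf) / (n - 1 - 2))
    expect_equal(res$statistic, f_oracle, tolerance = 1e-8)
    expect_equal(res$p_value, pf(f_oracle, 1, n - 3, lower.tail = FALSE),
                 tolerance = 1e-10)
  }
})

test_that("a candidate orthogonal to the residuals is ineligible", {
  set.seed(12)
  x <- rnorm(30)
  y <- factor(rep(c("I", "J"), 15), levels = c("I", "J"))
  yv <- ifelse(y == "J", 1, -1)
  # candidate built orthogonal to the current model's residuals
  Xr <- cbind(1, x)
  resid <- yv - Xr %*% solve(t(Xr) %*% Xr, t(Xr) %*% yv)
  cand <- rnorm(30)
  cand <- cand - Xr %*% solve(t(Xr) %*% Xr, t(Xr) %*% cand) -
    drop(crossprod(resid, cand) / crossprod(resid)) * resid
  X <- cbind(a = x, q = drop(cand))
  res <- partial_f(X, y, "a", "q")
  expect_equal(res$statistic, 0, tolerance = 1e-8)
  expect_equal(res$p_value, 1, tolerance = 1e-8)
  # a duplicated (rank-deficient) candidate reports F = 0, p = 1
  Xd <- cbind(a = x, dup = x)
  res_d <- partial_f(Xd, y, "a", "dup")
  expect_identical(c(res_d$statistic, res_d$p_value), c(0, 1))
})

test_that("stepwise returns 'no model' on constant or null features", {
  X <- matrix(1, 12, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- factor(rep(c("I", "J"), 6), levels = c("I", "J"))
  tr <- stepwise(X, y)
  expect_true(tr$no_model)
  expect_identical(nrow(tr$events), 0L)
  # label-independent noise features: no-model outcomes occur across seeds
  outcomes <- vapply(1:20, function(s) {
    set.seed(700 + s)
    Xn <- matrix(rnorm(12 * 4), 12, 4,
                 dimnames = list(NULL, paste0("f", 1:4)))
    stepwise(Xn, y)$no_model
  }, TRUE)
  expect_gte(mean(outcomes), 0.5)
})

test_that("stepwise enters the planted feature first and skips its copy", {
  # B carries the same signal as A plus unit noise (corr(A, B) ~ 0.8,
  # the co-expression regime the minimal-redundancy constraint targets)
  n_runs <- 100
  first_is_A <- entered_B <- logical(n_runs)
  for (s in seq_len(n_runs)) {
    set.seed(1500 + s)
    n <- 40
    y <- factor(rep(c("I", "J"), each = 20), levels = c("I", "J"))
    A <- rnorm(n) + ifelse(y == "J", 3, 0)  # 3 SD separation
    B <- A + rnorm(n, sd = 1)               # redundant co-expressed copy
    C <- rnorm(n)                           # pure noise
    X <- cbind(A = A, B = B, C = C)
    tr <- stepwise(X, y)
    first_is_A[s] <- nrow(tr$events) > 0 && tr$events$feature[1] == "A"
    entered_B[s] <- "B" %in% tr$selected
  }
  expect_gte(mean(first_is_A & !entered_B), 0.95)
})

test_that("stepwise honors thresholds, removal and the cycling guard", {
  expect_error(stepwise(matrix(rnorm(20), ncol = 2,
                               dimnames = list(NULL, c("a", "b"))),
                        rep(c("I", "J"), 5), p_enter = 0.2, p_remove = 0.1),
               "p_enter <= p_remove")
  # adversarial correlated design terminates within the step guard
  set.seed(77)
  n <- 30
  y <- factor(rep(c("I", "J"), each = 15), levels = c("I", "J"))
  base <- rnorm(n) + ifelse(y == "J", 1.5, 0)
  X <- sapply(1:6, function(k) base + rnorm(n, sd = 0.4))
  colnames(X) <- paste0("g", 1:6)
  tr <- stepwise(X, y, max_steps = 25)
  expect_lte(max(tr$events$step, 0), 25)
  # replaying the event log from the empty set yields the final set
  replay <- character(0)
  for (r in seq_len(nrow(tr$events))) {
    ev <- tr$events[r, ]
    replay <- if (ev$action == "enter") c(replay, ev$feature) else
      setdiff(replay, ev$feature)
  }
  expect_identical(replay, tr$selected)
})

test_that("ensemble_rank handles degenerate configurations", {
  d <- planted_design(n_per_class = 10, p = 6, seed = 20)
  r0 <- ensemble_rank(d$X, d$y, n_iterations = 0)
  expect_identical(r0$n_models, 0L)
  expect_true(all(r0$ranking$count == 0))
  expect_warning(
    r1 <- ensemble_rank(d$X, d$y, n_iterations = 20, subset_size = 3,
                        accuracy_threshold = 1.01, seed = 1),
    "no subset")
  expect_identical(r1$n_passing, 0L)
  expect_true(all(r1$ranking$frequency == 0))
  expect_error(ensemble_rank(d$X, d$y, subset_size = 7), "exceeds")
})

test_that("ensemble_rank is seed-reproducible and seed-stable", {
  d <- planted_design(n_per_class = 20, p = 10, informative = 1:2,
                      delta = 2.5, seed = 21)
  ra <- ensemble_rank(d$X, d$y, n_iterations = 500, seed = 5)
  rb <- ensemble_rank(d$X, d$y, n_iterations = 500, seed = 5)
  expect_identical(ra$ranking, rb$ranking)
  rc <- ensemble_rank(d$X, d$y, n_iterations = 500, seed = 6)
  counts_a <- ra$ranking$count[order(ra$ranking$feature)]
  counts_c <- rc$ranking$count[order(rc$ranking$feature)]
  # Pearson on counts: rank-based correlation is uninformative here
  # because the null features' counts are exchangeable (their relative
  # ranks are pure Monte-Carlo noise); the planted/null count separation
  # is what must be stable across seeds
  expect_gt(cor(counts_a, counts_c), 0.9)
  # and the planted features stay on top under both seeds
  expect_setequal(ra$ranking$feature[1:2], c("F01", "F02"))
  expect_setequal(rc$ranking$feature[1:2], c("F01", "F02"))
})

test_that("exhaustive ensemble mode enumerates every subset once", {
  d <- planted_design(n_per_class = 12, p = 7, informative = 1:2,
                      delta = 2.5, seed = 22)
  re <- ensemble_rank(d$X, d$y, subset_size = 3, exhaustive = TRUE)
  expect_identical(re$n_models, 35L)  # choose(7, 3)
  # oracle: direct enumeration with the generic LOOCV path
  subs <- combn(7, 3, simplify = FALSE)
  counts <- integer(7)
  passing <- 0L
  for (sub in subs) {
    cm <- loocv(d$X[, sub, drop = FALSE], d$y, covariance_mode = "diagonal")
    acc <- sum(diag(cm$counts)) / sum(cm$counts)
    if (acc >= 0.80) {
      passing <- passing + 1L
      counts[sub] <- counts[sub] + 1L
    }
  }
  expect_identical(re$n_passing, passing)
  expect_identical(re$ranking$count[order(match(re$ranking$feature,
                                                colnames(d$X)))], counts)
})

test_that("fast diagonal LOOCV agrees with the generic fold-by-fold path", {
  for (s in 1:5) {
    d <- planted_design(n_per_class = 10, p = 4, delta = 1.5, seed = 30 + s)
    cm <- loocv(d$X, d$y, covariance_mode = "diagonal")
    acc_generic <- sum(diag(cm$counts)) / sum(cm$counts)
    acc_fast <- cytosig:::loocv_diag_accuracy(d$X, as.integer(d$y) - 1L)
    expect_equal(acc_fast, acc_generic)
  }
})

test_that("label-permuted data rarely produce passing models", {
  d <- planted_design(n_per_class = 15, p = 10, informative = integer(0),
                      seed = 40)
  frac_passing <- vapply(1:25, function(s) {
    set.seed(2000 + s)
    yp <- sample(d$y)
    r <- suppressWarnings(
      ensemble_rank(d$X, yp, n_iterations = 40, subset_size = 5,
                    seed = 3000 + s))
    r$n_passing / r$n_models
  }, 0)
  expect_lt(mean(frac_passing), 0.05)
})

test_that("build_final_model refits the top-ranked features", {
  d <- planted_design(n_per_class = 20, p = 10, informative = 1:2,
                      delta = 2.5, seed = 23)
  rk <- ensemble_rank(d$X, d$y, n_iterations = 300, seed = 9)
  fin <- build_final_model(d$X, d$y, rk, top_k = 2)
  expect_s3_class(fin$model, "cyto_lda")
  expect_identical(fin$model$covariance_mode, "diagonal")
  expect_identical(sort(fin$features),
                   sort(rk$ranking$feature[1:2]))
  expect_error(build_final_model(d$X, d$y, rk, top_k = 0), "at least 1")
  expect_error(build_final_model(d$X, d$y, rk, top_k = 99), "exceeds")
  # top_k = all features reproduces the direct diagonal fit
  fin_all <- build_final_model(d$X, d$y, rk, top_k = 10)
  direct <- fit_lda(d$X[, fin_all$features], d$y, covariance_mode = "diagonal")
  expect_equal(sort(fin_all$model$B), sort(direct$B), tolerance = 1e-12)
  # planted model beats the median of random 2-feature models
  accs <- vapply(1:40, function(s) {
    set.seed(4000 + s)
    sub <- sample(10, 2)
    cm <- loocv(d$X[, sub, drop = FALSE], d$y, covariance_mode = "diagonal")
    sum(diag(cm$counts)) / sum(cm$counts)
  }, 0)
  acc_fin <- sum(diag(fin$confusion$counts)) / sum(fin$confusion$counts)
  expect_gt(acc_fin, median(accs))
})
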