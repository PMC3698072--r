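test_that("the decision boundary sits midway between symmetric class means", {
  set.seed(1)
  x <- matrix(c(rnorm(20, -1, 0.5), rnorm(20, 1, 0.5)), ncol = 1,
              dimnames = list(NULL, "f"))
  y <- factor(rep(c("I", "J"), each = 20), levels = c("I", "J"))
  # force exact symmetry so the boundary is exactly 0
  x[1:20] <- -(x[21:40])
  fit <- fit_lda(x, y)
  expect_equal(fit$B0, 0, tolerance = 1e-10)
  expect_identical(as.character(predict(fit, 0.5)), "J")
  expect_identical(as.character(predict(fit, -0.5)), "I")
})

test_that("a score of exactly zero assigns to group J (strict rule)", {
  set.seed(2)
  x <- matrix(rnorm(20), ncol = 1, dimnames = list(NULL, "f"))
  y <- factor(rep(c("I", "J"), 10), levels = c("I", "J"))
  fit <- fit_lda(x, y)
  # construct the observation whose score is exactly B0 + x*B = 0
  x0 <- -fit$B0 / fit$B
  pred <- predict(fit, x0)
  expect_equal(attr(pred, "score"), 0, tolerance = 1e-12)
  expect_identical(as.character(pred), "J")
})

test_that("pooled-covariance assignments match the closed-form Bayes rule", {
  set.seed(33)
  n <- 60
  X <- matrix(rnorm(2 * n), ncol = 2, dimnames = list(NULL, c("a", "b")))
  y <- factor(rep(c("I", "J"), each = n / 2), levels = c("I", "J"))
  X[y == "J", ] <- X[y == "J", ] + c(1.2, -0.8)
  fit <- fit_lda(X, y)
  Xtest <- matrix(rnorm(400), ncol = 2)
  pred <- predict(fit, Xtest)
  # independent oracle: plug-in Gaussian Bayes rule with pooled covariance
  muI <- colMeans(X[y == "I", ]); muJ <- colMeans(X[y == "J", ])
  S <- ((crossprod(sweep(X[y == "I", ], 2, muI))) +
          (crossprod(sweep(X[y == "J", ], 2, muJ)))) / (n - 2)
  Sinv <- solve(S)
  dI <- apply(Xtest, 1, function(v) -0.5 * t(v - muI) %*% Sinv %*% (v - muI))
  dJ <- apply(Xtest, 1, function(v) -0.5 * t(v - muJ) %*% Sinv %*% (v - muJ))
  oracle <- ifelse(dJ >= dI, "J", "I")
  expect_identical(as.character(pred), oracle)
})

test_that("assignments agree with MASS::lda on seeded Gaussian data", {
  set.seed(44)
  X <- matrix(rnorm(160), ncol = 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- factor(rep(c("I", "J"), each = 20), levels = c("I", "J"))
  X[y == "J", 1:2] <- X[y == "J", 1:2] + 1.5
  fit <- fit_lda(X, y)
  ours <- as.character(predict(fit, X))
  mass <- as.character(stats::predict(MASS::lda(X, y, prior = c(0.5, 0.5)),
                                      X)$class)
  expect_identical(ours, mass)
})

test_that("standardized coefficients are canonical: single feature is +-1", {
  set.seed(3)
  x <- matrix(2 + rnorm(30), ncol = 1, dimnames = list(NULL, "f"))
  y <- factor(rep(c("I", "J"), 15), levels = c("I", "J"))
  x[y == "J", ] <- x[y == "J", ] + 2
  fit <- fit_lda(x, y)
  expect_equal(abs(fit$standardized), 1, tolerance = 1e-12)
  expect_equal(sign(fit$standardized), 1)  # J has the larger mean
  fit_dn <- fit_lda(-x, y)
  expect_equal(fit_dn$standardized, -1, tolerance = 1e-12)
})

test_that("standardized coefficients are invariant to feature rescaling", {
  set.seed(4)
  X <- matrix(rnorm(120), ncol = 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- factor(rep(c("I", "J"), each = 20), levels = c("I", "J"))
  X[y == "J", ] <- X[y == "J", ] + c(1, -0.5, 0.3)
  fit1 <- fit_lda(X, y)
  X2 <- X
  X2[, "b"] <- X2[, "b"] * 2  # doubled scale
  fit2 <- fit_lda(X2, y)
  expect_equal(fit2$B[2], fit1$B[2] / 2, tolerance = 1e-10)
  expect_equal(fit2$standardized, fit1$standardized, tolerance = 1e-10)
  # assignments unchanged under affine rescaling (pooled mode)
  expect_identical(as.character(predict(fit2, X2)),
                   as.character(predict(fit1, X)))
})

test_that("two mirror-image features get equal standardized magnitudes", {
  set.seed(5)
  base <- rnorm(40)
  y <- factor(rep(c("I", "J"), each = 20), levels = c("I", "J"))
  shift <- ifelse(y == "J", 1, 0)
  X <- cbind(a = base + shift + rnorm(40, sd = 0.3),
             b = -(base + shift + rnorm(40, sd = 0.3)))
  fit <- fit_lda(X, y)
  expect_equal(abs(fit$standardized[1]), abs(fit$standardized[2]),
               tolerance = 0.3)
})

test_that("diagonal mode matches pooled mode when the truth is diagonal", {
  set.seed(6)
  n <- 500
  X <- matrix(rnorm(3 * n), ncol = 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- factor(rep(c("I", "J"), each = n / 2), levels = c("I", "J"))
  X[y == "J", ] <- X[y == "J", ] + c(1, 0.5, -0.7)
  pf <- predict(fit_lda(X, y, covariance_mode = "pooled_full"), X)
  pd <- predict(fit_lda(X, y, covariance_mode = "diagonal"), X)
  expect_gte(mean(as.character(pf) == as.character(pd)), 0.99)
})

test_that("singular pooled covariance errors or falls back to ridge", {
  set.seed(7)
  x <- rnorm(20)
  X <- cbind(a = x, b = 2 * x)  # exactly collinear
  y <- factor(rep(c("I", "J"), 10), levels = c("I", "J"))
  expect_error(fit_lda(X, y, on_singular = "error"), "diagonal")
  expect_message(fit <- fit_lda(X, y, on_singular = "ridge"), "ridge")
  expect_true(all(is.finite(fit$B)))
  # diagonal mode rejects zero-variance features by name
  Xz <- cbind(a = x, z = rep(1, 20))
  expect_error(fit_lda(Xz, y, covariance_mode = "diagonal"), "z")
})

test_that("proportional priors shift the intercept by the log prior ratio", {
  set.seed(8)
  x <- matrix(rnorm(30), ncol = 1, dimnames = list(NULL, "f"))
  y <- factor(c(rep("I", 20), rep("J", 10)), levels = c("I", "J"))
  x[y == "J", ] <- x[y == "J", ] + 1
  f_eq <- fit_lda(x, y, priors = "equal")
  f_pr <- fit_lda(x, y, priors = "proportional")
  expect_equal(f_pr$B0 - f_eq$B0, log((10 / 30) / (20 / 30)),
               tolerance = 1e-10)
})

test_that("LOOCV separates well-separated classes and matches hand folds", {
  set.seed(9)
  x <- matrix(c(rnorm(5, -4), rnorm(5, 4)), ncol = 1,
              dimnames = list(NULL, "f"))
  y <- factor(rep(c("I", "J"), each = 5), levels = c("I", "J"))
  cm <- loocv(x, y)
  expect_equal(unname(diag(cm$counts)), c(5, 5))
  # N = 4 toy set: enumerate all folds with the closed-form 1-D rule
  x4 <- matrix(c(0, 1, 10, 11), ncol = 1, dimnames = list(NULL, "f"))
  y4 <- factor(c("I", "I", "J", "J"), levels = c("I", "J"))
  hand <- character(4)
  for (i in 1:4) {
    xi <- x4[-i, 1]; yi <- y4[-i]
    mI <- mean(xi[yi == "I"]); mJ <- mean(xi[yi == "J"])
    vI <- if (sum(yi == "I") > 1) var(xi[yi == "I"]) * (sum(yi == "I") - 1) else 0
    vJ <- if (sum(yi == "J") > 1) var(xi[yi == "J"]) * (sum(yi == "J") - 1) else 0
    s2 <- (vI + vJ) / (length(xi) - 2)
    score <- (mJ - mI) / s2 * (x4[i, 1] - (mI + mJ) / 2)
    hand[i] <- if (score >= 0) "J" else "I"
  }
  cm4 <- loocv(x4, y4)
  expect_identical(as.character(attr(cm4, "assigned")), hand)
})

test_that("LOOCV accuracy on well-separated synthetic classes is >= 0.95", {
  accs <- vapply(1:50, function(s) {
    d <- planted_design(n_per_class = 20, p = 3, informative = 1,
                        delta = 4, seed = 600 + s)
    cm <- loocv(d$X, d$y)
    sum(diag(cm$counts)) / sum(cm$counts)
  }, 0)
  expect_gte(mean(accs), 0.95)
})

test_that("the five rates reproduce hand-computed values and edge cases", {
  m1 <- evaluate_metrics(confusion_matrix(rbind(c(19, 2), c(2, 7)),
                                          c("male", "female")))
  expect_equal(unname(m1$rounded),
               c(0.87, 0.78, 0.90, 0.78, 0.90))  # acc, sens, spec, ppv, npv
  m2 <- evaluate_metrics(confusion_matrix(rbind(c(17, 4), c(3, 17)),
                                          c("HC", "GWI")))
  expect_equal(unname(m2$rounded), c(0.83, 0.85, 0.81, 0.81, 0.85))
  mp <- evaluate_metrics(confusion_matrix(rbind(c(10, 0), c(0, 10)),
                                          c("I", "J")))
  expect_equal(unname(unlist(mp[c("accuracy", "sensitivity", "specificity",
                                  "ppv", "npv")])), rep(1, 5))
  # zero denominator: nothing assigned positive -> PPV undefined, flagged
  m0 <- evaluate_metrics(confusion_matrix(rbind(c(10, 0), c(5, 0)),
                                          c("I", "J")))
  expect_true(is.na(m0$ppv))
  expect_identical(m0$undefined, "ppv")
})

test_that("swapping class labels swaps sens/spec and PPV/NPV", {
  k <- rbind(c(14, 7), c(4, 16))
  m <- evaluate_metrics(confusion_matrix(k, c("HC", "GWI")))
  # flipped matrix: rows/cols reordered, positive class now the old negative
  m_swap <- evaluate_metrics(confusion_matrix(k[2:1, 2:1], c("GWI", "HC")))
  expect_equal(m_swap$accuracy, m$accuracy)
  expect_equal(m_swap$sensitivity, m$specificity)
  expect_equal(m_swap$specificity, m$sensitivity)
  expect_equal(m_swap$ppv, m$npv)
  expect_equal(m_swap$npv, m$ppv)
})

test_that("leakage-free in-fold standardization matches one-shot closely", {
  for (s in 1:3) {
    g <- generate_cohort(study_template(seed = s))
    sel <- select_cohort(g$panel, sexes = c("male", "female"),
                         diagnosis = "HC")
    Xl <- log2_transform(impute_missing(sel$X, sel$mask))
    Xp <- zscore(Xl)
    feats <- colnames(Xp)[1:5]
    one_shot <- loocv(Xp, sel$y, features = feats)
    in_fold <- loocv(Xl, sel$y, features = feats, scale_in_fold = TRUE)
    agree <- mean(as.character(attr(one_shot, "assigned")) ==
                    as.character(attr(in_fold, "assigned")))
    expect_gte(agree, 0.9)
  }
})

test_that("per-fold reselection runs and is more conservative than refit", {
  d <- planted_design(n_per_class = 12, p = 5, informative = 1,
                      delta = 2.5, seed = 71)
  cm <- loocv(d$X, d$y, reselect = TRUE)
  expect_s3_class(cm, "confusion_matrix")
  expect_identical(sum(cm$counts), 24L)
  # with a strong planted marker the reselected folds still classify well
  expect_gte(sum(diag(cm$counts)) / sum(cm$counts), 0.75)
})
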