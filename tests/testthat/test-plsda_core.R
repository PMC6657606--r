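test_that("PLS1 with one component on a single predictor is least squares", {
  set.seed(20)
  x <- matrix(rnorm(25), ncol = 1)
  y <- 2 + 3 * x[, 1] + rnorm(25, sd = 0.2)
  fit <- pls_fit(x, y, A = 1)
  ols <- lm(y ~ x[, 1])
  expect_equal(pls_predict(fit, x), unname(fitted(ols)), tolerance = 1e-10)
})

test_that("full-rank PLS equals the normal-equations oracle and mixOmics", {
  set.seed(22)
  X <- matrix(rnorm(30 * 5), 30, 5)
  colnames(X) <- paste0("v", 1:5)
  y <- X %*% c(1, -2, 0.5, 0, 1) + rnorm(30, sd = 0.3)
  fit <- pls_fit(X, y, A = 5)
  # oracle: explicit normal equations on the centered problem
  Xc <- scale(X, scale = FALSE)
  b <- solve(crossprod(Xc), crossprod(Xc, y - mean(y)))
  oracle <- mean(y) + Xc %*% b
  expect_equal(pls_predict(fit, X), oracle[, 1], tolerance = 1e-8)
  # independent cross-check: mixOmics NIPALS at intermediate complexity
  mo <- suppressMessages(mixOmics::pls(X, as.numeric(y), ncomp = 3,
                                       scale = FALSE, mode = "regression"))
  mo_pred <- predict(mo, X)$predict[, 1, 3]
  expect_equal(pls_predict(fit, X, A = 3), unname(mo_pred), tolerance = 1e-6)
})

test_that("score vectors are orthogonal and the fit is deterministic", {
  set.seed(23)
  X <- matrix(rnorm(40 * 6), 40, 6)
  y <- rnorm(40)
  fit <- pls_fit(X, y, A = 4)
  G <- crossprod(fit$T)
  expect_lt(max(abs(G[upper.tri(G)])), 1e-8)
  expect_identical(fit$coef, pls_fit(X, y, A = 4)$coef)
})

test_that("degenerate responses and excess components are handled", {
  set.seed(24)
  X <- matrix(rnorm(30), 10, 3)
  # response orthogonal to every centered column -> no covariance to model
  y <- residuals(lm(rnorm(10) ~ scale(X, scale = FALSE)))
  fit <- pls_fit(X, as.numeric(y), A = 1)
  expect_lt(max(abs(fit$coef)), 1e-8)
  # rank-1 X cannot support 2 components
  Xr <- cbind(1:6, 2 * (1:6), -1 * (1:6))
  expect_error(pls_fit(Xr, rnorm(6), A = 2), "effective rank")
  expect_error(pls_fit(X, rnorm(10), A = 4), "exceeds min")
})

test_that("binary PLSDA codes classes as +/-1 with an antisymmetric response", {
  d <- make_two_class(n_per = 15, p = 3, sep = 8, seed = 30)
  m1 <- plsda_fit(d$X, d$labels, A = 1)
  pr1 <- plsda_predict(m1, d$X)
  expect_equal(unname(pr1$class), d$labels)   # separable: training accuracy 1
  # swapping the coding negates responses exactly
  m2 <- plsda_fit(d$X, d$labels, A = 1, class_pos = "b", class_neg = "a")
  pr2 <- plsda_predict(m2, d$X)
  expect_equal(pr1$response, -pr2$response, tolerance = 1e-10)
  # boundary convention: response exactly at the cutoff -> negative class
  m0 <- m1
  m0$cutoff <- pr1$response[1]
  expect_equal(plsda_predict(m0, d$X[1, , drop = FALSE])$class, m1$class_neg)
  expect_error(plsda_fit(d$X, rep("a", 30), A = 1), "exactly 2 classes")
})

test_that("PLSDA responses are affine in the input rows", {
  d <- make_two_class(n_per = 12, p = 4, sep = 5, seed = 31)
  m <- plsda_fit(d$X, d$labels, A = 2)
  x1 <- d$X[1, ]
  x2 <- d$X[20, ]
  a <- 0.3
  mix <- rbind(a * x1 + (1 - a) * x2)
  r <- plsda_predict(m, rbind(x1, x2, mix))$response
  expect_equal(r[3], a * r[1] + (1 - a) * r[2], tolerance = 1e-10)
})

test_that("bias-corrected cutoff is near zero for balanced classes, shifted for imbalance", {
  d <- make_two_class(n_per = 20, p = 3, sep = 6, seed = 32)
  mb <- plsda_fit(d$X, d$labels, A = 1, bias_correction = TRUE)
  expect_lt(abs(mb$cutoff), 0.15)
  idx <- c(1:20, 21:25)   # 20 vs 5
  mi <- plsda_fit(d$X[idx, ], d$labels[idx], A = 1, bias_correction = TRUE)
  expect_gt(abs(mi$cutoff), abs(mb$cutoff))
})

test_that("MCCV pools misclassifications per the stated error-rate formula", {
  d <- make_two_class(n_per = 15, p = 3, sep = 6, seed = 33)
  cv <- mccv_select_lvs(d$X, d$labels, K = 12, holdout = 0.3, A_max = 3,
                        seed = 7)
  # ERMCCV(A) = sum_i M_i / N, recomputed independently from stored counts
  expect_equal(cv$ermccv, rowSums(cv$M) / cv$N, tolerance = 1e-15)
  expect_equal(cv$N, cv$K * sum(cv$holdout_sizes))
  expect_true(all(cv$ermccv >= 0 & cv$ermccv <= 1))
  # ties resolve to the smallest A
  expect_equal(cv$A_best, which.min(cv$ermccv))
  expect_identical(cv$M, mccv_select_lvs(d$X, d$labels, K = 12, holdout = 0.3,
                                         A_max = 3, seed = 7)$M)
})

test_that("separable data select one component with zero error", {
  x <- matrix(c(rnorm(15, -5), rnorm(15, 5)), ncol = 1)
  cv <- mccv_select_lvs(x, rep(c("a", "b"), each = 15), K = 20, seed = 8)
  expect_equal(cv$A_best, 1L)
  expect_equal(cv$ermccv[1], 0)
})

test_that("label noise yields chance-level cross-validation error", {
  ers <- vapply(1:20, function(s) {
    set.seed(400 + s)
    X <- matrix(rnorm(40 * 5), 40, 5)
    lab <- rep(c("a", "b"), each = 20)
    cv <- mccv_select_lvs(X, lab, K = 20, A_max = 3, seed = s)
    mean(cv$ermccv)
  }, numeric(1))
  expect_equal(mean(ers), 0.5, tolerance = 0.06)
})

test_that("complexity selection resists overfitting when signal spans 2 latent directions", {
  chosen <- vapply(1:50, function(s) {
    set.seed(500 + s)
    n <- 40; p <- 10
    T2 <- matrix(rnorm(n * 2), n, 2)           # signal scores
    L <- matrix(rnorm(2 * p), 2, p)            # loadings into 10-D
    X <- T2 %*% L + matrix(rnorm(n * p, sd = 0.3), n, p)
    lab <- ifelse(T2[, 1] + 0.5 * T2[, 2] > 0, "a", "b")
    if (length(unique(lab)) < 2 || min(table(lab)) < 6) return(1L)
    mccv_select_lvs(X, lab, K = 25, A_max = 8, seed = s)$A_best
  }, integer(1))
  expect_gte(mean(chosen <= 3), 0.9)
})
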