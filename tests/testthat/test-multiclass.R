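fit_small <- function(strategy, m = 3, n_per = 12, sep = 6, seed = 40,
                      K = 8) {
  set.seed(seed)
  p <- 4
  mu <- matrix(rnorm(m * p, sd = 0), m, p)
  for (c in seq_len(m)) mu[c, ] <- 0
  centers <- diag(sep, m, p)
  X <- do.call(rbind, lapply(seq_len(m), function(c)
    matrix(rnorm(n_per * p), n_per, p) + matrix(centers[c, ], n_per, p,
                                                byrow = TRUE)))
  lab <- factor(rep(paste0("c", seq_len(m)), each = n_per))
  f <- if (strategy == "ovr") ovr_fit else ovo_fit
  list(model = f(X, lab, K = K, seed = 1), X = X, labels = lab)
}

test_that("submodel counts follow the strategy formulas", {
  pan <- generate_panel(separated_spec(seed = 41))$panel
  Z <- apply_autoscale(pan, fit_autoscale(pan))
  ovr <- ovr_fit(Z, pan$labels, K = 5, A_max = 3, seed = 2)
  ovo <- ovo_fit(Z, pan$labels, K = 5, A_max = 3, seed = 2)
  expect_length(ovr$submodels, 7)
  expect_length(ovo$submodels, 21)
  expect_equal(ovr$average_LVs, mean(ovr$submodel_LVs))
  expect_equal(ovo$average_LVs, mean(ovo$submodel_LVs))
})

test_that("three separable classes are classified perfectly by both strategies", {
  for (strategy in c("ovr", "ovo")) {
    fs <- fit_small(strategy)
    pred <- if (strategy == "ovr") ovr_predict(fs$model, fs$X)
            else ovo_predict(fs$model, fs$X)
    expect_equal(as.character(pred$class), as.character(fs$labels),
                 label = strategy)
  }
})

test_that("with two classes OVR, OVO and the plain binary model agree", {
  d <- make_two_class(n_per = 14, p = 3, sep = 6, seed = 42)
  ovr <- ovr_fit(d$X, d$labels, K = 10, seed = 3, bias_correction = FALSE)
  ovo <- ovo_fit(d$X, d$labels, K = 10, seed = 3)
  bin <- plsda_fit(d$X, d$labels, A = ovo$submodels[[1]]$model$A)
  p_ovr <- as.character(ovr_predict(ovr, d$X)$class)
  p_ovo <- as.character(ovo_predict(ovo, d$X)$class)
  p_bin <- plsda_predict(bin, d$X)$class
  expect_equal(p_ovo, p_bin)
  expect_equal(p_ovr, p_ovo)
  # the two mirrored OVR submodels produce opposite responses
  r1 <- plsda_predict(ovr$submodels[[1]]$model, d$X)$response
  r2 <- plsda_predict(ovr$submodels[[2]]$model, d$X)$response
  expect_equal(r1, -r2, tolerance = 1e-10)
})

test_that("OVR assigns by largest corrected response with deterministic ties", {
  fs <- fit_small("ovr")
  pred <- ovr_predict(fs$model, fs$X)
  manual <- apply(pred$scores, 1, which.max)
  expect_equal(as.integer(pred$class), unname(manual))
  # all-negative scores still assign the argmax class (no reject option)
  row_neg <- which(apply(pred$scores, 1, max) < 0)
  if (length(row_neg)) {
    expect_false(anyNA(pred$class[row_neg]))
  }
})

test_that("OVO majority voting resolves cyclic ties by summed margins", {
  fs <- fit_small("ovo", m = 3)
  model <- fs$model
  pred <- ovo_predict(model, fs$X)
  expect_equal(rowSums(pred$votes), rep(3, nrow(fs$X)), ignore_attr = TRUE)
  # construct a cycle: c1 beats c2, c2 beats c3, c3 beats c1 (1 vote each);
  # the winner must be the class with the largest summed signed margin
  m3 <- model
  stub <- function(pos, neg, coefs, icpt) {
    pls <- list(coef_path = matrix(coefs, ncol = 1), intercepts = icpt,
                x_mean = rep(0, 4), y_mean = 0, A = 1, A_effective = 1,
                P = matrix(coefs, ncol = 1))
    class(pls) <- "pls_model"
    structure(list(pls = pls, class_pos = pos, class_neg = neg,
                   cutoff = 0, A = 1), class = "plsda_model")
  }
  z <- rbind(rep(0, 4))
  m3$submodels <- list(
    `c1|c2` = list(model = stub("c1", "c2", rep(0, 4), 0.40)),
    `c1|c3` = list(model = stub("c1", "c3", rep(0, 4), -0.10)),
    `c2|c3` = list(model = stub("c2", "c3", rep(0, 4), 0.30))
  )
  v <- ovo_predict(m3, z)
  expect_equal(unname(v$votes[1, ]), c(1, 1, 1))
  # margins: c1 = +0.40 - 0.10 = 0.30; c2 = -0.40 + 0.30 = -0.10;
  #          c3 = +0.10 - 0.30 = -0.20  -> c1 wins
  expect_equal(as.character(v$class), "c1")
})

test_that("renaming classes permutes predictions consistently", {
  fs <- fit_small("ovo", m = 3, sep = 4, seed = 44)
  pred1 <- as.character(ovo_predict(fs$model, fs$X)$class)
  ren <- c(c1 = "zz", c2 = "aa", c3 = "mm")
  lab2 <- factor(unname(ren[as.character(fs$labels)]),
                 levels = unname(ren))
  model2 <- ovo_fit(fs$X, lab2, K = 8, seed = 1)
  pred2 <- as.character(ovo_predict(model2, fs$X)$class)
  expect_equal(unname(ren[pred1]), pred2)
})

test_that("accuracy reports match the correct-count ratio and confusion total", {
  expect_equal(accuracy(c("a", "b"), c("a", "b"))$accuracy, 1)
  r <- accuracy(rep("a", 67), c(rep("a", 62), rep("b", 5)))
  expect_equal(r$N_C, 62L)
  expect_equal(round(r$accuracy, 3), 0.925)
  r2 <- accuracy(rep("a", 67), c(rep("a", 45), rep("b", 22)))
  expect_equal(round(r2$accuracy, 3), 0.672)
  expect_equal(sum(r$confusion), r$N_P)
  expect_error(accuracy(character(0), character(0)), "empty")
  expect_error(accuracy("a", c("a", "b")), "dimension mismatch")
})

test_that("loading importance is max-normalized and recovers a planted marker", {
  fs <- fit_small("ovo", m = 3)
  imp <- loading_importance(fs$model)
  expect_equal(max(imp$importance), 1)
  expect_true(all(imp$importance >= 0))
  # single informative element dominates the ranking
  hits <- 0
  for (s in 1:25) {
    set.seed(600 + s)
    n <- 20
    X <- matrix(rnorm(3 * n * 5), 3 * n, 5)
    X[, 1] <- X[, 1] + rep(c(-4, 0, 4), each = n)
    lab <- rep(c("a", "b", "c"), each = n)
    m <- ovo_fit(X, lab, K = 5, A_max = 2, seed = s)
    imp <- loading_importance(m)
    hits <- hits + (which.max(imp$importance) == 1)
  }
  expect_gte(hits, 20)
})
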