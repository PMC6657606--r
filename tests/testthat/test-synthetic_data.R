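test_that("the reference element profile exposes the printed scales", {
  prof <- default_element_profile()
  expect_equal(nrow(prof), 15)
  fe <- default_element_profile("Fe")
  expect_equal(c(fe$mean, fe$sd), c(52.16, 19.22))
  sr <- default_element_profile("Sr")
  expect_equal(c(sr$mean, sr$sd), c(11.16, 3.18))
  k <- default_element_profile("K")
  expect_equal(c(k$mean, k$sd), c(4668, 1066))
  expect_error(default_element_profile("Unobtainium"), "unknown element")
})

test_that("default panels have the reference shape and are seed-reproducible", {
  gen <- generate_panel(synthetic_spec(seed = 50))
  expect_equal(dim(gen$panel$X), c(210, 15))
  expect_equal(nlevels(gen$panel$labels), 7)
  expect_equal(as.integer(table(gen$panel$labels)), rep(30, 7))
  expect_true(all(gen$panel$X >= 0))
  gen2 <- generate_panel(synthetic_spec(seed = 50))
  expect_identical(gen$panel$X, gen2$panel$X)
  gen3 <- generate_panel(synthetic_spec(seed = 51))
  expect_false(identical(gen$panel$X, gen3$panel$X))
})

test_that("realized class means recover the specified means", {
  spec <- synthetic_spec(n_per_class = 200, within_sd_frac = 0.5, seed = 52)
  gen <- generate_panel(spec)
  pan <- gen$panel
  sdv <- spec$profile$sd
  for (c in seq_len(spec$m)) {
    idx <- pan$labels == spec$class_names[c]
    realized <- colMeans(pan$X[idx, ])
    se <- spec$within_sd_frac * sdv / sqrt(sum(idx))
    # truncation at 0 can bias trace elements slightly; 4 SE covers it
    expect_true(all(abs(realized - gen$truth$class_means[c, ]) < 4 * se),
                label = spec$class_names[c])
  }
})

test_that("planted outliers are recorded and visible in the data", {
  spec <- synthetic_spec(n_outliers = 3, outlier_sd = 10, seed = 53)
  gen <- generate_panel(spec)
  expect_length(gen$truth$outlier_rows, 3)
  expect_identical(gen$panel$samples[gen$truth$outlier_rows],
                   gen$truth$outlier_ids)
  clean <- generate_panel(synthetic_spec(seed = 53))
  moved <- which(rowSums(gen$panel$X != clean$panel$X) > 0)
  expect_setequal(moved, gen$truth$outlier_rows)
})

test_that("spec validation rejects infeasible settings", {
  expect_error(synthetic_spec(class_names = c("x", "y")), "length != m")
  expect_error(synthetic_spec(class_shifts = matrix(0, 2, 2)), "must be 7 x 15")
  expect_error(synthetic_spec(n_outliers = 10000), "more outliers")
  bad <- default_element_profile()
  bad$sd[1] <- 0
  expect_error(synthetic_spec(profile = bad), "positive")
})

test_that("correlated draws honour the requested common correlation", {
  spec <- synthetic_spec(m = 1, n_per_class = 600, correlation = 0.6,
                         class_shifts = matrix(0, 1, 15), seed = 54)
  pan <- generate_panel(spec)$panel
  cm <- cor(pan$X)
  off <- cm[upper.tri(cm)]
  expect_equal(mean(off), 0.6, tolerance = 0.05)
})

test_that("a zero-shift panel carries no class signal", {
  pan <- generate_panel(null_spec(seed = 55))$panel
  Z <- apply_autoscale(pan, fit_autoscale(pan))
  train <- unlist(lapply(levels(pan$labels), function(cl)
    which(pan$labels == cl)[1:22]))
  test <- setdiff(seq_len(210), train)
  fit <- ovo_fit(Z[train, ], pan$labels[train], K = 5, A_max = 2, seed = 1)
  acc <- accuracy(pan$labels[test],
                  ovo_predict(fit, Z[test, ])$class)$accuracy
  expect_lt(acc, 0.35)   # chance is 1/7; full null calibration is tested end-to-end
})
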