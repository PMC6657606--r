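# Independent oracles and fixture builders used across the suite.
# Oracles are deliberately plain (explicit loops, closed forms) so they stay
# independent of the implementation paths they check.

# Greedy maximin selection, brute force: recompute every candidate's minimum
# distance to the selected set by explicit loops at every step.
ks_oracle <- function(X, n_select) {
  X <- as.matrix(X)
  n <- nrow(X)
  d2 <- function(i, j) sum((X[i, ] - X[j, ])^2)
  best <- c(1L, 2L)
  best_d <- -1
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      dij <- d2(i, j)
      if (dij > best_d + 1e-12) {
        best <- c(i, j)
        best_d <- dij
      }
    }
  }
  sel <- best
  while (length(sel) < n_select) {
    cand_best <- NA_integer_
    cand_d <- -1
    for (i in seq_len(n)) {
      if (i %in% sel) next
      mind <- Inf
      for (s in sel) mind <- min(mind, d2(i, s))
      if (mind > cand_d + 1e-12) {
        cand_best <- i
        cand_d <- mind
      }
    }
    sel <- c(sel, cand_best)
  }
  sel
}

# Deterministic dense angular grid for Stahel-Donoho outlyingness in 2-D.
sde_grid_oracle <- function(X, n_angles = 3600) {
  stopifnot(ncol(X) == 2)
  theta <- pi * (seq_len(n_angles) - 1) / n_angles
  best <- rep(0, nrow(X))
  for (th in theta) {
    z <- X[, 1] * cos(th) + X[, 2] * sin(th)
    s <- stats::mad(z)
    if (s <= 0) next
    r <- abs(z - stats::median(z)) / s
    best <- pmax(best, r)
  }
  best
}

# Two well-separated Gaussian classes in p dimensions.
make_two_class <- function(n_per = 15, p = 3, sep = 6, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per * p), n_per, p),
             matrix(rnorm(n_per * p, mean = sep / sqrt(p)), n_per, p))
  list(X = X, labels = rep(c("a", "b"), each = n_per))
}

# Panel with m well-separated classes: class c shifted +shift_sd pooled SDs
# in elements 2c-1 and 2c (within-class SD equal to the pooled SD).
separated_spec <- function(m = 7, n_per_class = 30, shift_sd = 4, seed = 1) {
  prof <- default_element_profile()
  S <- matrix(0, m, nrow(prof))
  for (c in seq_len(m)) S[c, c(2 * c - 1, 2 * c)] <- shift_sd
  synthetic_spec(m = m, n_per_class = n_per_class, class_shifts = S,
                 within_sd_frac = 1, seed = seed)
}

# Spec with no class structure at all (null panel).
null_spec <- function(seed, m = 7, n_per_class = 30) {
  prof <- default_element_profile()
  synthetic_spec(m = m, n_per_class = n_per_class,
                 class_shifts = matrix(0, m, nrow(prof)),
                 within_sd_frac = 1, seed = seed)
}

# A small panel written to CSV, for IO tests.
write_temp_panel_csv <- function(df) {
  f <- tempfile(fileext = ".csv")
  utils::write.csv(df, f, row.names = FALSE)
  f
}
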