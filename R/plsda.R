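#' Binary PLS discriminant analysis
#'
#' Encodes the two classes as a dummy response of +1 (`class_pos`) and -1
#' (`class_neg`), fits PLS1 on it, and classifies new samples by
#' thresholding the continuous predicted response at a cutoff. The default
#' cutoff is 0, the midpoint of the coding. With `bias_correction = TRUE`
#' the cutoff is instead the midpoint of the two class-mean training
#' responses, which recenters the boundary when class sizes are unequal
#' (an imbalanced fit drags the response mean toward the larger class).
#'
#' @param X numeric matrix (typically autoscaled training data).
#' @param labels vector/factor with exactly two classes present.
#' @param A number of latent variables.
#' @param class_pos,class_neg which label is coded +1 / -1; default: first
#'   and second factor level of `labels`.
#' @param bias_correction logical; see above.
#' @return a `plsda_model`: the wrapped `pls_model` plus `class_pos`,
#'   `class_neg`, `cutoff`, `A`.
#' @examples
#' X <- rbind(matrix(rnorm(40, -2), 20, 2), matrix(rnorm(40, 2), 20, 2))
#' lab <- rep(c("a", "b"), each = 20)
#' m <- plsda_fit(X, lab, A = 1)
#' table(plsda_predict(m, X)$class, lab)
#' @export
plsda_fit <- function(X, labels, A, class_pos = NULL, class_neg = NULL,
                      bias_correction = FALSE) {
  X <- as.matrix(X)
  labels <- if (is.factor(labels)) droplevels(labels) else
    factor(labels, levels = unique(labels))
  if (nlevels(labels) != 2) {
    stop(sprintf("binary PLSDA needs exactly 2 classes, got %d (%s)",
                 nlevels(labels), paste(levels(labels), collapse = ", ")),
         call. = FALSE)
  }
  class_pos <- class_pos %||% levels(labels)[1]
  class_neg <- class_neg %||% setdiff(levels(labels), class_pos)
  if (!all(c(class_pos, class_neg) %in% levels(labels))) {
    stop("class_pos/class_neg not among the labels", call. = FALSE)
  }
  y <- ifelse(labels == class_pos, 1, -1)
  pls <- pls_fit(X, y, A)
  cutoff <- 0
  if (bias_correction) {
    r <- pls_predict(pls, X)
    cutoff <- (mean(r[y > 0]) + mean(r[y < 0])) / 2
  }
  structure(list(pls = pls, class_pos = class_pos, class_neg = class_neg,
                 cutoff = cutoff, A = A,
                 bias_correction = bias_correction),
            class = "plsda_model")
}

#' Predict classes and continuous responses from a binary PLSDA model
#'
#' A response strictly above the cutoff is assigned `class_pos`; at or below
#' the cutoff, `class_neg` (the boundary itself is a measure-zero
#' convention). The continuous responses are returned as well because the
#' one-versus-rest assembly ranks them across submodels.
#'
#' @param model a `plsda_model`.
#' @param X new data matrix.
#' @param A component count (default: the model's).
#' @return list with `response` (numeric), `margin` (response minus cutoff)
#'   and `class` (character).
#' @export
plsda_predict <- function(model, X, A = model$A) {
  stopifnot(inherits(model, "plsda_model"))
  r <- pls_predict(model$pls, X, A = A)
  cls <- ifelse(r > model$cutoff, model$class_pos, model$class_neg)
  list(response = r, margin = r - model$cutoff, class = cls)
}

#' Choose the number of latent variables by Monte Carlo cross-validation
#'
#' Repeatedly splits the training data at random into a model portion and a
#' held-out portion (stratified by class so both classes are always present
#' in the model portion), fits binary PLSDA at every candidate component
#' count, and pools misclassifications over all splits:
#' `ERMCCV(A) = sum_i M_i / N`, where `M_i` counts misclassified held-out
#' samples in split i and `N` is the total number of held-out tests. The
#' chosen complexity minimizes ERMCCV, with ties resolved toward the
#' smallest A (the more parsimonious model).
#'
#' @param X numeric training matrix.
#' @param labels two-class label vector.
#' @param K number of random splits (default 100).
#' @param holdout fraction of each class held out per split (default 0.30).
#' @param A_max largest candidate component count; default
#'   `min(10, p, smallest model-portion size - 1)`.
#' @param seed integer seed for the random splits.
#' @param bias_correction passed to [plsda_fit()] for each split.
#' @param class_pos,class_neg coding, as in [plsda_fit()].
#' @return an `mccv_result`: `ermccv` per candidate A, per-split
#'   misclassification counts `M` (A_max x K), holdout sizes, `N`,
#'   `A_best`, and the parameters used.
#' @examples
#' X <- rbind(matrix(rnorm(30, -3), 15, 2), matrix(rnorm(30, 3), 15, 2))
#' mccv_select_lvs(X, rep(c("a", "b"), each = 15), K = 10, seed = 1)$A_best
#' @export
mccv_select_lvs <- function(X, labels, K = 100, holdout = 0.30, A_max = NULL,
                            seed = 1, bias_correction = FALSE,
                            class_pos = NULL, class_neg = NULL) {
  X <- as.matrix(X)
  labels <- if (is.factor(labels)) droplevels(labels) else
    factor(labels, levels = unique(labels))
  if (nlevels(labels) != 2) stop("MCCV selection expects two classes", call. = FALSE)
  if (K < 1) stop("K must be >= 1", call. = FALSE)
  if (holdout <= 0 || holdout >= 1) stop("holdout must be in (0, 1)", call. = FALSE)
  n <- nrow(X)
  p <- ncol(X)
  idx_by_class <- split(seq_len(n), labels)
  n_hold <- vapply(idx_by_class, function(ix) {
    h <- round(holdout * length(ix))
    max(1L, min(length(ix) - 2L, as.integer(h)))
  }, integer(1))
  if (any(vapply(idx_by_class, length, integer(1)) - n_hold < 2)) {
    stop("a class is too small to keep 2 training samples per split", call. = FALSE)
  }
  n_model <- n - sum(n_hold)
  A_max <- A_max %||% min(10L, p, n_model - 1L)
  if (A_max < 1) stop("A_max must be >= 1", call. = FALSE)
  A_max <- min(A_max, p, n_model - 1L)
  M <- matrix(0L, nrow = A_max, ncol = K)
  with_seed(seed, {
    for (k in seq_len(K)) {
      hold <- unlist(mapply(function(ix, h) sample(ix, h),
                            idx_by_class, n_hold, SIMPLIFY = FALSE),
                     use.names = FALSE)
      train <- setdiff(seq_len(n), hold)
      fit <- plsda_fit(X[train, , drop = FALSE], labels[train], A = A_max,
                       class_pos = class_pos, class_neg = class_neg,
                       bias_correction = FALSE)
      y_true <- as.character(labels[hold])
      ytr <- ifelse(labels[train] == fit$class_pos, 1, -1)
      r_train_all <- NULL
      if (bias_correction) {
        r_train_all <- vapply(seq_len(A_max), function(a)
          pls_predict(fit$pls, X[train, , drop = FALSE], A = a),
          numeric(length(train)))
      }
      for (a in seq_len(A_max)) {
        cut_a <- 0
        if (bias_correction) {
          ra <- r_train_all[, a]
          cut_a <- (mean(ra[ytr > 0]) + mean(ra[ytr < 0])) / 2
        }
        r <- pls_predict(fit$pls, X[hold, , drop = FALSE], A = a)
        pred <- ifelse(r > cut_a, fit$class_pos, fit$class_neg)
        M[a, k] <- sum(pred != y_true)
      }
    }
  })
  N <- as.integer(K * sum(n_hold))
  ermccv <- rowSums(M) / N
  A_best <- which.min(ermccv)   # ties -> smallest A
  structure(list(K = K, holdout = holdout, A_candidates = seq_len(A_max),
                 M = M, holdout_sizes = n_hold, N = N,
                 ermccv = ermccv, A_best = as.integer(A_best),
                 seed = seed),
            class = "mccv_result")
}

#' @export
print.mccv_result <- function(x, ...) {
  cat(sprintf("mccv_result: K = %d, holdout = %.2f, N = %d\n",
              x$K, x$holdout, x$N))
  cat("  ERMCCV:", paste(sprintf("A=%d: %.3f", x$A_candidates, x$ermccv),
                         collapse = "  "), "\n")
  cat(sprintf("  chosen A = %d (ERMCCV %.3f)\n", x$A_best, x$ermccv[x$A_best]))
  invisible(x)
}
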