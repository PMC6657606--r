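#' Univariate partial least squares by NIPALS
#'
#' Fits PLS1 regression with X-block deflation. At each step the weight
#' vector is the (normalized) covariance between the deflated X and the
#' response, the score is the projection of X on it, and X is deflated by
#' the rank-one score/loading product. The regression coefficients for every
#' intermediate component count are kept (`coef_path`), so one fit serves
#' all candidate model complexities during cross-validation.
#'
#' Centering is handled internally from the training data; callers normally
#' pass autoscaled X, in which case the coefficients act on z-scores.
#'
#' If the response carries no covariance with the (remaining) X block the
#' iteration stops early and the coefficient path is padded with the last
#' attained coefficients; requesting more components than the X block's
#' effective rank is an error.
#'
#' @param X numeric matrix, n x p.
#' @param y numeric response of length n.
#' @param A number of latent variables, `1 <= A <= min(p, n - 1)`.
#' @return a `pls_model`: weights `W` (p x A), x-loadings `P`, y-loadings
#'   `q`, scores `T`, `coef_path` (p x A, column a = coefficients using a
#'   components), `coef` (final column), intercepts per component count,
#'   centering vectors, `A`, and `A_effective` (components actually
#'   extracted).
#' @examples
#' X <- matrix(rnorm(60), 20, 3); y <- X %*% c(1, -1, 0) + rnorm(20, sd = .1)
#' fit <- pls_fit(X, y, A = 2)
#' head(pls_predict(fit, X))
#' @export
pls_fit <- function(X, y, A) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  p <- ncol(X)
  if (length(y) != n) stop_dim(length(y), n, "responses")
  if (A < 1) stop("A must be >= 1", call. = FALSE)
  if (A > min(p, n - 1L)) {
    stop(sprintf("A = %d exceeds min(p, n - 1) = %d", A, min(p, n - 1L)),
         call. = FALSE)
  }
  x_mean <- colMeans(X)
  y_mean <- mean(y)
  E <- sweep(X, 2, x_mean, "-")
  f <- y - y_mean
  x_scale0 <- max(abs(E), 1e-300)
  W <- P <- matrix(0, p, A)
  Tm <- matrix(0, n, A)
  q <- numeric(A)
  A_eff <- 0L
  for (a in seq_len(A)) {
    w <- crossprod(E, f)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-10) {
      if (max(abs(E)) < 1e-8 * x_scale0) {
        stop(sprintf("A = %d exceeds the effective rank of X (rank %d)", A, A_eff),
             call. = FALSE)
      }
      break  # no covariance left: remaining components add nothing
    }
    w <- w / nw
    t <- E %*% w
    tt <- sum(t^2)
    if (tt < 1e-20) break
    pv <- crossprod(E, t) / tt
    qa <- sum(f * t) / tt
    E <- E - t %*% t(pv)
    f <- f - t * qa
    W[, a] <- w
    P[, a] <- pv
    Tm[, a] <- t
    q[a] <- qa
    A_eff <- a
  }
  coef_path <- matrix(0, p, A)
  if (A_eff > 0) {
    for (a in seq_len(A_eff)) {
      ia <- seq_len(a)
      coef_path[, a] <- W[, ia, drop = FALSE] %*%
        solve(crossprod(P[, ia, drop = FALSE], W[, ia, drop = FALSE]),
              q[ia])
    }
  }
  if (A_eff < A && A_eff > 0) {
    for (a in seq((A_eff + 1L), A)) coef_path[, a] <- coef_path[, A_eff]
  }
  intercepts <- as.numeric(y_mean - crossprod(coef_path, x_mean))
  rownames(coef_path) <- colnames(X)
  structure(list(W = W, P = P, q = q, T = Tm,
                 coef_path = coef_path, coef = coef_path[, A],
                 intercepts = intercepts,
                 x_mean = x_mean, y_mean = y_mean,
                 A = A, A_effective = max(A_eff, 1L)),
            class = "pls_model")
}

#' Predict from a fitted PLS model
#'
#' @param model a `pls_model`.
#' @param X new data with the model's column count.
#' @param A component count to use (default: the model's `A`); any
#'   `1 <= A <= model$A` is available from the stored coefficient path.
#' @return numeric vector of predicted responses.
#' @export
pls_predict <- function(model, X, A = model$A) {
  stopifnot(inherits(model, "pls_model"))
  X <- as.matrix(X)
  if (ncol(X) != length(model$x_mean)) stop_dim(ncol(X), length(model$x_mean))
  if (A < 1 || A > model$A) {
    stop(sprintf("A = %d not in stored path [1, %d]", A, model$A), call. = FALSE)
  }
  as.numeric(X %*% model$coef_path[, A] + model$intercepts[A])
}
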