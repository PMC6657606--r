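#' Fit an autoscaling model
#'
#' Computes per-element training means and standard deviations (n-1
#' denominator). Autoscaling -- mean-centering each element and rescaling to
#' unit standard deviation -- puts elements whose natural scales span four
#' orders of magnitude (e.g. Cd at ~0.08 ug/g versus K at ~4700 ug/g) on an
#' equal footing before projection-based modelling.
#'
#' @param X numeric matrix or `element_panel`.
#' @return a `scaling_model`: list with `means`, `sds`, `elements`.
#' @examples
#' fit_autoscale(cbind(a = c(1, 2, 3), b = c(2, 4, 6)))
#' @export
fit_autoscale <- function(X) {
  if (inherits(X, "element_panel")) X <- X$X
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("need at least 2 rows to estimate a standard deviation",
                        call. = FALSE)
  means <- colMeans(X)
  sds <- apply(X, 2, stats::sd)
  zero <- which(sds <= 0 | !is.finite(sds))
  if (length(zero)) {
    nm <- colnames(X) %||% as.character(seq_len(ncol(X)))
    stop("zero-variance element(s): ", paste(nm[zero], collapse = ", "),
         call. = FALSE)
  }
  structure(list(means = means, sds = sds,
                 elements = colnames(X) %||% paste0("element_", seq_len(ncol(X)))),
            class = "scaling_model")
}

#' Apply (or invert) an autoscaling model
#'
#' @param X numeric matrix or `element_panel` with the same column count as
#'   the model.
#' @param model a `scaling_model` from [fit_autoscale()].
#' @return matrix of z-scores `(x - mean) / sd`.
#' @export
apply_autoscale <- function(X, model) {
  stopifnot(inherits(model, "scaling_model"))
  if (inherits(X, "element_panel")) X <- X$X
  X <- as.matrix(X)
  if (ncol(X) != length(model$means)) stop_dim(ncol(X), length(model$means))
  sweep(sweep(X, 2, model$means, "-"), 2, model$sds, "/")
}

#' @rdname apply_autoscale
#' @param Z matrix of autoscaled values to map back to the original scale.
#' @export
invert_autoscale <- function(Z, model) {
  stopifnot(inherits(model, "scaling_model"))
  Z <- as.matrix(Z)
  if (ncol(Z) != length(model$means)) stop_dim(ncol(Z), length(model$means))
  sweep(sweep(Z, 2, model$sds, "*"), 2, model$means, "+")
}

#' Principal component analysis for exploratory scores and loadings
#'
#' Thin SVD of the column-centered input. In the pipeline the input is
#' already autoscaled, so this is correlation-matrix PCA of the raw panel.
#' Loading signs are fixed by forcing the largest-magnitude loading of each
#' component positive, making score plots reproducible across platforms.
#'
#' @param X numeric matrix (typically autoscaled).
#' @param k number of components, at most `min(n - 1, p)`.
#' @return a `pca_result`: `scores` (n x k), `loadings` (p x k, orthonormal
#'   columns), `explained_variance_ratio` (fractions of total variance,
#'   non-increasing), `center`.
#' @examples
#' pca_fit(matrix(rnorm(40), 10, 4), k = 2)$explained_variance_ratio
#' @export
pca_fit <- function(X, k = 2) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  kmax <- min(n - 1L, p)
  if (k < 1 || k > kmax) {
    stop(sprintf("k = %d out of range [1, min(n-1, p) = %d]", k, kmax),
         call. = FALSE)
  }
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr, "-")
  sv <- svd(Xc, nu = 0, nv = k)
  total <- sum(Xc^2)
  ratio <- sv$d[seq_len(k)]^2 / total
  loadings <- sv$v
  # sign convention: dominant loading positive per component
  for (j in seq_len(k)) {
    piv <- which.max(abs(loadings[, j]))
    if (loadings[piv, j] < 0) loadings[, j] <- -loadings[, j]
  }
  rownames(loadings) <- colnames(X)
  colnames(loadings) <- paste0("PC", seq_len(k))
  scores <- Xc %*% loadings
  structure(list(scores = scores, loadings = loadings,
                 explained_variance_ratio = ratio, center = ctr),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("pca_result: %d components\n", ncol(x$loadings)))
  cat("  explained variance:",
      paste(sprintf("%.2f%%", 100 * x$explained_variance_ratio),
            collapse = ", "), "\n")
  invisible(x)
}
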