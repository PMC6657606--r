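#' Stahel-Donoho outlyingness by random projections
#'
#' A sample's outlyingness is its worst-case robust z-score over 1-D
#' projections of the data: for each random unit vector v, project all
#' samples onto v and score sample i as
#' `|x_i' v - median(X v)| / (1.4826 * MAD(X v))`; the reported score is the
#' maximum over projections. Because median and MAD resist contamination,
#' clusters of outliers cannot mask each other the way they can with
#' classical Mahalanobis distance.
#'
#' By default the random unit vectors are normalized differences of random
#' sample pairs (`directions = "pairs"`), the classical Stahel-Donoho
#' subsampling scheme. Pair differences concentrate in the directions the
#' data actually occupy, which keeps the worst-case z-score of a clean
#' sample near its nominal 1-D behaviour -- essential for a fixed cutoff
#' like the three-sigma rule -- while any direction pointing at a gross
#' outlier is sampled as soon as one of its pairs involves that sample.
#' Directions drawn uniformly from the unit sphere
#' (`directions = "sphere"`) are also available; note that in dimension
#' p >> 2 the maximum over many sphere directions is inflated for every
#' sample (each direction is per-direction standardized, so even
#' negligible-variance dimensions contribute full-size z-scores, and the
#' n-sample MAD noise compounds over the maximum), which makes a fixed
#' cutoff unusable unless the data are effectively low-dimensional.
#'
#' Directions are drawn sequentially from `seed`, so the first k directions
#' of a longer run reproduce a shorter run exactly. Projections with zero
#' MAD (all projected values tied) are skipped; if every projection
#' degenerates the data carry no usable scale and an error is raised.
#'
#' @param X numeric matrix, n >= 3 rows.
#' @param n_projections number of random directions (default 1000).
#' @param seed integer seed controlling the directions (default 1).
#' @param directions direction sampling scheme: `"pairs"` (default) or
#'   `"sphere"`.
#' @return numeric vector of n nonnegative scores.
#' @examples
#' X <- rbind(matrix(rnorm(60), 30, 2), c(10, 10))
#' sde_outlyingness(X, n_projections = 500, seed = 1)[31] > 3
#' @export
sde_outlyingness <- function(X, n_projections = 1000, seed = 1,
                             directions = c("pairs", "sphere")) {
  X <- as.matrix(X)
  directions <- match.arg(directions)
  n <- nrow(X)
  p <- ncol(X)
  if (n < 3) stop("need at least 3 samples for a robust scale", call. = FALSE)
  if (n_projections < 1) stop("n_projections must be >= 1", call. = FALSE)
  if (directions == "pairs") {
    # one 2-row column per projection keeps direction draws nested in k
    U <- with_seed(seed, matrix(stats::runif(2 * n_projections), nrow = 2))
    i <- ceiling(U[1, ] * n)
    off <- ceiling(U[2, ] * (n - 1))
    j <- 1L + (i + off - 1L) %% n          # j != i, uniform over the rest
    V <- t(X[i, , drop = FALSE] - X[j, , drop = FALSE])
  } else {
    V <- with_seed(seed, matrix(stats::rnorm(p * n_projections), nrow = p))
  }
  len <- sqrt(colSums(V^2))
  nonzero <- len > 0
  if (!any(nonzero)) {
    stop("degenerate scale: every projection has zero MAD (tied data)",
         call. = FALSE)
  }
  V <- sweep(V[, nonzero, drop = FALSE], 2, len[nonzero], "/")
  Z <- X %*% V                               # n x n_projections
  med <- apply(Z, 2, stats::median)
  scl <- apply(Z, 2, stats::mad)             # 1.4826 * MAD by default
  ok <- scl > 0
  if (!any(ok)) {
    stop("degenerate scale: every projection has zero MAD (tied data)",
         call. = FALSE)
  }
  A <- abs(sweep(Z[, ok, drop = FALSE], 2, med[ok], "-"))
  A <- sweep(A, 2, scl[ok], "/")
  scores <- apply(A, 1, max)
  names(scores) <- rownames(X)
  scores
}

#' Flag outliers within each origin class
#'
#' Outlyingness is computed separately inside every class, so a sample is
#' judged against its own origin's distribution, not the pooled panel --
#' pooling would let genuine between-origin differences masquerade as
#' outliers. Samples whose score exceeds `threshold` (default 3, the
#' three-sigma rule) are flagged. Screening is single-pass: scores are not
#' recomputed after exclusion.
#'
#' Before projecting, each class is robustly standardized element-wise
#' (median centred, scaled by 1.4826 MAD). Concentration scales span four
#' orders of magnitude across elements, so random projections of the raw
#' matrix are dominated by the high-level elements (K, Ca) and a gross
#' anomaly confined to trace elements (Cd, Pb, Co) would be invisible;
#' standardizing restores sensitivity to every element. The median/MAD pair
#' is used rather than mean/SD so a gross outlier cannot deflate its own
#' score through the scale estimate.
#'
#' @param panel an [element_panel()]; every class needs >= 3 samples.
#' @param threshold outlyingness cutoff (default 3).
#' @param n_projections random projections per class (default 1000).
#' @param seed integer seed; each class uses a seed derived from it.
#' @param standardize robustly standardize each class before projecting
#'   (default TRUE; disable only for data already on a common scale).
#' @param directions direction sampling scheme, see [sde_outlyingness()].
#' @return an `sde_result`: per-class list of scores and masks, the flagged
#'   sample ids, and the parameters used.
#' @export
flag_outliers_per_class <- function(panel, threshold = 3,
                                    n_projections = 1000, seed = 1,
                                    standardize = TRUE,
                                    directions = c("pairs", "sphere")) {
  stopifnot(inherits(panel, "element_panel"))
  directions <- match.arg(directions)
  classes <- levels(panel$labels)
  per_class <- vector("list", length(classes))
  names(per_class) <- classes
  for (k in seq_along(classes)) {
    idx <- which(panel$labels == classes[k])
    if (length(idx) < 3) {
      stop(sprintf("class '%s' has %d samples; need >= 3", classes[k],
                   length(idx)), call. = FALSE)
    }
    Xk <- panel$X[idx, , drop = FALSE]
    if (standardize) Xk <- robust_standardize(Xk)
    sc <- sde_outlyingness(Xk, n_projections = n_projections,
                           seed = derive_seed(seed, k),
                           directions = directions)
    per_class[[k]] <- list(
      indices = idx,
      samples = panel$samples[idx],
      outlyingness = sc,
      outlier_mask = sc > threshold
    )
  }
  flagged_idx <- unlist(lapply(per_class, function(cl) cl$indices[cl$outlier_mask]),
                        use.names = FALSE)
  structure(list(per_class = per_class,
                 threshold = threshold,
                 n_projections = n_projections,
                 directions = directions,
                 seed = seed,
                 outlier_indices = sort(flagged_idx),
                 outlier_ids = panel$samples[sort(flagged_idx)]),
            class = "sde_result")
}

#' @export
print.sde_result <- function(x, ...) {
  flags <- vapply(x$per_class, function(cl) sum(cl$outlier_mask), integer(1))
  cat(sprintf("sde_result: threshold %.3g, %d projections, seed %s\n",
              x$threshold, x$n_projections, format(x$seed)))
  cat("  flags per class:",
      paste(sprintf("%s=%d", names(flags), flags), collapse = ", "), "\n")
  cat(sprintf("  total flagged: %d\n", length(x$outlier_ids)))
  invisible(x)
}

# Median-centre and MAD-scale columns. Columns whose MAD is zero (more than
# half the class tied) fall back to the SD, and to unit scale when that is
# zero too -- a constant column then contributes nothing to any projection.
robust_standardize <- function(X) {
  ctr <- apply(X, 2, stats::median)
  scl <- apply(X, 2, stats::mad)
  fall <- scl <= 0
  if (any(fall)) scl[fall] <- apply(X[, fall, drop = FALSE], 2, stats::sd)
  scl[scl <= 0] <- 1
  sweep(sweep(X, 2, ctr, "-"), 2, scl, "/")
}

#' Remove flagged outliers from a panel
#'
#' @param panel the `element_panel` the screening was run on.
#' @param result an `sde_result` from [flag_outliers_per_class()].
#' @return the panel restricted to unflagged samples (row order preserved).
#' @export
remove_outliers <- function(panel, result) {
  stopifnot(inherits(panel, "element_panel"), inherits(result, "sde_result"))
  keep <- setdiff(seq_len(n_samples(panel)), result$outlier_indices)
  subset_panel(panel, keep)
}
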