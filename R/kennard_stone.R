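#' Kennard-Stone maximin sample selection
#'
#' Deterministic space-filling selection: the first two picks are the pair
#' at maximum Euclidean distance; each later pick maximizes its minimum
#' distance to the already-selected set. Ties are broken toward the lowest
#' row index (for the seed pair, the lexicographically smallest index pair),
#' so identical input always yields an identical selection.
#'
#' @param X numeric matrix of candidate points (rows).
#' @param n_select how many rows to select; `2 <= n_select <= nrow(X)`.
#' @return integer vector of selected row indices, in selection order.
#' @examples
#' kennard_stone(cbind(c(0, 1, 2, 3, 10)), 3)   # 1, 5, 4
#' @export
kennard_stone <- function(X, n_select) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n_select < 2) stop("n_select must be >= 2 (the algorithm seeds with a pair)",
                         call. = FALSE)
  if (n_select > n) stop(sprintf("n_select = %d exceeds n = %d", n_select, n),
                         call. = FALSE)
  D <- as.matrix(stats::dist(X))
  # seed pair: maximum distance; ties -> smallest (i, j)
  up <- which(upper.tri(D), arr.ind = TRUE)
  dv <- D[up]
  best <- up[which(dv == max(dv)), , drop = FALSE]
  best <- best[order(best[, 1], best[, 2]), , drop = FALSE]
  sel <- as.integer(best[1, 1:2])
  if (n_select > 2) {
    remaining <- setdiff(seq_len(n), sel)
    mind <- pmin(D[, sel[1]], D[, sel[2]])
    while (length(sel) < n_select) {
      pick <- remaining[which.max(mind[remaining])]   # which.max: lowest index on ties
      sel <- c(sel, pick)
      remaining <- setdiff(remaining, pick)
      mind <- pmin(mind, D[, pick])
    }
  }
  as.integer(sel)
}

#' Split a panel into learning and prediction sets, class by class
#'
#' Kennard-Stone selection is run independently inside each origin class --
#' classes from different regions occupy different parts of element space,
#' and a pooled split could starve a class of training representatives. The
#' per-class selections are then merged into the final learning and
#' prediction sets. Distances are measured on the autoscaled full-panel
#' representation (scaling fitted on all retained samples), so the split
#' geometry is comparable across elements of very different natural scale.
#'
#' @param panel an outlier-filtered [element_panel()]; every class needs
#'   >= 3 samples.
#' @param train_rule either the string `"ceil23"` (default: train count is
#'   `ceiling(2 n / 3)` per class), a single integer count applied to every
#'   class, a named integer vector of per-class counts, or a fraction in
#'   (0, 1) rounded up per class.
#' @return a `split_plan`: per-class train/test index lists, a per-class
#'   summary table, and merged `learning`/`prediction` index vectors into
#'   the panel.
#' @examples
#' pan <- generate_panel(synthetic_spec(seed = 7))$panel
#' split_per_class(pan)$summary
#' @export
split_per_class <- function(panel, train_rule = "ceil23") {
  stopifnot(inherits(panel, "element_panel"))
  classes <- levels(panel$labels)
  Z <- apply_autoscale(panel, fit_autoscale(panel))
  n_train_for <- function(cls, n) {
    if (identical(train_rule, "ceil23")) return(as.integer(ceiling(2 * n / 3)))
    if (is.numeric(train_rule) && length(train_rule) == 1 && is.null(names(train_rule))) {
      if (train_rule > 0 && train_rule < 1) return(as.integer(ceiling(train_rule * n)))
      return(as.integer(train_rule))
    }
    if (is.numeric(train_rule) && !is.null(names(train_rule))) {
      if (!cls %in% names(train_rule)) {
        stop(sprintf("train_rule has no entry for class '%s'", cls), call. = FALSE)
      }
      return(as.integer(train_rule[[cls]]))
    }
    stop("unrecognised train_rule", call. = FALSE)
  }
  per_class <- vector("list", length(classes))
  names(per_class) <- classes
  for (k in seq_along(classes)) {
    idx <- which(panel$labels == classes[k])
    n_k <- length(idx)
    if (n_k < 3) {
      stop(sprintf("class '%s' has %d retained samples; need >= 3",
                   classes[k], n_k), call. = FALSE)
    }
    nt <- n_train_for(classes[k], n_k)
    if (nt < 2 || nt > n_k) {
      stop(sprintf("train count %d infeasible for class '%s' (n = %d)",
                   nt, classes[k], n_k), call. = FALSE)
    }
    sel <- kennard_stone(Z[idx, , drop = FALSE], nt)
    per_class[[k]] <- list(train = idx[sel],
                           test = idx[setdiff(seq_len(n_k), sel)])
  }
  summary <- data.frame(
    class = classes,
    n = vapply(per_class, function(s) length(s$train) + length(s$test), integer(1)),
    n_train = vapply(per_class, function(s) length(s$train), integer(1)),
    n_test = vapply(per_class, function(s) length(s$test), integer(1)),
    row.names = NULL
  )
  structure(list(per_class = per_class,
                 summary = summary,
                 learning = sort(unlist(lapply(per_class, `[[`, "train"),
                                        use.names = FALSE)),
                 prediction = sort(unlist(lapply(per_class, `[[`, "test"),
                                          use.names = FALSE)),
                 train_rule = train_rule),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("split_plan: %d learning / %d prediction\n",
              length(x$learning), length(x$prediction)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
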