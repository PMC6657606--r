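#' One-versus-rest multiclass PLSDA
#'
#' Builds m binary submodels, one per class: submodel i codes class i as +1
#' and the pooled remaining m - 1 classes as -1. Each submodel's latent
#' variable count is chosen independently by MCCV ([mccv_select_lvs()]).
#' Because every 1-versus-rest fit is imbalanced (1 : m-1), submodels use
#' the bias-corrected cutoff by default; assignment ranks the
#' cutoff-corrected responses, so the correction matters even under argmax.
#'
#' @param X autoscaled training matrix.
#' @param labels class labels (>= 2 classes, each with >= 2 samples).
#' @param K,holdout,A_max MCCV settings, see [mccv_select_lvs()].
#' @param seed integer; each submodel derives its own split seed from it.
#' @param bias_correction default TRUE for OVR.
#' @return a `multiclass_plsda` with `strategy = "ovr"`, ordered `classes`,
#'   one `plsda_model` + `mccv_result` per class, and `average_LVs`.
#' @examples
#' pan <- generate_panel(synthetic_spec(m = 3, n_per_class = 12, seed = 3))$panel
#' Z <- apply_autoscale(pan, fit_autoscale(pan))
#' fit <- ovr_fit(Z, pan$labels, K = 10)
#' fit$average_LVs
#' @export
ovr_fit <- function(X, labels, K = 100, holdout = 0.30, A_max = NULL,
                    seed = 1, bias_correction = TRUE) {
  X <- as.matrix(X)
  labels <- if (is.factor(labels)) droplevels(labels) else
    factor(labels, levels = unique(labels))
  classes <- levels(labels)
  m <- length(classes)
  if (m < 2) stop("need at least 2 classes", call. = FALSE)
  small <- table(labels) < 2
  if (any(small)) {
    stop("class(es) with < 2 training samples: ",
         paste(names(which(small)), collapse = ", "), call. = FALSE)
  }
  submodels <- vector("list", m)
  names(submodels) <- classes
  for (i in seq_len(m)) {
    lab2 <- factor(ifelse(labels == classes[i], classes[i], ".rest"),
                   levels = c(classes[i], ".rest"))
    cv <- mccv_select_lvs(X, lab2, K = K, holdout = holdout, A_max = A_max,
                          seed = derive_seed(seed, i),
                          bias_correction = bias_correction,
                          class_pos = classes[i], class_neg = ".rest")
    fit <- plsda_fit(X, lab2, A = cv$A_best,
                     class_pos = classes[i], class_neg = ".rest",
                     bias_correction = bias_correction)
    submodels[[i]] <- list(model = fit, mccv = cv)
  }
  new_multiclass("ovr", classes, submodels, seed)
}

#' One-versus-one multiclass PLSDA
#'
#' Builds m(m-1)/2 pairwise binary submodels, each trained only on the rows
#' of its two classes; prediction is by majority vote over all pairwise
#' assignments. Pairwise training sets are nearly balanced when class sizes
#' are, so the plain cutoff-0 rule is the default here.
#'
#' @inheritParams ovr_fit
#' @param bias_correction default FALSE for OVO.
#' @return a `multiclass_plsda` with `strategy = "ovo"` and one submodel per
#'   unordered class pair.
#' @export
ovo_fit <- function(X, labels, K = 100, holdout = 0.30, A_max = NULL,
                    seed = 1, bias_correction = FALSE) {
  X <- as.matrix(X)
  labels <- if (is.factor(labels)) droplevels(labels) else
    factor(labels, levels = unique(labels))
  classes <- levels(labels)
  m <- length(classes)
  if (m < 2) stop("need at least 2 classes", call. = FALSE)
  small <- table(labels) < 2
  if (any(small)) {
    stop("class(es) with < 2 training samples: ",
         paste(names(which(small)), collapse = ", "), call. = FALSE)
  }
  pairs <- utils::combn(m, 2)
  submodels <- vector("list", ncol(pairs))
  for (s in seq_len(ncol(pairs))) {
    i <- pairs[1, s]; j <- pairs[2, s]
    rows <- which(labels %in% classes[c(i, j)])
    lab2 <- factor(as.character(labels[rows]), levels = classes[c(i, j)])
    cv <- mccv_select_lvs(X[rows, , drop = FALSE], lab2, K = K,
                          holdout = holdout, A_max = A_max,
                          seed = derive_seed(seed, s),
                          bias_correction = bias_correction,
                          class_pos = classes[i], class_neg = classes[j])
    fit <- plsda_fit(X[rows, , drop = FALSE], lab2, A = cv$A_best,
                     class_pos = classes[i], class_neg = classes[j],
                     bias_correction = bias_correction)
    submodels[[s]] <- list(model = fit, mccv = cv)
    names(submodels)[s] <- paste(classes[i], classes[j], sep = "|")
  }
  new_multiclass("ovo", classes, submodels, seed)
}

new_multiclass <- function(strategy, classes, submodels, seed) {
  lvs <- vapply(submodels, function(s) s$model$A, numeric(1))
  structure(list(strategy = strategy, classes = classes,
                 submodels = submodels,
                 submodel_LVs = lvs,
                 average_LVs = mean(lvs),
                 submodel_ermccv = vapply(submodels, function(s)
                   s$mccv$ermccv[s$mccv$A_best], numeric(1)),
                 seed = seed),
            class = "multiclass_plsda")
}

#' @export
print.multiclass_plsda <- function(x, ...) {
  cat(sprintf("multiclass_plsda (%s): %d classes, %d submodels\n",
              toupper(x$strategy), length(x$classes), length(x$submodels)))
  cat(sprintf("  average LVs: %.2f; mean submodel ERMCCV: %.3f\n",
              x$average_LVs, mean(x$submodel_ermccv)))
  invisible(x)
}

#' Predict origin classes with a one-versus-rest model
#'
#' Each sample receives m cutoff-corrected responses and is assigned to the
#' class with the largest; exact ties go to the class earliest in the
#' model's class order. There is no reject option: an all-negative response
#' vector still yields the argmax class.
#'
#' @param model a `multiclass_plsda` with strategy `"ovr"`.
#' @param X autoscaled data matrix.
#' @return list with `class` (factor) and `scores` (n x m matrix of
#'   cutoff-corrected responses).
#' @export
ovr_predict <- function(model, X) {
  stopifnot(inherits(model, "multiclass_plsda"), model$strategy == "ovr")
  X <- as.matrix(X)
  m <- length(model$classes)
  scores <- vapply(seq_len(m), function(i)
    plsda_predict(model$submodels[[i]]$model, X)$margin,
    numeric(nrow(X)))
  scores <- matrix(scores, nrow = nrow(X), ncol = m,
                   dimnames = list(rownames(X), model$classes))
  pick <- apply(scores, 1, which.max)   # ties -> earliest class
  list(class = factor(model$classes[pick], levels = model$classes),
       scores = scores)
}

#' Predict origin classes with a one-versus-one model
#'
#' Every pairwise submodel casts one vote; the class with most votes wins.
#' If several classes tie on votes the winner is the tied class with the
#' largest sum of signed response margins over the submodels it appears in
#' (a cyclic A>B>C>A situation is resolved by how decisively each class won
#' and lost); any remaining tie goes to class order.
#'
#' @param model a `multiclass_plsda` with strategy `"ovo"`.
#' @param X autoscaled data matrix.
#' @return list with `class` (factor) and `votes` (n x m count matrix).
#' @export
ovo_predict <- function(model, X) {
  stopifnot(inherits(model, "multiclass_plsda"), model$strategy == "ovo")
  X <- as.matrix(X)
  n <- nrow(X)
  m <- length(model$classes)
  votes <- matrix(0L, n, m, dimnames = list(rownames(X), model$classes))
  margin_sum <- matrix(0, n, m, dimnames = dimnames(votes))
  for (s in seq_along(model$submodels)) {
    sub <- model$submodels[[s]]$model
    pr <- plsda_predict(sub, X)
    i <- match(sub$class_pos, model$classes)
    j <- match(sub$class_neg, model$classes)
    wins_i <- pr$margin > 0
    votes[, i] <- votes[, i] + as.integer(wins_i)
    votes[, j] <- votes[, j] + as.integer(!wins_i)
    margin_sum[, i] <- margin_sum[, i] + pr$margin
    margin_sum[, j] <- margin_sum[, j] - pr$margin
  }
  pick <- integer(n)
  for (r in seq_len(n)) {
    top <- which(votes[r, ] == max(votes[r, ]))
    if (length(top) > 1) {
      best <- margin_sum[r, top]
      top <- top[best == max(best)]
    }
    pick[r] <- top[1]   # class order breaks any remaining tie
  }
  list(class = factor(model$classes[pick], levels = model$classes),
       votes = votes)
}

#' Classification accuracy and confusion matrix
#'
#' Accuracy is the fraction of correctly predicted samples,
#' `N_C / N_P`, where `N_P` is the prediction-set size and `N_C` the number
#' of correct assignments. The confusion matrix has true classes as rows
#' and predicted classes as columns.
#'
#' @param true,predicted equal-length label vectors.
#' @param classes optional class ordering for the confusion matrix; default
#'   is the union of levels in order of appearance.
#' @return an `accuracy_report`: `N_P`, `N_C`, `accuracy`, `confusion`.
#' @examples
#' accuracy(c("a", "a", "b"), c("a", "b", "b"))$accuracy
#' @export
accuracy <- function(true, predicted, classes = NULL) {
  if (length(true) != length(predicted)) {
    stop_dim(length(predicted), length(true), "predictions")
  }
  if (!length(true)) stop("empty prediction set: accuracy undefined", call. = FALSE)
  classes <- classes %||% unique(c(as.character(true), as.character(predicted)))
  t_f <- factor(as.character(true), levels = classes)
  p_f <- factor(as.character(predicted), levels = classes)
  confusion <- table(true = t_f, predicted = p_f)
  N_P <- length(true)
  N_C <- sum(diag(confusion))
  structure(list(N_P = N_P, N_C = as.integer(N_C),
                 accuracy = N_C / N_P, confusion = confusion),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("accuracy: %.3f (%d / %d)\n", x$accuracy, x$N_C, x$N_P))
  print(x$confusion)
  invisible(x)
}

#' Element importance from submodel loadings
#'
#' Aggregates the absolute first-latent-variable x-loadings across all
#' binary submodels (mean over submodels) and normalizes the result to a
#' maximum of 1. Absolute values are used because each submodel's loading
#' sign depends only on its arbitrary +1/-1 coding direction. The ranking
#' identifies which elements carry the discriminating signal -- the marker
#' elements of the panel.
#'
#' @param model a fitted `multiclass_plsda`.
#' @return data.frame with columns `element` and `importance`, in panel
#'   column order.
#' @export
loading_importance <- function(model) {
  stopifnot(inherits(model, "multiclass_plsda"))
  p <- nrow(model$submodels[[1]]$model$pls$P)
  L <- vapply(model$submodels, function(s) abs(s$model$pls$P[, 1]),
              numeric(p))
  L <- matrix(L, nrow = p)
  imp <- rowMeans(L)
  imp <- imp / max(imp)
  elements <- rownames(model$submodels[[1]]$model$pls$coef_path) %||%
    paste0("element_", seq_along(imp))
  data.frame(element = elements, importance = unname(imp))
}
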