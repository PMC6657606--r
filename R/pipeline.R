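#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end workflow with its default:
#' 1000 random projections and a 3-sigma cutoff for outlier screening, the
#' ceiling(2n/3) per-class train rule, and MCCV with 100 splits holding out
#' 30% for latent-variable selection.
#'
#' @param sde_threshold outlyingness cutoff (default 3).
#' @param sde_projections random projections per class (default 1000).
#' @param sde_seed seed for the projection directions.
#' @param train_rule passed to [split_per_class()].
#' @param mccv_K,mccv_holdout,mccv_A_max,mccv_seed MCCV settings, see
#'   [mccv_select_lvs()].
#' @param strategies which multiclass strategies to run.
#' @param ovr_bias_correction,ovo_bias_correction cutoff handling per
#'   strategy (OVR submodels are 1 : m-1 imbalanced, so correction defaults
#'   on there; OVO pairs are near-balanced, so it defaults off).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(sde_threshold = 3, sde_projections = 1000,
                            sde_seed = 1, train_rule = "ceil23",
                            mccv_K = 100, mccv_holdout = 0.30,
                            mccv_A_max = NULL, mccv_seed = 1,
                            strategies = c("ovr", "ovo"),
                            ovr_bias_correction = TRUE,
                            ovo_bias_correction = FALSE) {
  strategies <- match.arg(strategies, c("ovr", "ovo"), several.ok = TRUE)
  structure(list(sde_threshold = sde_threshold,
                 sde_projections = sde_projections, sde_seed = sde_seed,
                 train_rule = train_rule, mccv_K = mccv_K,
                 mccv_holdout = mccv_holdout, mccv_A_max = mccv_A_max,
                 mccv_seed = mccv_seed, strategies = strategies,
                 ovr_bias_correction = ovr_bias_correction,
                 ovo_bias_correction = ovo_bias_correction),
            class = "pipeline_config")
}

#' Run the full origin-authentication workflow
#'
#' Stages, in order: (1) Stahel-Donoho outlier screening within each class
#' and removal of flagged samples; (2) per-class Kennard-Stone splitting of
#' the retained panel into learning and prediction sets; (3) autoscaling
#' refitted on the learning set only and applied to both sets -- the
#' prediction set never influences scaling, component selection or model
#' fitting; (4) for each requested strategy, per-submodel MCCV selection of
#' latent variables, final fitting on the learning set, and prediction of
#' the held-back prediction set; (5) accuracy, confusion matrix, average
#' latent variables, ERMCCV and loading-importance reporting.
#'
#' @param panel an [element_panel()].
#' @param config a [pipeline_config()].
#' @return a named list of `pipeline_report` objects, one per strategy.
#'   Each carries the confusion matrix, accuracy, per-submodel LV counts
#'   and ERMCCV, average LVs, flagged outlier ids, the per-class split
#'   summary, the element importance table, and the seeds used.
#' @examples
#' pan <- generate_panel(synthetic_spec(m = 3, n_per_class = 12, seed = 5))$panel
#' rep <- run_pipeline(pan, pipeline_config(mccv_K = 10, strategies = "ovo"))
#' rep$ovo$accuracy$accuracy
#' @export
run_pipeline <- function(panel, config = pipeline_config()) {
  stopifnot(inherits(panel, "element_panel"),
            inherits(config, "pipeline_config"))
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE)
    })
  }
  sde <- run_stage("outliers",
    flag_outliers_per_class(panel, threshold = config$sde_threshold,
                            n_projections = config$sde_projections,
                            seed = config$sde_seed))
  retained <- run_stage("outliers", remove_outliers(panel, sde))
  plan <- run_stage("split", split_per_class(retained, config$train_rule))
  learn <- subset_panel(retained, plan$learning)
  pred <- subset_panel(retained, plan$prediction)
  scal <- run_stage("autoscale", fit_autoscale(learn))
  Z_learn <- apply_autoscale(learn, scal)
  Z_pred <- apply_autoscale(pred, scal)

  outlier_counts <- vapply(sde$per_class, function(cl) sum(cl$outlier_mask),
                           integer(1))
  split_summary <- plan$summary
  split_summary$n_outliers <- as.integer(outlier_counts[split_summary$class])
  split_summary$n_input <- split_summary$n + split_summary$n_outliers
  split_summary <- split_summary[, c("class", "n_input", "n_outliers",
                                     "n_train", "n_test")]

  reports <- list()
  for (strategy in config$strategies) {
    model <- run_stage(paste0("fit_", strategy), {
      if (strategy == "ovr") {
        ovr_fit(Z_learn, learn$labels, K = config$mccv_K,
                holdout = config$mccv_holdout, A_max = config$mccv_A_max,
                seed = config$mccv_seed,
                bias_correction = config$ovr_bias_correction)
      } else {
        ovo_fit(Z_learn, learn$labels, K = config$mccv_K,
                holdout = config$mccv_holdout, A_max = config$mccv_A_max,
                seed = config$mccv_seed,
                bias_correction = config$ovo_bias_correction)
      }
    })
    pr <- run_stage(paste0("predict_", strategy),
                    if (strategy == "ovr") ovr_predict(model, Z_pred)
                    else ovo_predict(model, Z_pred))
    acc <- accuracy(pred$labels, pr$class, classes = model$classes)
    reports[[strategy]] <- structure(list(
      strategy = strategy,
      confusion = acc$confusion,
      accuracy = acc,
      submodel_LVs = model$submodel_LVs,
      average_LVs = model$average_LVs,
      submodel_ermccv = model$submodel_ermccv,
      outlier_ids = sde$outlier_ids,
      split_summary = split_summary,
      importance = loading_importance(model),
      predicted = stats::setNames(as.character(pr$class), pred$samples),
      model = model,
      seeds = list(sde = config$sde_seed, mccv = config$mccv_seed)),
      class = "pipeline_report")
  }
  reports
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("pipeline_report (%s)\n", toupper(x$strategy)))
  cat(sprintf("  accuracy: %.3f (%d / %d); average LVs: %.2f; mean ERMCCV: %.3f\n",
              x$accuracy$accuracy, x$accuracy$N_C, x$accuracy$N_P,
              x$average_LVs, mean(x$submodel_ermccv)))
  cat(sprintf("  outliers removed: %d; learning %d / prediction %d\n",
              length(x$outlier_ids), sum(x$split_summary$n_train),
              sum(x$split_summary$n_test)))
  invisible(x)
}

#' Serialize a pipeline report
#'
#' Writes a machine-readable JSON file and, alongside it, a human-readable
#' plain-text summary (same path with extension `.txt`). Accuracy is
#' printed to three decimals in the text summary.
#'
#' @param report a `pipeline_report`.
#' @param path output path for the JSON file.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "pipeline_report"))
  if (is.null(report$accuracy$N_P) || report$accuracy$N_P == 0) {
    stop("empty prediction set: accuracy undefined", call. = FALSE)
  }
  payload <- list(
    strategy = report$strategy,
    accuracy = report$accuracy$accuracy,
    N_C = report$accuracy$N_C,
    N_P = report$accuracy$N_P,
    confusion = list(classes = rownames(report$confusion),
                     counts = unclass(report$confusion)),
    submodel_LVs = as.list(report$submodel_LVs),
    average_LVs = report$average_LVs,
    submodel_ermccv = as.list(report$submodel_ermccv),
    outlier_ids = report$outlier_ids,
    split_summary = report$split_summary,
    importance = report$importance,
    seeds = report$seeds
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  txt <- sub("\\.[A-Za-z0-9]+$", "", path)
  txt <- paste0(txt, ".txt")
  lines <- c(
    sprintf("strategy: %s", toupper(report$strategy)),
    sprintf("accuracy: %.3f (%d / %d)", report$accuracy$accuracy,
            report$accuracy$N_C, report$accuracy$N_P),
    sprintf("average LVs: %.2f", report$average_LVs),
    sprintf("outliers removed: %s",
            if (length(report$outlier_ids))
              paste(report$outlier_ids, collapse = ", ") else "none"),
    "", "confusion matrix (rows = true, cols = predicted):",
    utils::capture.output(print(report$confusion)),
    "", "per-class split:",
    utils::capture.output(print(report$split_summary, row.names = FALSE)),
    "", "element importance (first-LV loadings, max-normalized):",
    utils::capture.output(print(report$importance, row.names = FALSE))
  )
  writeLines(lines, txt)
  invisible(path)
}

#' Read back a serialized pipeline report
#'
#' @param path JSON path written by [write_report()].
#' @return list mirroring the JSON payload, with the confusion matrix
#'   restored as a named matrix.
#' @export
read_report <- function(path) {
  payload <- jsonlite::fromJSON(path)
  cm <- payload$confusion$counts
  if (!is.null(cm)) {
    cm <- as.matrix(cm)
    dimnames(cm) <- list(true = payload$confusion$classes,
                         predicted = payload$confusion$classes)
    payload$confusion <- cm
  }
  payload
}
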