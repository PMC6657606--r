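#' Element concentration panel
#'
#' An `element_panel` bundles a samples-by-elements concentration matrix
#' (micrograms per gram) with per-sample origin labels. It is the common
#' currency of the pipeline: outlier screening, splitting, scaling and
#' classification all consume and return panels.
#'
#' Invariants enforced at construction: no missing values, no negative
#' concentrations, unique element names, one label per sample.
#'
#' @param X numeric matrix, n samples x p elements.
#' @param labels origin class per sample; coerced to a factor whose levels
#'   follow first appearance order (kept stable so downstream class ordering
#'   is reproducible).
#' @param samples optional character vector of sample ids; defaults to
#'   `sample_<row>` when absent.
#' @param elements optional element names; defaults to `colnames(X)`.
#'
#' @return An object of class `element_panel`: a list with components
#'   `X` (named matrix), `samples`, `elements`, `labels`.
#' @examples
#' pan <- element_panel(matrix(1:6, 3, 2), labels = c("a", "a", "b"),
#'                      elements = c("Zn", "Fe"))
#' n_samples(pan)
#' @export
element_panel <- function(X, labels, samples = NULL, elements = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- nrow(X)
  p <- ncol(X)
  elements <- elements %||% colnames(X) %||% paste0("element_", seq_len(p))
  elements <- as.character(elements)
  if (length(elements) != p) {
    stop(sprintf("%d element names for %d columns", length(elements), p),
         call. = FALSE)
  }
  if (anyDuplicated(elements)) {
    stop("element names must be unique: ",
         paste(unique(elements[duplicated(elements)]), collapse = ", "),
         call. = FALSE)
  }
  samples <- samples %||% rownames(X) %||% paste0("sample_", seq_len(n))
  samples <- as.character(samples)
  if (length(samples) != n) {
    stop(sprintf("%d sample ids for %d rows", length(samples), n),
         call. = FALSE)
  }
  if (length(labels) != n) {
    stop(sprintf("%d labels for %d samples", length(labels), n),
         call. = FALSE)
  }
  if (!is.factor(labels)) labels <- factor(labels, levels = unique(labels))
  labels <- droplevels(labels)
  bad <- which(!is.finite(X), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("missing or non-finite concentration at sample '%s', element '%s'",
                 samples[bad[1, 1]], elements[bad[1, 2]]), call. = FALSE)
  }
  neg <- which(X < 0, arr.ind = TRUE)
  if (nrow(neg)) {
    stop(sprintf("negative concentration at sample '%s', element '%s'",
                 samples[neg[1, 1]], elements[neg[1, 2]]), call. = FALSE)
  }
  dimnames(X) <- list(samples, elements)
  structure(list(X = X, samples = samples, elements = elements,
                 labels = labels),
            class = "element_panel")
}

#' @export
print.element_panel <- function(x, ...) {
  cat(sprintf("element_panel: %d samples x %d elements, %d classes\n",
              nrow(x$X), ncol(x$X), nlevels(x$labels)))
  tab <- table(x$labels)
  cat("  classes:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' Number of samples / elements in a panel
#' @param panel an `element_panel`.
#' @return integer count.
#' @export
n_samples <- function(panel) nrow(panel$X)

#' @rdname n_samples
#' @export
n_elements <- function(panel) ncol(panel$X)

#' Subset a panel by sample index
#'
#' @param panel an `element_panel`.
#' @param idx integer or logical index over samples.
#' @return the reduced `element_panel`; row order follows `idx`.
#' @export
subset_panel <- function(panel, idx) {
  element_panel(panel$X[idx, , drop = FALSE],
                labels = panel$labels[idx],
                samples = panel$samples[idx],
                elements = panel$elements)
}

#' Read an element panel from delimited text
#'
#' Reads a comma-separated file with a header row: one numeric column per
#' element, a categorical label column, and optionally a sample-id column.
#' All non-label, non-id columns must be numeric, non-missing and
#' non-negative; violations are reported with the offending row and column.
#'
#' @param path path to a CSV file.
#' @param label_column name of the origin label column (default `"origin"`).
#' @param id_column optional name of a sample-id column; when absent ids are
#'   synthesized from row numbers.
#' @return an [element_panel()].
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(Zn = c(1, 2), Fe = c(3, 4), origin = c("a", "b")),
#'           f, row.names = FALSE)
#' read_panel(f)
#' @export
read_panel <- function(path, label_column = "origin", id_column = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, sep = ",", header = TRUE,
                          na.strings = c("", "NA"), data.table = FALSE)
  if (!label_column %in% names(dt)) {
    stop(sprintf("label column '%s' not found in %s", label_column, path),
         call. = FALSE)
  }
  labels <- as.character(dt[[label_column]])
  samples <- NULL
  if (!is.null(id_column)) {
    if (!id_column %in% names(dt)) {
      stop(sprintf("id column '%s' not found in %s", id_column, path),
           call. = FALSE)
    }
    samples <- as.character(dt[[id_column]])
  }
  keep <- setdiff(names(dt), c(label_column, id_column))
  if (!length(keep)) stop("no element columns found", call. = FALSE)
  for (cl in keep) {
    v <- dt[[cl]]
    if (!is.numeric(v)) {
      stop(sprintf("column '%s' is not numeric", cl), call. = FALSE)
    }
    if (anyNA(v)) {
      stop(sprintf("missing value in column '%s', row %d", cl, which(is.na(v))[1]),
           call. = FALSE)
    }
  }
  X <- as.matrix(dt[keep])
  element_panel(X, labels = labels, samples = samples, elements = keep)
}

#' Write an element panel to CSV
#'
#' Concentrations are serialized with 17 significant digits so that a
#' read/write/read round trip reproduces the matrix bit-exactly.
#'
#' @param panel an `element_panel`.
#' @param path output CSV path.
#' @param label_column,id_column column names used in the output file.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path, label_column = "origin",
                        id_column = "sample") {
  stopifnot(inherits(panel, "element_panel"))
  out <- data.table::as.data.table(
    lapply(seq_along(panel$elements), function(j) {
      sub("^\\s+", "", formatC(panel$X[, j], format = "g", digits = 17))
    }))
  data.table::setnames(out, panel$elements)
  out[[id_column]] <- panel$samples
  out[[label_column]] <- as.character(panel$labels)
  data.table::setcolorder(out, c(id_column, panel$elements, label_column))
  data.table::fwrite(out, path, sep = ",")
  invisible(path)
}
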