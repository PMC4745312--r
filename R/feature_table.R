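#' Feature table: objects x named features with optional class labels
#'
#' The common currency between the feature-extraction, feature-selection and
#' classification stages: a numeric matrix with one row per object and one
#' column per named feature, an optional factor of suitability labels, and a
#' provenance string recording how the values were produced.
#'
#' @param values numeric matrix, one row per object; must have unique,
#'   non-empty column names and finite values.
#' @param labels optional character/factor of length `nrow(values)` with
#'   levels `suitable`/`unsuitable`.
#' @param object_ids optional vector of object identifiers.
#' @param provenance optional free-form string (e.g. a config hash).
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(values, labels = NULL, object_ids = NULL,
                          provenance = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(colnames(values)) || anyDuplicated(colnames(values)) ||
      any(!nzchar(colnames(values))))
    stopf("feature columns must have unique non-empty names")
  if (any(!is.finite(values)))
    stopf("feature values must all be finite")
  if (!is.null(labels)) {
    labels <- factor(as.character(labels), levels = c("suitable", "unsuitable"))
    if (anyNA(labels))
      stopf("labels must be 'suitable' or 'unsuitable'")
    if (length(labels) != nrow(values))
      stopf("labels length (%d) != number of objects (%d)",
            length(labels), nrow(values))
  }
  if (is.null(object_ids)) object_ids <- seq_len(nrow(values))
  structure(list(values = values, labels = labels, object_ids = object_ids,
                 provenance = provenance),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d objects x %d features\n",
              nrow(x$values), ncol(x$values)))
  if (!is.null(x$labels)) {
    tb <- table(x$labels)
    cat(sprintf("  labels: %s\n",
                paste(sprintf("%s=%d", names(tb), tb), collapse = ", ")))
  }
  cat("  features:", paste(head(colnames(x$values), 8), collapse = ", "),
      if (ncol(x$values) > 8) "...", "\n")
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

#' @export
as.data.frame.feature_table <- function(x, ...) {
  df <- data.frame(object_id = x$object_ids, x$values,
                   check.names = FALSE, row.names = NULL)
  if (!is.null(x$labels)) df$label <- as.character(x$labels)
  df
}

#' Subset a feature table by rows and/or feature names
#'
#' @param x a [feature_table()].
#' @param rows row indices (default all).
#' @param features character vector of feature names (default all).
#' @return A `feature_table`.
#' @export
subset_features <- function(x, rows = NULL, features = NULL) {
  stopifnot(inherits(x, "feature_table"))
  if (is.null(rows)) rows <- seq_len(nrow(x$values))
  if (is.null(features)) features <- colnames(x$values)
  missing <- setdiff(features, colnames(x$values))
  if (length(missing))
    stopf("unknown features: %s", paste(missing, collapse = ", "))
  feature_table(x$values[rows, features, drop = FALSE],
                labels = if (!is.null(x$labels)) x$labels[rows],
                object_ids = x$object_ids[rows],
                provenance = x$provenance)
}

#' Write / read a feature table as CSV
#'
#' The CSV has an `object_id` column, one column per feature, and (if labels
#' are present) a trailing `label` column; a lossless round-trip format.
#'
#' @param x a [feature_table()].
#' @param path file path.
#' @return `write_feature_csv` returns `path` invisibly; `read_feature_csv`
#'   returns a `feature_table`.
#' @export
write_feature_csv <- function(x, path) {
  stopifnot(inherits(x, "feature_table"))
  write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  if (!"object_id" %in% names(df)) stopf("missing 'object_id' column")
  labels <- if ("label" %in% names(df)) df$label
  feat <- setdiff(names(df), c("object_id", "label"))
  feature_table(as.matrix(df[feat]), labels = labels,
                object_ids = df$object_id)
}
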