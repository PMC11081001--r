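# CSV interchange for feature matrices, selection masks and score tables.

#' Read / write labeled feature matrices as CSV
#'
#' One row per sample, numeric feature columns, labels in a `label` column,
#' header row included.
#'
#' @param x A [feature_matrix()].
#' @param path File path.
#' @param label_col Name of the label column; default `"label"`.
#' @return `write_feature_matrix` returns `path` invisibly;
#'   `read_feature_matrix` returns a [feature_matrix()].
#' @export
write_feature_matrix <- function(x, path, label_col = "label") {
  if (!inherits(x, "feature_matrix")) stopf("`x` must be a feature_matrix")
  df <- as.data.frame(x$values)
  names(df) <- x$feature_ids
  df[[label_col]] <- x$labels
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path, label_col = "label") {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!label_col %in% names(df)) stopf("no `%s` column in %s", label_col, path)
  labels <- df[[label_col]]
  df[[label_col]] <- NULL
  feature_matrix(as.matrix(df), labels, feature_ids = names(df))
}

#' Read / write selection masks as one-column 0/1 CSV
#'
#' @param mask Logical vector.
#' @param path File path.
#' @return `write_mask` returns `path` invisibly; `read_mask` returns a
#'   logical vector.
#' @export
write_mask <- function(mask, path) {
  utils::write.csv(data.frame(selected = as.integer(mask)), path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  utils::read.csv(path)$selected > 0
}
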