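#' Labeled feature dataset for two-class resampling
#'
#' Container for a numeric feature matrix with binary labels, the unit every
#' resampler consumes and produces. By convention label `1` is the positive /
#' minority class (seizure) and label `0` the negative / majority class
#' (nonseizure).
#'
#' @param X numeric matrix, rows = samples, columns = features.
#' @param y binary label vector (0/1), length `nrow(X)`.
#' @return an object of class `labeled_dataset` with elements `X` and `y`.
#' @examples
#' d <- labeled_dataset(matrix(rnorm(20), 10, 2), rep(c(0, 1), 5))
#' minority_indices(d)
#' @export
labeled_dataset <- function(X, y) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.integer(y)
  assert_that(nrow(X) >= 2L, "a labeled_dataset needs at least 2 samples")
  assert_that(length(y) == nrow(X), "length(y) must equal nrow(X)")
  assert_that(all(y %in% c(0L, 1L)), "labels must be 0 (majority) or 1 (minority)")
  assert_that(all(is.finite(X)), "X must not contain NA/NaN/Inf")
  if (is.null(colnames(X))) {
    colnames(X) <- paste0("feature_", seq_len(ncol(X)) - 1L)
  }
  structure(list(X = X, y = y), class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf(
    "<labeled_dataset> %d samples x %d features | minority (1): %d, majority (0): %d\n",
    nrow(x$X), ncol(x$X), sum(x$y == 1L), sum(x$y == 0L)
  ))
  invisible(x)
}

#' @rdname labeled_dataset
#' @param data a `labeled_dataset`.
#' @export
minority_indices <- function(data) which(data$y == 1L)

#' @rdname labeled_dataset
#' @export
majority_indices <- function(data) which(data$y == 0L)

#' Read / write a labeled dataset as delimited text
#'
#' The on-disk layout is one row per sample with feature columns
#' `feature_0 .. feature_{d-1}` followed by a `label` column, either
#' comma-separated (`.csv`) or tab-separated (anything else).
#'
#' @param path file path; extension `.csv` selects comma separation.
#' @return `read_dataset()` returns a `labeled_dataset`;
#'   `write_dataset()` returns `path` invisibly.
#' @export
read_dataset <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE)
  assert_that("label" %in% names(df), "dataset file must have a 'label' column")
  y <- df[["label"]]
  X <- as.matrix(df[setdiff(names(df), "label")])
  labeled_dataset(X, y)
}

#' @rdname read_dataset
#' @param data a `labeled_dataset`.
#' @export
write_dataset <- function(data, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- as.data.frame(data$X)
  df$label <- data$y
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
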