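#' Exact k-nearest-neighbour search
#'
#' Shared kNN backend for all resamplers. Neighbours are exact (full distance
#' evaluation, no approximation) and ties are broken deterministically by the
#' lower reference row index, so results are reproducible across platforms.
#'
#' When `X_query` is `NULL` the query set is the reference set and each point
#' is excluded from its own neighbour list.
#'
#' @param X_ref numeric matrix of reference points (rows = points).
#' @param X_query numeric matrix of query points, or `NULL` for a
#'   self-query with self-exclusion.
#' @param k number of neighbours; must be smaller than the number of
#'   available references (`nrow(X_ref) - 1` for a self-query).
#' @param metric distance metric; only `"euclidean"` is supported.
#' @return a `neighbor_table`: list with integer matrix `indices`
#'   (`n_query x k`, row indices into `X_ref`) and numeric matrix
#'   `distances`, each row sorted by ascending distance.
#' @examples
#' X <- matrix(c(0, 0, 1, 0, 5, 0), ncol = 2, byrow = TRUE)
#' compute_neighbors(X, k = 1)$indices
#' @export
compute_neighbors <- function(X_ref, X_query = NULL, k, metric = "euclidean") {
  X_ref <- as.matrix(X_ref)
  metric <- match.arg(metric, "euclidean")
  self_query <- is.null(X_query)
  Xq <- if (self_query) X_ref else as.matrix(X_query)
  assert_that(ncol(Xq) == ncol(X_ref), "query and reference dimensionality differ")
  n_avail <- nrow(X_ref) - if (self_query) 1L else 0L
  assert_that(is_count(k) && k >= 1L, "k must be a positive integer")
  if (k > n_avail) {
    stop(sprintf("k = %d but only %d reference points are available", k, n_avail),
         call. = FALSE)
  }

  n_q <- nrow(Xq)
  idx <- matrix(NA_integer_, n_q, k)
  dst <- matrix(NA_real_, n_q, k)
  tX <- t(X_ref)
  for (i in seq_len(n_q)) {
    d2 <- colSums((tX - Xq[i, ])^2)
    if (self_query) d2[i] <- Inf
    # order() is stable on the index tie-break vector
    o <- order(d2, seq_along(d2))[seq_len(k)]
    idx[i, ] <- o
    dst[i, ] <- sqrt(d2[o])
  }
  structure(list(indices = idx, distances = dst, k = k, metric = metric),
            class = "neighbor_table")
}

#' @export
print.neighbor_table <- function(x, ...) {
  cat(sprintf("<neighbor_table> %d queries, k = %d (%s)\n",
              nrow(x$indices), x$k, x$metric))
  invisible(x)
}
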