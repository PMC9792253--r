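#' Configuration for the resamplers
#'
#' Bundles the neighbourhood sizes and synthesis parameters shared by all
#' five resamplers. The neighbourhood sizes default to 5, the usual choice in
#' the SMOTE family.
#'
#' @param k_noise neighbours for the noise test: a minority sample whose
#'   `k_noise` nearest neighbours are all majority is treated as noise.
#' @param k_boundary neighbours for the boundary-majority test.
#' @param k_danger neighbours for danger-set membership (and the size of the
#'   minority neighbour pool in SMOTE-style partner selection).
#' @param target_ratio desired minority/majority count ratio after
#'   resampling, in (0, 1]. Default 1 (fully balanced training set).
#' @param metric distance metric, currently `"euclidean"`. Features are used
#'   as given; any scaling is the caller's responsibility.
#' @param seed integer seed making every resampling run replayable; `NULL`
#'   uses the ambient RNG stream.
#' @param keep_noise if `TRUE`, noise-flagged minority rows are retained in
#'   the output dataset (they are never used as synthesis parents either
#'   way). Default `FALSE`: noise rows are filtered out.
#' @param partner_mode how BNNSMOTE picks the interpolation partner:
#'   `"uniform"` (default) draws uniformly from all clean minority samples,
#'   `"knn"` restricts to the parent's `k_danger` minority nearest
#'   neighbours as in classic SMOTE.
#' @return an object of class `resample_config`.
#' @export
resample_config <- function(k_noise = 5L, k_boundary = 5L, k_danger = 5L,
                            target_ratio = 1.0, metric = "euclidean",
                            seed = NULL, keep_noise = FALSE,
                            partner_mode = c("uniform", "knn")) {
  partner_mode <- match.arg(partner_mode)
  metric <- match.arg(metric, "euclidean")
  for (k in list(k_noise, k_boundary, k_danger)) {
    assert_that(is_count(k) && k >= 1L, "all neighbourhood sizes k must be >= 1")
  }
  assert_that(is_scalar_num(target_ratio) && target_ratio > 0 && target_ratio <= 1,
              "target_ratio must lie in (0, 1]")
  if (!is.null(seed)) assert_that(is_count(seed), "seed must be an integer")
  structure(list(
    k_noise = as.integer(k_noise), k_boundary = as.integer(k_boundary),
    k_danger = as.integer(k_danger), target_ratio = target_ratio,
    metric = metric, seed = if (is.null(seed)) NULL else as.integer(seed),
    keep_noise = isTRUE(keep_noise), partner_mode = partner_mode
  ), class = "resample_config")
}

#' @export
print.resample_config <- function(x, ...) {
  cat(sprintf(
    "<resample_config> k_noise=%d k_boundary=%d k_danger=%d target_ratio=%g metric=%s seed=%s\n",
    x$k_noise, x$k_boundary, x$k_danger, x$target_ratio, x$metric,
    if (is.null(x$seed)) "NULL" else x$seed
  ))
  invisible(x)
}

# ---- internal machinery shared by the resamplers ------------------------

empty_provenance <- function() {
  data.frame(parent = integer(0), partner = integer(0), delta = numeric(0))
}

new_resample_result <- function(dataset, n_synth, noise_indices, danger_indices,
                                provenance, method, config) {
  structure(list(
    dataset = dataset, n_synth = as.integer(n_synth),
    noise_indices = as.integer(noise_indices),
    danger_indices = as.integer(danger_indices),
    provenance = provenance, method = method, config = config
  ), class = "resample_result")
}

#' @export
print.resample_result <- function(x, ...) {
  cat(sprintf(
    "<resample_result:%s> %d synthetic rows | %d noise, %d danger | output: %d minority vs %d majority\n",
    x$method, x$n_synth, length(x$noise_indices), length(x$danger_indices),
    sum(x$dataset$y == 1L), sum(x$dataset$y == 0L)
  ))
  invisible(x)
}

# No-op result (balanced input, inverted imbalance, empty danger set ...):
# dataset passes through unchanged apart from optional noise removal.
noop_result <- function(data, method, config, noise_indices = integer(0),
                        danger_indices = integer(0), drop_noise = FALSE) {
  out <- data
  if (drop_noise && length(noise_indices)) {
    keep <- setdiff(seq_len(nrow(data$X)), noise_indices)
    out <- labeled_dataset(data$X[keep, , drop = FALSE], data$y[keep])
  }
  new_resample_result(out, 0L, noise_indices, danger_indices,
                      empty_provenance(), method, config)
}

# Number of synthetic rows needed to reach target_ratio given the number of
# minority rows that will be retained in the output.
n_synth_needed <- function(n_minority_retained, n_majority, target_ratio) {
  max(0L, as.integer(round(target_ratio * n_majority)) - n_minority_retained)
}

# Guard shared by every resampler: returns NULL when resampling should
# proceed, otherwise a ready-made no-op result (with a warning where the
# contract calls for one).
resample_guard <- function(data, cfg, method) {
  assert_that(inherits(data, "labeled_dataset"), "data must be a labeled_dataset")
  n_min <- sum(data$y == 1L)
  n_maj <- sum(data$y == 0L)
  assert_that(n_min > 0L && n_maj > 0L,
              "both classes must be present before resampling")
  if (n_min > n_maj) {
    warning(sprintf("%s: minority count (%d) exceeds majority count (%d); no-op",
                    method, n_min, n_maj), call. = FALSE)
    return(noop_result(data, method, cfg))
  }
  if (n_min >= round(cfg$target_ratio * n_maj)) {
    # already at (or beyond) the requested balance
    return(noop_result(data, method, cfg))
  }
  NULL
}

# Append synthetic minority rows to a dataset.
bind_synthetic <- function(data, keep_rows, X_synth) {
  X <- data$X[keep_rows, , drop = FALSE]
  y <- data$y[keep_rows]
  if (nrow(X_synth)) {
    colnames(X_synth) <- colnames(data$X)
    X <- rbind(X, X_synth)
    y <- c(y, rep(1L, nrow(X_synth)))
  }
  labeled_dataset(X, y)
}

#' Export synthesis provenance as JSON lines
#'
#' Writes one JSON record per synthetic row with its parent index, partner
#' index and interpolation coefficient `delta` (indices refer to rows of the
#' dataset that was resampled).
#'
#' @param result a `resample_result`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_provenance <- function(result, path) {
  assert_that(inherits(result, "resample_result"), "need a resample_result")
  con <- file(path, open = "wt")
  on.exit(close(con))
  p <- result$provenance
  if (nrow(p)) {
    for (i in seq_len(nrow(p))) {
      writeLines(jsonlite::toJSON(
        list(row = i, parent = p$parent[i], partner = p$partner[i],
             delta = p$delta[i]),
        auto_unbox = TRUE, digits = NA), con)
    }
  }
  invisible(path)
}
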