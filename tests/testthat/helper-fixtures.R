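# Fixtures built in code; no data files.

# A small architecture exercising every op kind: strided initial conv,
# non-expanding bottleneck, expanding strided stage with a residual
# repetition, pointwise head, pooling, linear classifier.
tiny_model_spec <- function(input_length = 16L) {
  layers <- rbind(
    bnnsmote:::spec_row("conv1d", c = 4, s = 2, kernel = 3),
    bnnsmote:::spec_row("bottleneck", t = 1, c = 4, n = 1, s = 1, kernel = 3),
    bnnsmote:::spec_row("bottleneck", t = 6, c = 6, n = 2, s = 2, kernel = 3),
    bnnsmote:::spec_row("pointwise_conv", c = 8, s = 1, kernel = 1),
    bnnsmote:::spec_row("avgpool"),
    bnnsmote:::spec_row("linear", c = 2)
  )
  model_spec(layers, input_length = input_length, input_channels = 1L,
             num_classes = 2L)
}

# Linearly separable labeled windows: class 1 carries a strong oscillation
# on top of unit noise, class 0 is pure noise.
make_separable_segs <- function(n = 200L, len = 64L, fs = 64, gain = 3,
                                seed = 1L) {
  set.seed(seed)
  y <- rep(c(0L, 1L), length.out = n)
  segs <- array(stats::rnorm(n * len), c(n, 1L, len))
  tt <- seq_len(len) / fs
  for (i in which(y == 1L)) {
    segs[i, 1L, ] <- segs[i, 1L, ] +
      gain * sin(2 * pi * 6 * tt + stats::runif(1, 0, 2 * pi))
  }
  structure(list(segments = segs, labels = y, offsets = seq_len(n) - 1,
                 window_s = len / fs, step_s = len / fs, fs = fs,
                 channel_names = "CH1"), class = "segment_set")
}

# Minimal segment_set wrapper around a plain feature array (one channel).
segs_from_matrix <- function(X, labels, fs = 1) {
  n <- nrow(X); len <- ncol(X)
  structure(list(segments = array(X, c(n, 1L, len)), labels = as.integer(labels),
                 offsets = seq_len(n) - 1, window_s = len / fs, step_s = len / fs,
                 fs = fs, channel_names = "CH1"), class = "segment_set")
}

# Brute-force kNN oracle: full pairwise distances, stable sort, ties by
# lower reference index. Intentionally independent of compute_neighbors().
brute_knn <- function(X_ref, X_query = NULL, k) {
  self <- is.null(X_query)
  Xq <- if (self) X_ref else X_query
  idx <- matrix(NA_integer_, nrow(Xq), k)
  dst <- matrix(NA_real_, nrow(Xq), k)
  for (i in seq_len(nrow(Xq))) {
    d <- sqrt(rowSums(sweep(X_ref, 2, Xq[i, ])^2))
    if (self) d[i] <- Inf
    o <- order(d, seq_along(d))
    idx[i, ] <- o[seq_len(k)]
    dst[i, ] <- d[o[seq_len(k)]]
  }
  list(indices = idx, distances = dst)
}

expect_balanced <- function(result, target_ratio = 1) {
  n1 <- sum(result$dataset$y == 1L)
  n0 <- sum(result$dataset$y == 0L)
  expect_equal(n1, round(target_ratio * n0))
}
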