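#' Butterworth bandpass filtering
#'
#' Filters every channel with a Butterworth bandpass (default 0.5–50 Hz, the
#' standard EEG denoising band), applied forward and backward
#' (zero-phase, which doubles the effective order). Metadata is preserved.
#'
#' @param record an [eeg_record()].
#' @param low_hz lower passband edge (Hz).
#' @param high_hz upper passband edge (Hz); must be below the Nyquist
#'   frequency `fs / 2`.
#' @param order filter order of the underlying one-pass design (default 4).
#' @return the filtered [eeg_record()].
#' @export
bandpass <- function(record, low_hz = 0.5, high_hz = 50, order = 4L) {
  assert_that(inherits(record, "eeg_record"), "record must be an eeg_record")
  nyq <- record$fs / 2
  assert_that(low_hz > 0 && low_hz < high_hz,
              "need 0 < low_hz < high_hz")
  if (high_hz >= nyq) {
    stop(sprintf("high_hz (%g) must be below the Nyquist frequency (%g)",
                 high_hz, nyq), call. = FALSE)
  }
  bf <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  n <- ncol(record$data)
  # demean (DC carries no EEG information and lies below the passband) and
  # extend with odd reflections so the zero-phase pass sees no edge steps;
  # pad covers ~3 periods of the lowest passband frequency
  p <- min(n - 1L, as.integer(ceiling(3 * record$fs / low_hz)))
  filtered <- t(apply(record$data, 1L, function(ch) {
    x <- ch - mean(ch)
    xp <- c(2 * x[1] - rev(x[2:(p + 1L)]), x,
            2 * x[n] - rev(x[(n - p):(n - 1L)]))
    signal::filtfilt(bf, xp)[(p + 1L):(p + n)]
  }))
  eeg_record(filtered, record$fs, record$channel_names,
             record$seizure_intervals)
}

#' Sliding-window segmentation
#'
#' Cuts a record into fixed-length windows (default 4 s with a 2 s step, so
#' that at 256 Hz each segment holds 1024 samples) and labels each window
#' ictal or nonictal from the record's seizure annotations.
#'
#' Label rules: `"majority-overlap"` (default) marks a window ictal when at
#' least half of it lies inside a seizure interval; `"any-overlap"` when any
#' part does; `"full-containment"` only when the whole window does.
#'
#' @param record an [eeg_record()].
#' @param window_s window length in seconds.
#' @param step_s step between window starts in seconds.
#' @param label_rule one of `"majority-overlap"`, `"any-overlap"`,
#'   `"full-containment"`.
#' @return a `segment_set`: list with `segments` (array
#'   `n_segments x n_channels x window_samples`), `labels` (1 = ictal),
#'   `offsets` (window start times, s), `window_s`, `step_s`, `fs` and
#'   `channel_names`.
#' @export
segment <- function(record, window_s = 4, step_s = 2,
                    label_rule = c("majority-overlap", "any-overlap",
                                   "full-containment")) {
  assert_that(inherits(record, "eeg_record"), "record must be an eeg_record")
  label_rule <- match.arg(label_rule)
  fs <- record$fs
  duration <- ncol(record$data) / fs
  if (duration < window_s) {
    stop(sprintf("record too short to segment: %.2f s < window of %.2f s",
                 duration, window_s), call. = FALSE)
  }
  win <- as.integer(round(window_s * fs))
  n_seg <- as.integer(floor((duration - window_s) / step_s) + 1)
  offsets <- (seq_len(n_seg) - 1) * step_s

  segs <- array(NA_real_, dim = c(n_seg, nrow(record$data), win))
  for (i in seq_len(n_seg)) {
    s0 <- as.integer(round(offsets[i] * fs))  # 0-based first sample
    segs[i, , ] <- record$data[, (s0 + 1L):(s0 + win), drop = FALSE]
  }

  iv <- record$seizure_intervals
  overlap <- vapply(offsets, function(o) {
    if (!nrow(iv)) return(0)
    sum(pmax(0, pmin(iv[, 2], o + window_s) - pmax(iv[, 1], o)))
  }, numeric(1))
  labels <- switch(label_rule,
    "majority-overlap" = as.integer(overlap >= window_s / 2),
    "any-overlap" = as.integer(overlap > 0),
    "full-containment" = as.integer(overlap >= window_s - 1e-9)
  )

  structure(list(segments = segs, labels = labels, offsets = offsets,
                 window_s = window_s, step_s = step_s, fs = fs,
                 channel_names = record$channel_names),
            class = "segment_set")
}

#' @export
print.segment_set <- function(x, ...) {
  cat(sprintf(
    "<segment_set> %d segments x %d channels x %d samples (%g s window, %g s step @ %g Hz) | ictal: %d, nonictal: %d\n",
    dim(x$segments)[1], dim(x$segments)[2], dim(x$segments)[3],
    x$window_s, x$step_s, x$fs, sum(x$labels == 1L), sum(x$labels == 0L)
  ))
  invisible(x)
}

#' Single-channel view of a segment set
#'
#' @param segs a `segment_set`.
#' @param channel channel name or index.
#' @return a `segment_set` with one channel.
#' @export
segment_channel <- function(segs, channel) {
  assert_that(inherits(segs, "segment_set"), "segs must be a segment_set")
  idx <- if (is.character(channel)) match(channel, segs$channel_names)
         else as.integer(channel)
  assert_that(!is.na(idx) && idx >= 1L && idx <= dim(segs$segments)[2],
              "unknown channel")
  out <- segs
  out$segments <- segs$segments[, idx, , drop = FALSE]
  out$channel_names <- segs$channel_names[idx]
  out
}

#' Flatten a segment set to a labeled feature dataset
#'
#' Each segment becomes one row by concatenating its channels' samples, so
#' resamplers and vector-space classifiers can operate on windows directly.
#'
#' @param segs a `segment_set`.
#' @return a [labeled_dataset()].
#' @export
segments_to_dataset <- function(segs) {
  assert_that(inherits(segs, "segment_set"), "segs must be a segment_set")
  d <- dim(segs$segments)
  X <- matrix(segs$segments, nrow = d[1])  # row-major over (channel, sample)
  labeled_dataset(X, segs$labels)
}

# Per-segment, per-channel scalar reduction used by the ANOVA screen.
segment_feature <- function(segs, feature = c("log_energy", "mean_abs",
                                              "variance")) {
  feature <- match.arg(feature)
  d <- dim(segs$segments)
  out <- matrix(NA_real_, d[1], d[2])
  for (ch in seq_len(d[2])) {
    x <- segs$segments[, ch, , drop = FALSE]
    dim(x) <- c(d[1], d[3])
    out[, ch] <- switch(feature,
      log_energy = log(rowSums(x^2) + .Machine$double.xmin),
      mean_abs = rowMeans(abs(x)),
      variance = apply(x, 1L, stats::var)
    )
  }
  colnames(out) <- segs$channel_names
  out
}

#' ANOVA-based channel screening
#'
#' For each channel, reduces every segment to a scalar feature (default: log
#' signal energy) and tests whether the ictal and nonictal groups differ with
#' a one-way two-group analysis of variance. Channels with `p < alpha` are
#' retained; for two groups the F statistic equals the square of the pooled
#' two-sample t statistic.
#'
#' @param segs a `segment_set` containing both ictal and nonictal segments.
#' @param feature scalar reduction: `"log_energy"` (default), `"mean_abs"`
#'   or `"variance"`.
#' @param alpha significance level for retention (default 0.05).
#' @return a `channel_selection`: data frame with columns `channel`,
#'   `statistic` (F), `p_value`, `retained`, and attribute `alpha`.
#' @export
anova_select <- function(segs, feature = "log_energy", alpha = 0.05) {
  assert_that(inherits(segs, "segment_set"), "segs must be a segment_set")
  g <- factor(segs$labels, levels = c(0L, 1L))
  if (length(unique(segs$labels)) < 2L) {
    stop("anova_select needs both ictal and nonictal segments", call. = FALSE)
  }
  feats <- segment_feature(segs, feature)
  res <- lapply(seq_len(ncol(feats)), function(ch) {
    ow <- stats::oneway.test(feats[, ch] ~ g, var.equal = TRUE)
    c(statistic = unname(ow$statistic), p_value = unname(ow$p.value))
  })
  res <- do.call(rbind, res)
  out <- data.frame(channel = segs$channel_names,
                    statistic = res[, "statistic"],
                    p_value = res[, "p_value"],
                    retained = res[, "p_value"] < alpha,
                    row.names = NULL)
  attr(out, "alpha") <- alpha
  attr(out, "feature") <- feature
  class(out) <- c("channel_selection", "data.frame")
  out
}
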