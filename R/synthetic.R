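# Ground-truth-bearing generators. Every generator is a pure function of
# its config (same seed -> bit-identical output) and returns any planted
# structure alongside the data -- truth is recorded, never inferred.

#' Configuration for the two-class point-cloud generator
#'
#' @param n_major number of majority (nonseizure) points.
#' @param n_minor number of minority (seizure) points; `2 <= n_minor <=
#'   n_major`.
#' @param n_features feature-space dimension.
#' @param separation distance between the class means in cluster
#'   standard-deviation units. The default 2 gives the overlapping boundary
#'   of the standard imbalanced fixture; values >= 8 give well-separated
#'   clusters with exactly recoverable planted noise.
#' @param noise_frac fraction of minority points relocated into the
#'   majority core and recorded as planted noise, in `[0, 1)`.
#' @param seed integer seed.
#' @return an object of class `cluster_config`.
#' @export
cluster_config <- function(n_major = 600L, n_minor = 20L, n_features = 2L,
                           separation = 2, noise_frac = 0, seed = 1L) {
  assert_that(is_count(n_major) && is_count(n_minor) &&
                n_major >= n_minor && n_minor >= 2L,
              "need n_major >= n_minor >= 2")
  assert_that(is_scalar_num(separation) && separation >= 0,
              "separation must be >= 0")
  assert_that(is_scalar_num(noise_frac) && noise_frac >= 0 && noise_frac < 1,
              "noise_frac must be in [0, 1)")
  structure(list(n_major = as.integer(n_major), n_minor = as.integer(n_minor),
                 n_features = as.integer(n_features), separation = separation,
                 noise_frac = noise_frac, seed = as.integer(seed)),
            class = "cluster_config")
}

# Spherical normal deviates truncated at radius 3 (redraw beyond). Bounded
# tails are what make planted ground truth exact: no legitimate cluster
# member can wander into the other class's core.
rnorm_trunc <- function(n, d, radius = 3) {
  X <- matrix(stats::rnorm(n * d), n, d)
  repeat {
    bad <- which(sqrt(rowSums(X^2)) > radius)
    if (!length(bad)) break
    X[bad, ] <- matrix(stats::rnorm(length(bad) * d), length(bad), d)
  }
  X
}

#' Generate an imbalanced two-class point cloud with planted noise
#'
#' Majority points follow a spherical normal at the origin and minority
#' points a spherical normal centred `separation` standard deviations away
#' along the first axis (both truncated at radius 3 sd). A `noise_frac`
#' fraction of minority rows is then relocated deep inside the majority
#' core — mutually spaced at least 1 sd apart so each planted point is an
#' isolated minority point by construction — and returned as ground truth.
#'
#' @param cfg a [cluster_config()].
#' @return list with `dataset` (a [labeled_dataset()]; majority rows first),
#'   `truth` (row indices of the planted noise points) and `config`.
#' @examples
#' gen <- make_clusters(cluster_config(n_major = 100, n_minor = 10,
#'                                     separation = 8, noise_frac = 0.2,
#'                                     seed = 42))
#' gen$truth
#' @export
make_clusters <- function(cfg = cluster_config()) {
  assert_that(inherits(cfg, "cluster_config"), "cfg must be a cluster_config")
  with_seed(cfg$seed, {
    d <- cfg$n_features
    X_maj <- rnorm_trunc(cfg$n_major, d)
    center <- c(cfg$separation, rep(0, d - 1L))
    X_min <- sweep(rnorm_trunc(cfg$n_minor, d), 2L, center, `+`)

    n_noise <- as.integer(round(cfg$noise_frac * cfg$n_minor))
    noise_rows_min <- integer(0)
    if (n_noise > 0L) {
      noise_rows_min <- sample.int(cfg$n_minor, n_noise)
      placed <- matrix(NA_real_, 0, d)
      for (j in seq_len(n_noise)) {
        ok <- FALSE
        for (try in seq_len(1000L)) {
          cand <- 0.5 * rnorm_trunc(1L, d)  # sd 0.5, inside the majority core
          if (!nrow(placed) ||
              min(sqrt(rowSums((placed - matrix(cand, nrow(placed), d,
                                                byrow = TRUE))^2))) >= 1) {
            ok <- TRUE; break
          }
        }
        if (!ok) stop("could not place isolated noise points; lower noise_frac",
                      call. = FALSE)
        placed <- rbind(placed, cand)
      }
      X_min[noise_rows_min, ] <- placed
    }

    X <- rbind(X_maj, X_min)
    y <- c(rep(0L, cfg$n_major), rep(1L, cfg$n_minor))
    truth <- cfg$n_major + sort(noise_rows_min)
    list(dataset = labeled_dataset(X, y), truth = as.integer(truth),
         config = cfg)
  })
}

#' Configuration for the synthetic EEG generator
#'
#' @param duration_s recording length in seconds.
#' @param fs sampling rate (Hz), default 256.
#' @param n_channels number of channels; 23 gives the standard bipolar
#'   montage labels of [chbmit_channel_names()].
#' @param seizure_intervals numeric matrix of `[start_s, end_s)` rows, or
#'   `NULL` for a seizure-free record.
#' @param affected_channels channel names receiving seizure bursts; default
#'   is every channel. Must be a subset of the montage.
#' @param burst_freq_hz spike-wave fundamental (default 3 Hz, the canonical
#'   generalized-seizure motif).
#' @param burst_gain burst amplitude as a multiple of the channel's
#'   background RMS; 0 disables bursts entirely.
#' @param background_exponent spectral exponent of the 1/f^a background.
#' @param seed integer seed.
#' @return an object of class `synth_eeg_config`.
#' @export
synth_eeg_config <- function(duration_s = 120, fs = 256, n_channels = 23L,
                             seizure_intervals = NULL,
                             affected_channels = NULL,
                             burst_freq_hz = 3, burst_gain = 3,
                             background_exponent = 1, seed = 1L) {
  assert_that(fs > 2 * burst_freq_hz, "fs must exceed twice the burst frequency")
  names <- if (n_channels == 23L) chbmit_channel_names()
           else paste0("CH", seq_len(n_channels))
  if (is.null(affected_channels)) affected_channels <- names
  assert_that(all(affected_channels %in% names),
              "affected_channels must be a subset of the montage")
  structure(list(duration_s = duration_s, fs = fs,
                 n_channels = as.integer(n_channels),
                 channel_names = names,
                 seizure_intervals = seizure_intervals,
                 affected_channels = affected_channels,
                 burst_freq_hz = burst_freq_hz, burst_gain = burst_gain,
                 background_exponent = background_exponent,
                 seed = as.integer(seed)),
            class = "synth_eeg_config")
}

# Band-limited 1/f^a background noise via spectral shaping.
one_over_f_noise <- function(n, fs, exponent) {
  spec <- stats::fft(stats::rnorm(n))
  f <- c(0, seq_len(n - 1)) * fs / n
  f <- pmin(f, fs - f)             # two-sided frequency axis
  shape <- ifelse(f > 0, f^(-exponent / 2), 0)
  x <- Re(stats::fft(spec * shape, inverse = TRUE)) / n
  x / stats::sd(x)
}

#' Generate a synthetic multichannel EEG record
#'
#' Background activity is band-limited `1/f`-type noise (30 µV RMS) per
#' channel. Inside each annotated seizure interval the affected channels
#' additionally carry a spike-wave-like oscillation: a `burst_freq_hz`
#' fundamental plus a weaker second harmonic under a raised-cosine onset /
#' offset envelope, scaled to `burst_gain` times the channel's background
#' RMS. The annotations are carried in the returned record.
#'
#' @param cfg a [synth_eeg_config()].
#' @return an [eeg_record()].
#' @export
make_eeg <- function(cfg = synth_eeg_config()) {
  assert_that(inherits(cfg, "synth_eeg_config"), "cfg must be a synth_eeg_config")
  with_seed(cfg$seed, {
    n <- as.integer(round(cfg$duration_s * cfg$fs))
    amp <- 30  # background RMS, microvolts
    data <- matrix(NA_real_, cfg$n_channels, n)
    for (ch in seq_len(cfg$n_channels)) {
      data[ch, ] <- amp * one_over_f_noise(n, cfg$fs, cfg$background_exponent)
    }

    iv <- cfg$seizure_intervals
    if (!is.null(iv) && length(iv) && cfg$burst_gain > 0) {
      iv <- matrix(as.numeric(iv), ncol = 2)
      aff <- match(cfg$affected_channels, cfg$channel_names)
      for (r in seq_len(nrow(iv))) {
        i0 <- as.integer(round(iv[r, 1] * cfg$fs)) + 1L
        i1 <- as.integer(round(iv[r, 2] * cfg$fs))
        t <- (seq(i0, i1) - i0) / cfg$fs
        len <- t[length(t)]
        ramp <- pmin(1, pmin(t, len - t) / 0.5)      # 0.5 s raised ramps
        env <- (1 - cos(pmin(ramp, 1) * pi)) / 2
        for (ch in aff) {
          ph <- stats::runif(1, 0, 2 * pi)
          wave <- sin(2 * pi * cfg$burst_freq_hz * t + ph) +
            0.5 * sin(4 * pi * cfg$burst_freq_hz * t + 2 * ph)
          data[ch, i0:i1] <- data[ch, i0:i1] +
            cfg$burst_gain * amp * env * wave / stats::sd(wave)
        }
      }
    }
    eeg_record(data, cfg$fs, cfg$channel_names,
               seizure_intervals = cfg$seizure_intervals)
  })
}

#' Generate an imbalanced labeled segment set
#'
#' Wraps [make_eeg()] and [segment()] so that the ictal:nonictal segment
#' ratio approximates `ratio` (default 1:30, the imbalance of long-term
#' scalp EEG monitoring). A single seizure interval of the right length is
#' placed on the segmentation grid; the exact achieved ratio is reported in
#' the result.
#'
#' @param ratio desired ictal/nonictal segment count ratio.
#' @param duration_s recording length (s).
#' @param n_channels number of channels (default 1: the classifier operates
#'   per channel).
#' @param window_s,step_s segmentation geometry.
#' @param fs sampling rate (Hz).
#' @param burst_gain seizure burst amplitude multiplier.
#' @param seed integer seed.
#' @return a `segment_set` with extra fields `achieved_ratio` and
#'   `target_ratio`.
#' @export
make_imbalanced_segments <- function(ratio = 1 / 30, duration_s = 512,
                                     n_channels = 1L, window_s = 4,
                                     step_s = 2, fs = 256, burst_gain = 3,
                                     seed = 1L) {
  assert_that(ratio > 0 && ratio <= 1, "ratio must be in (0, 1]")
  n_seg <- floor((duration_s - window_s) / step_s) + 1
  f_min <- ratio / (1 + ratio)
  n_ictal <- max(2L, as.integer(round(f_min * n_seg)))
  # an interval of length 2*(n_ictal - 1) on the step grid yields exactly
  # n_ictal majority-overlap ictal windows
  a <- round(duration_s / 3 / step_s) * step_s
  b <- a + step_s * (n_ictal - 1L)
  cfg <- synth_eeg_config(duration_s = duration_s, fs = fs,
                          n_channels = n_channels,
                          seizure_intervals = matrix(c(a, b), 1),
                          burst_gain = burst_gain, seed = seed)
  rec <- make_eeg(cfg)
  segs <- segment(rec, window_s = window_s, step_s = step_s)
  n1 <- sum(segs$labels == 1L); n0 <- sum(segs$labels == 0L)
  segs$achieved_ratio <- n1 / n0
  segs$target_ratio <- ratio
  segs
}
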