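# Bandpass, segmentation, ANOVA screening, channel subsetting.

make_tone <- function(freq, fs = 256, dur = 8) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  sin(2 * pi * freq * t)
}

test_that("a DC channel is annihilated by the bandpass", {
  rec <- eeg_record(matrix(5, 1, 256 * 4), fs = 256)
  out <- bandpass(rec)
  expect_lt(max(abs(out$data)), 5 * 1e-6)
})

test_that("passband and stopband tones match the analytic response", {
  fs <- 256
  bf <- signal::butter(4, c(0.5, 50) / (fs / 2), type = "pass")
  H <- function(f) {
    # analytic transfer function at one digital frequency; forward-backward
    # application squares the magnitude
    w <- 2 * pi * f / fs
    nb <- seq_along(bf$b) - 1; na <- seq_along(bf$a) - 1
    Mod(sum(bf$b * exp(-1i * w * nb)) / sum(bf$a * exp(-1i * w * na)))^2
  }
  rms_ratio <- function(f0) {
    rec <- eeg_record(matrix(make_tone(f0, fs), 1), fs = fs)
    out <- bandpass(rec)
    core <- (fs + 1):(ncol(out$data) - fs)   # trim filter edge transients
    sqrt(mean(out$data[1, core]^2) / mean(rec$data[1, core]^2))
  }
  # passband: measured attenuation matches the analytic response
  expect_equal(rms_ratio(10), H(10), tolerance = 0.02)
  expect_gt(rms_ratio(10), 0.95)
  # stopband: the analytic response (~1.5e-5) is buried under edge-padding
  # leakage, so assert the bound rather than the exact value
  expect_lt(rms_ratio(100), 0.10)
  expect_lt(H(100), 1e-4)
})

test_that("filtering is linear in the input amplitude", {
  set.seed(40)
  x <- rnorm(256 * 3)
  r1 <- bandpass(eeg_record(matrix(x, 1), 256))
  r7 <- bandpass(eeg_record(matrix(7 * x, 1), 256))
  # zero-phase filtering solves for edge initial conditions in floating
  # point, so scaling commutes to ~1e-9 of the signal scale
  expect_lt(max(abs(r7$data - 7 * r1$data)) / max(abs(r7$data)), 5e-9)
})

test_that("bandpass rejects cutoffs at or above Nyquist", {
  rec <- eeg_record(matrix(rnorm(512), 1), 256)
  expect_error(bandpass(rec, 0.5, 128), "Nyquist")
})

test_that("segment count follows the sliding-window formula", {
  rec <- eeg_record(matrix(rnorm(23 * 256 * 60), 23), 256,
                    chbmit_channel_names())
  segs <- segment(rec, 4, 2)
  expect_equal(dim(segs$segments), c(29L, 23L, 1024L))
  # partition case: step = window is lossless
  segs2 <- segment(rec, 4, 4)
  expect_equal(dim(segs2$segments)[1], 15L)
  expect_equal(as.numeric(segs2$segments[3, 5, ]),
               as.numeric(rec$data[5, (2 * 1024 + 1):(3 * 1024)]))
  expect_error(segment(eeg_record(matrix(rnorm(256), 1), 256), 4, 2),
               "too short")
})

test_that("window labels follow the majority-overlap rule", {
  rec <- eeg_record(matrix(rnorm(256 * 30), 1), 256,
                    seizure_intervals = matrix(c(10, 20), 1))
  segs <- segment(rec, 4, 2)
  ict <- segs$offsets[segs$labels == 1L]
  expect_setequal(ict, c(8, 10, 12, 14, 16, 18))  # 50% overlap at both edges
  any_ov <- segment(rec, 4, 2, label_rule = "any-overlap")
  expect_setequal(any_ov$offsets[any_ov$labels == 1L], seq(8, 18, 2))
  full <- segment(rec, 4, 2, label_rule = "full-containment")
  expect_setequal(full$offsets[full$labels == 1L], c(10, 12, 14, 16))
})

test_that("two-group F equals the squared pooled t statistic", {
  set.seed(41)
  for (i in 1:50) {
    n1 <- sample(5:20, 1); n0 <- sample(5:20, 1)
    X <- matrix(rnorm((n1 + n0) * 8), n1 + n0, 8)
    X[seq_len(n1), ] <- X[seq_len(n1), ] + runif(1, 0, 2)
    segs <- segs_from_matrix(X, c(rep(1L, n1), rep(0L, n0)))
    sel <- anova_select(segs)
    tt <- stats::t.test(
      bnnsmote:::segment_feature(segs)[segs$labels == 1L, 1],
      bnnsmote:::segment_feature(segs)[segs$labels == 0L, 1],
      var.equal = TRUE)
    expect_equal(sel$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  }
})

test_that("a five-sd energy shift is always retained", {
  set.seed(42)
  e1 <- rnorm(30); e0 <- rnorm(30) + 5
  # build windows whose log-energy reproduces these scalars
  X <- rbind(t(sapply(e1, function(e) rnorm(16) * sqrt(exp(e) / 16))),
             t(sapply(e0, function(e) rnorm(16) * sqrt(exp(e) / 16))))
  segs <- segs_from_matrix(X, c(rep(1L, 30), rep(0L, 30)))
  sel <- anova_select(segs)
  expect_true(sel$retained[1])
})

test_that("single-label segment sets are rejected", {
  segs <- segs_from_matrix(matrix(rnorm(80), 10, 8), rep(1L, 10))
  expect_error(anova_select(segs), "both ictal and nonictal")
})

test_that("channel subsetting honours names, order and errors", {
  rec <- make_eeg(synth_eeg_config(duration_s = 4, seed = 2))
  all_keep <- select_channels(rec, rec$channel_names)
  expect_equal(all_keep$data, rec$data)
  ten <- select_channels(rec, chbmit_selected_channels())
  expect_equal(ten$channel_names, chbmit_selected_channels())
  expect_equal(nrow(ten$data), 10L)
  expect_equal(unname(ten$data[1, ]), unname(rec$data[3, ]))  # T7-P7 is ch 3
  expect_error(select_channels(rec, "NOT-A-CHANNEL"), "unknown channel")
  expect_error(select_channels(rec, character(0)), "at least one")
})

test_that("channel subsetting commutes with segmentation", {
  rec <- make_eeg(synth_eeg_config(duration_s = 12, n_channels = 5, seed = 3,
                                   seizure_intervals = matrix(c(4, 8), 1)))
  keep <- c("CH4", "CH2")
  a <- segment(select_channels(rec, keep), 4, 2)
  b <- segment(rec, 4, 2)
  b_sub <- b$segments[, match(keep, rec$channel_names), , drop = FALSE]
  expect_equal(a$segments, b_sub)
  expect_equal(a$labels, b$labels)
})
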