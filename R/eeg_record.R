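#' Multichannel EEG record
#'
#' Container for a multichannel EEG recording with sampling rate, bipolar
#' montage channel names and annotated seizure intervals. All times are in
#' seconds, intervals are half-open `[start, end)` and sample indices are
#' 0-based at the interface level.
#'
#' @param data numeric matrix, `n_channels x n_samples`, in microvolts.
#' @param fs sampling rate in Hz.
#' @param channel_names character vector of unique montage labels (e.g.
#'   `"T7-P7"`), length `n_channels`.
#' @param seizure_intervals numeric matrix with columns `start_s`, `end_s`
#'   (or an empty/NULL value for a seizure-free record); intervals must be
#'   sorted, non-overlapping and lie within the recording.
#' @return an object of class `eeg_record`.
#' @export
eeg_record <- function(data, fs, channel_names = NULL, seizure_intervals = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  assert_that(is_scalar_num(fs) && fs > 0, "fs must be a positive number")
  n_ch <- nrow(data)
  if (is.null(channel_names)) channel_names <- paste0("CH", seq_len(n_ch))
  assert_that(length(channel_names) == n_ch,
              "channel_names must have one entry per channel")
  assert_that(!anyDuplicated(channel_names), "channel names must be unique")
  dur <- ncol(data) / fs
  if (is.null(seizure_intervals) || length(seizure_intervals) == 0L) {
    seizure_intervals <- matrix(numeric(0), 0, 2)
  } else {
    seizure_intervals <- matrix(as.numeric(seizure_intervals), ncol = 2)
  }
  colnames(seizure_intervals) <- c("start_s", "end_s")
  if (nrow(seizure_intervals)) {
    assert_that(all(seizure_intervals[, 1] < seizure_intervals[, 2]),
                "seizure intervals must have start < end")
    assert_that(all(seizure_intervals >= 0) && all(seizure_intervals[, 2] <= dur),
                "seizure intervals must lie within the recording")
    if (nrow(seizure_intervals) > 1L) {
      o <- order(seizure_intervals[, 1])
      assert_that(identical(o, seq_len(nrow(seizure_intervals))) &&
                    all(seizure_intervals[-nrow(seizure_intervals), 2] <=
                          seizure_intervals[-1, 1]),
                  "seizure intervals must be sorted and non-overlapping")
    }
  }
  rownames(data) <- channel_names
  structure(list(data = data, fs = fs, channel_names = channel_names,
                 seizure_intervals = seizure_intervals),
            class = "eeg_record")
}

#' @export
print.eeg_record <- function(x, ...) {
  cat(sprintf(
    "<eeg_record> %d channels x %d samples @ %g Hz (%.1f s), %d seizure interval(s)\n",
    nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs,
    nrow(x$seizure_intervals)
  ))
  invisible(x)
}

#' Subset an EEG record by channel name
#'
#' Returns a record containing only the requested channels, in the order
#' given. The ten-channel montage of the reference channel selection can be
#' obtained with [chbmit_selected_channels()].
#'
#' @param record an [eeg_record()].
#' @param keep character vector of channel names to retain, in output order.
#' @return an [eeg_record()] with `length(keep)` channels.
#' @export
select_channels <- function(record, keep) {
  assert_that(inherits(record, "eeg_record"), "record must be an eeg_record")
  assert_that(length(keep) > 0L, "keep must name at least one channel")
  unknown <- setdiff(keep, record$channel_names)
  if (length(unknown)) {
    stop("unknown channel name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  rows <- match(keep, record$channel_names)
  eeg_record(record$data[rows, , drop = FALSE], record$fs,
             channel_names = keep,
             seizure_intervals = record$seizure_intervals)
}

#' Standard bipolar montage labels
#'
#' `chbmit_channel_names()` returns the 23-label bipolar longitudinal
#' montage used by the CHB-MIT scalp recordings (the montage repeats
#' "T8-P8"; the second occurrence is disambiguated as `"T8-P8-2"` so labels
#' stay unique). `chbmit_selected_channels()` returns the ten channels
#' retained by the ANOVA-based channel screening (channels 3, 4, 7, 8, 13,
#' 14, 15, 16, 20 and 22 of that montage).
#'
#' @return character vector of channel labels.
#' @export
chbmit_channel_names <- function() {
  c("FP1-F7", "F7-T7", "T7-P7", "P7-O1",
    "FP1-F3", "F3-C3", "C3-P3", "P3-O1",
    "FP2-F4", "F4-C4", "C4-P4", "P4-O2",
    "FP2-F8", "F8-T8", "T8-P8", "P8-O2",
    "FZ-CZ", "CZ-PZ", "P7-T7", "T7-FT9",
    "FT9-FT10", "FT10-T8", "T8-P8-2")
}

#' @rdname chbmit_channel_names
#' @export
chbmit_selected_channels <- function() {
  chbmit_channel_names()[c(3L, 4L, 7L, 8L, 13L, 14L, 15L, 16L, 20L, 22L)]
}
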