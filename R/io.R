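# File formats: a minimal EDF (European Data Format) codec for multichannel
# signals (ASCII headers + 16-bit little-endian samples, the dialect used
# by scalp-EEG archives: identical sampling rate on every channel),
# a TSV reader for seizure annotations, and RDS round-trips for segment
# sets. Annotations travel in a sidecar TSV rather than EDF+ events.

pad_field <- function(x, width) {
  s <- formatC(as.character(x), width = -width)
  substr(s, 1L, width)
}

num_field <- function(x, width) {
  s <- formatC(x, format = "g", digits = 8, width = -width)
  if (nchar(s) > width) s <- substr(formatC(x, format = "g", digits = 4), 1, width)
  pad_field(s, width)
}

#' Write an EEG record to an EDF file
#'
#' Signals are quantised to 16-bit integers over each channel's observed
#' physical range (one-second data records). Seizure annotations are not
#' stored in the EDF; keep them in a sidecar TSV (see
#' [read_annotations()]). Recordings are zero-padded to a whole number of
#' one-second records.
#'
#' @param record an [eeg_record()]; `fs` must be a positive integer.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_edf <- function(record, path) {
  assert_that(inherits(record, "eeg_record"), "record must be an eeg_record")
  fs <- record$fs
  assert_that(fs == as.integer(fs), "write_edf needs an integer sampling rate")
  ns <- nrow(record$data)
  n <- ncol(record$data)
  nrec <- as.integer(ceiling(n / fs))
  data <- record$data
  if (nrec * fs > n) {
    data <- cbind(data, matrix(0, ns, nrec * fs - n))
  }

  pmin_ <- apply(data, 1, min)
  pmax_ <- apply(data, 1, max)
  pmax_ <- ifelse(pmax_ <= pmin_, pmin_ + 1, pmax_)
  # the physical range is stored in 8-char ASCII fields; quantise against
  # the stored (rounded) values so the reader reconstructs with exactly the
  # written range, and widen outward until the rounded bounds enclose the data
  store_bound <- function(target, data_bound, step, side) {
    for (i in 0:20) {
      v <- as.numeric(num_field(target + side * i * step, 8))
      if (side * (v - data_bound) >= 0) return(v)
    }
    stop("could not encode physical range in the EDF header", call. = FALSE)
  }
  rng <- pmax_ - pmin_
  pmin_ <- mapply(store_bound, pmin_ - 0.005 * rng, pmin_, 0.005 * rng, -1)
  pmax_ <- mapply(store_bound, pmax_ + 0.005 * rng, pmax_, 0.005 * rng, +1)
  dmin <- -32768L; dmax <- 32767L

  con <- file(path, open = "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8),
    pad_field("X X X X", 80),
    pad_field("Startdate X X X X", 80),
    pad_field("01.01.00", 8), pad_field("00.00.00", 8),
    pad_field(256L * (1L + ns), 8),
    pad_field("", 44),
    pad_field(nrec, 8),
    pad_field(1L, 8),
    pad_field(ns, 4)
  )
  writeChar(hdr, con, eos = NULL)
  fields <- c(
    paste(vapply(record$channel_names, pad_field, "", width = 16), collapse = ""),
    paste(rep(pad_field("", 80), ns), collapse = ""),
    paste(rep(pad_field("uV", 8), ns), collapse = ""),
    paste(vapply(pmin_, num_field, "", width = 8), collapse = ""),
    paste(vapply(pmax_, num_field, "", width = 8), collapse = ""),
    paste(rep(pad_field(dmin, 8), ns), collapse = ""),
    paste(rep(pad_field(dmax, 8), ns), collapse = ""),
    paste(rep(pad_field("", 80), ns), collapse = ""),
    paste(rep(pad_field(as.integer(fs), 8), ns), collapse = ""),
    paste(rep(pad_field("", 32), ns), collapse = "")
  )
  writeChar(paste(fields, collapse = ""), con, eos = NULL)

  scale <- (pmax_ - pmin_) / (dmax - dmin)
  for (r in seq_len(nrec)) {
    cols <- ((r - 1L) * fs + 1L):(r * fs)
    for (ch in seq_len(ns)) {
      dig <- as.integer(round((data[ch, cols] - pmin_[ch]) / scale[ch]) + dmin)
      writeBin(pmin.int(pmax.int(dig, dmin), dmax), con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}

read_ascii <- function(con, n) {
  rawToChar(readBin(con, "raw", n))
}

#' Read an EDF file into an EEG record
#'
#' Supports the fixed-rate dialect written by [write_edf()] (every signal
#' sampled at the same rate, one-second records, 16-bit samples).
#'
#' @param path EDF file.
#' @param seizure_intervals optional annotation matrix (e.g. from
#'   [read_annotations()]) attached to the returned record.
#' @return an [eeg_record()].
#' @export
read_edf <- function(path, seizure_intervals = NULL) {
  con <- file(path, open = "rb")
  on.exit(close(con))
  read_ascii(con, 8)                                    # version
  read_ascii(con, 160)                                  # patient + recording
  read_ascii(con, 16)                                   # date + time
  as.integer(read_ascii(con, 8))                        # header bytes
  read_ascii(con, 44)
  nrec <- as.integer(read_ascii(con, 8))
  rec_dur <- as.numeric(read_ascii(con, 8))
  ns <- as.integer(read_ascii(con, 4))

  labels <- trimws(vapply(seq_len(ns), function(i) read_ascii(con, 16), ""))
  read_ascii(con, 80 * ns)                              # transducer
  read_ascii(con, 8 * ns)                               # physical dimension
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) read_ascii(con, 8), ""))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) read_ascii(con, 8), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) read_ascii(con, 8), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) read_ascii(con, 8), ""))
  read_ascii(con, 80 * ns)                              # prefiltering
  nr <- as.integer(vapply(seq_len(ns), function(i) read_ascii(con, 8), ""))
  read_ascii(con, 32 * ns)

  assert_that(length(unique(nr)) == 1L,
              "read_edf supports a single sampling rate across channels")
  fs <- nr[1] / rec_dur
  data <- matrix(0, ns, nrec * nr[1])
  for (r in seq_len(nrec)) {
    block <- readBin(con, "integer", n = ns * nr[1], size = 2, signed = TRUE,
                     endian = "little")
    m <- matrix(block, nrow = nr[1], ncol = ns)          # per-channel runs
    cols <- ((r - 1L) * nr[1] + 1L):(r * nr[1])
    for (ch in seq_len(ns)) {
      data[ch, cols] <- (m[, ch] - dmin[ch]) / (dmax[ch] - dmin[ch]) *
        (pmax_[ch] - pmin_[ch]) + pmin_[ch]
    }
  }
  eeg_record(data, fs, labels, seizure_intervals)
}

#' Read seizure annotations from a TSV file
#'
#' Expected columns: `record_id`, `start_s`, `end_s` (half-open seconds).
#' Intervals are validated to be sorted and non-overlapping per record.
#'
#' @param path TSV file.
#' @param record_id optional: return only this record's intervals as a
#'   two-column matrix; otherwise return the full data frame.
#' @return matrix (`start_s`, `end_s`) or data frame.
#' @export
read_annotations <- function(path, record_id = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("record_id", "start_s", "end_s")
  assert_that(all(need %in% names(df)), "annotations need record_id/start_s/end_s")
  assert_that(all(df$start_s < df$end_s), "annotation intervals need start < end")
  for (id in unique(df$record_id)) {
    iv <- df[df$record_id == id, c("start_s", "end_s"), drop = FALSE]
    iv <- iv[order(iv$start_s), , drop = FALSE]
    if (nrow(iv) > 1L) {
      assert_that(all(iv$end_s[-nrow(iv)] <= iv$start_s[-1]),
                  sprintf("overlapping annotations for record '%s'", id))
    }
  }
  if (is.null(record_id)) return(df)
  iv <- df[df$record_id == record_id, c("start_s", "end_s"), drop = FALSE]
  iv <- iv[order(iv$start_s), , drop = FALSE]
  as.matrix(iv)
}

#' Save / load a segment set
#'
#' Binary archive (RDS) for the segment tensor plus a JSON sidecar carrying
#' the metadata (`fs`, `window_s`, `step_s`, channel names) so the archive
#' is self-describing.
#'
#' @param segs a `segment_set`.
#' @param path output `.rds` path; the sidecar is written at `<path>.json`.
#' @return `save_segments()` returns `path` invisibly; `load_segments()`
#'   a `segment_set`.
#' @export
save_segments <- function(segs, path) {
  assert_that(inherits(segs, "segment_set"), "segs must be a segment_set")
  saveRDS(segs, path)
  jsonlite::write_json(
    list(fs = segs$fs, window_s = segs$window_s, step_s = segs$step_s,
         n_segments = dim(segs$segments)[1],
         channel_names = segs$channel_names),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_segments
#' @export
load_segments <- function(path) {
  segs <- readRDS(path)
  assert_that(inherits(segs, "segment_set"), "archive does not hold a segment_set")
  segs
}

# Reproducibility manifest: config hash (md5 of its canonical JSON), seed,
# package and R versions.
write_manifest <- function(config, seed, path) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  hash <- unname(tools::md5sum(tmp))
  jsonlite::write_json(
    list(config = config, config_md5 = hash, seed = seed,
         package_version = as.character(utils::packageVersion("bnnsmote")),
         r_version = R.version.string,
         created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    path, auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(path)
}
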