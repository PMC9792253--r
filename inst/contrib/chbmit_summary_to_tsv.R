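#!/usr/bin/env Rscript

# Contrib utility: convert a CHB-MIT chbXX-summary.txt file into the
# annotation TSV consumed by bnnsmote::read_annotations().
#
#   Rscript chbmit_summary_to_tsv.R chb01-summary.txt > chb01-annotations.tsv
#
# The summary format is irregular across patients (some use
# "Seizure Start Time", others "Seizure 1 Start Time"), which is why this
# lives in contrib rather than the package core. Lines are matched
# permissively; times are seconds from the start of the named file.

args <- commandArgs(trailingOnly = TRUE)
if (length(args) != 1L) stop("usage: chbmit_summary_to_tsv.R <summary.txt>")

lines <- readLines(args[1L], warn = FALSE)
current <- NA_character_
starts <- numeric(0); ends <- numeric(0); recs <- character(0)
pending_start <- NA_real_

for (ln in lines) {
  if (grepl("^File Name:", ln)) {
    current <- sub("\\.edf\\s*$", "", trimws(sub("^File Name:", "", ln)))
    pending_start <- NA_real_
  } else if (grepl("Seizure.*Start Time:", ln)) {
    pending_start <- as.numeric(gsub("[^0-9.]", "", sub(".*Start Time:", "", ln)))
  } else if (grepl("Seizure.*End Time:", ln)) {
    end <- as.numeric(gsub("[^0-9.]", "", sub(".*End Time:", "", ln)))
    if (!is.na(pending_start) && !is.na(current)) {
      recs <- c(recs, current); starts <- c(starts, pending_start)
      ends <- c(ends, end)
    }
    pending_start <- NA_real_
  }
}

cat("record_id\tstart_s\tend_s\n")
for (i in seq_along(recs)) {
  cat(sprintf("%s\t%g\t%g\n", recs[i], starts[i], ends[i]))
}
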