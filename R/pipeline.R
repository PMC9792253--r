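#' Configuration for an end-to-end pipeline run
#'
#' Describes one detection experiment: where the record comes from (an EDF
#' file with a TSV annotation sidecar, or the synthetic generator), the
#' preprocessing parameters, the resampler, the classifier and the
#' evaluation protocol. The global `seed` propagates to every stochastic
#' component.
#'
#' @param input_edf path to an EDF recording, or `NULL` to simulate.
#' @param annotations path to a seizure-annotation TSV (used with
#'   `input_edf`).
#' @param record_id record identifier inside the annotation file.
#' @param synth a [synth_eeg_config()] used when `input_edf` is `NULL`.
#' @param low_hz,high_hz,filter_order bandpass settings.
#' @param channels channel names to retain (`NULL` keeps all).
#' @param channel channel used for window classification (name or index
#'   into the retained set; default 1).
#' @param window_s,step_s,label_rule segmentation settings.
#' @param resampler resampler name from [resampler_registry()].
#' @param resample_cfg a [resample_config()].
#' @param classifier `"knn"` or `"onednet"`.
#' @param n_folds,test_frac evaluation protocol.
#' @param seed global integer seed.
#' @param out_dir output directory for report, manifest and provenance
#'   (`NULL` writes nothing).
#' @return an object of class `run_config`.
#' @export
run_config <- function(input_edf = NULL, annotations = NULL, record_id = NULL,
                       synth = synth_eeg_config(),
                       low_hz = 0.5, high_hz = 50, filter_order = 4L,
                       channels = NULL, channel = 1L,
                       window_s = 4, step_s = 2,
                       label_rule = "majority-overlap",
                       resampler = "bnnsmote",
                       resample_cfg = resample_config(),
                       classifier = "knn",
                       n_folds = 5L, test_frac = 0.2, seed = 1L,
                       out_dir = NULL) {
  if (!is.null(input_edf)) {
    assert_that(file.exists(input_edf), sprintf("no such file: %s", input_edf))
  }
  get_resampler(resampler)  # validates the name
  structure(as.list(environment()), class = "run_config")
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full seizure-detection pipeline
#'
#' Executes read (or simulate) -> bandpass -> channel selection -> sliding
#' window segmentation -> per-fold resample-train-only cross-validated
#' evaluation, and optionally writes the evaluation report and a
#' reproducibility manifest to `cfg$out_dir`.
#'
#' @param cfg a [run_config()].
#' @return the `eval_report`, with an attribute `"paths"` naming any files
#'   written.
#' @export
run_pipeline <- function(cfg) {
  assert_that(inherits(cfg, "run_config"), "cfg must be a run_config")

  record <- with_stage("read", {
    if (!is.null(cfg$input_edf)) {
      iv <- if (!is.null(cfg$annotations)) {
        read_annotations(cfg$annotations, cfg$record_id)
      } else NULL
      read_edf(cfg$input_edf, seizure_intervals = iv)
    } else {
      synth <- cfg$synth
      synth$seed <- cfg$seed
      make_eeg(synth)
    }
  })

  record <- with_stage("bandpass",
    bandpass(record, cfg$low_hz, cfg$high_hz, cfg$filter_order))

  if (!is.null(cfg$channels)) {
    record <- with_stage("select_channels", select_channels(record, cfg$channels))
  }

  segs <- with_stage("segment",
    segment(record, cfg$window_s, cfg$step_s, cfg$label_rule))
  segs <- with_stage("channel_view", segment_channel(segs, cfg$channel))

  report <- with_stage("evaluate", {
    graph <- if (cfg$classifier == "onednet") {
      build_model(default_spec(input_length = dim(segs$segments)[3]))
    } else NULL
    cross_validate(segs, resampler = cfg$resampler,
                   classifier = cfg$classifier, n_folds = cfg$n_folds,
                   test_frac = cfg$test_frac, seed = cfg$seed,
                   cfg = cfg$resample_cfg, graph = graph)
  })

  paths <- if (is.null(cfg$out_dir)) character(0) else {
    with_stage("write_outputs", {
      dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
      rp <- file.path(cfg$out_dir, "report.json")
      write_report(report, rp)
      mp <- file.path(cfg$out_dir, "manifest.json")
      serializable <- cfg
      serializable$synth <- unclass(serializable$synth)
      serializable$resample_cfg <- unclass(serializable$resample_cfg)
      write_manifest(unclass(serializable), cfg$seed, mp)
      c(report = rp, manifest = mp)
    })
  }
  attr(report, "paths") <- paths
  report
}
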