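#' Confusion matrix for binary seizure detection
#'
#' Positive = seizure (label 1), negative = nonseizure (label 0).
#'
#' @param y_true,y_pred binary 0/1 vectors of equal length.
#' @return an object of class `confusion_matrix` with fields `TP`, `FP`,
#'   `FN`, `TN`.
#' @examples
#' confusion_matrix(c(1, 1, 0, 0), c(1, 0, 0, 1))
#' @export
confusion_matrix <- function(y_true, y_pred) {
  assert_that(length(y_true) == length(y_pred),
              "y_true and y_pred must have equal length")
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  assert_that(all(y_true %in% 0:1) && all(y_pred %in% 0:1),
              "labels must be 0/1")
  structure(list(
    TP = sum(y_true == 1L & y_pred == 1L),
    FP = sum(y_true == 0L & y_pred == 1L),
    FN = sum(y_true == 1L & y_pred == 0L),
    TN = sum(y_true == 0L & y_pred == 0L)
  ), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> TP=%d FP=%d FN=%d TN=%d\n",
              x$TP, x$FP, x$FN, x$TN))
  invisible(x)
}

#' Accuracy, recall, precision and F1-score
#'
#' The four standard detection metrics: accuracy `(TP+TN)/total`, recall
#' `TP/(TP+FN)`, precision `TP/(TP+FP)` and their harmonic mean, the
#' F1-score `2*precision*recall/(precision+recall)`. A zero denominator
#' yields the convention value 0 (in particular F1 = 0 whenever TP = 0).
#'
#' @param cm a [confusion_matrix()].
#' @return named numeric vector `accuracy`, `recall`, `precision`, `f1`.
#' @export
classification_metrics <- function(cm) {
  assert_that(inherits(cm, "confusion_matrix"), "cm must be a confusion_matrix")
  total <- cm$TP + cm$FP + cm$FN + cm$TN
  assert_that(total > 0, "empty confusion matrix")
  safe_div <- function(num, den) if (den == 0) 0 else num / den
  acc <- (cm$TP + cm$TN) / total
  rec <- safe_div(cm$TP, cm$TP + cm$FN)
  pre <- safe_div(cm$TP, cm$TP + cm$FP)
  f1 <- safe_div(2 * pre * rec, pre + rec)
  c(accuracy = acc, recall = rec, precision = pre, f1 = f1)
}

# Stratified index split helpers ------------------------------------------

# Monte-Carlo split: one independent stratified 80/20 draw.
stratified_split <- function(y, test_frac, seed) {
  with_seed(seed, {
    test <- integer(0)
    for (cls in unique(y)) {
      rows <- which(y == cls)
      n_test <- max(1L, round(test_frac * length(rows)))
      test <- c(test, rows[sample.int(length(rows), n_test)])
    }
    sort(test)
  })
}

# Classic partitioned k-fold assignment, stratified by label.
kfold_assignment <- function(y, n_folds, seed) {
  with_seed(seed, {
    fold <- integer(length(y))
    for (cls in unique(y)) {
      rows <- which(y == cls)
      fold[rows] <- sample(rep_len(seq_len(n_folds), length(rows)))
    }
    fold
  })
}

#' Leakage-safe cross-validated resampler evaluation
#'
#' Evaluates a resampler + classifier combination with `n_folds` rounds.
#' Default protocol: independent stratified random 80/20 splits (Monte-Carlo
#' cross-validation, matching a "5-fold, 8:2 ratio" protocol); classic
#' partitioned k-fold is available via `mode = "kfold"`. The resampler is
#' fitted and applied **only** to the training portion of each fold — the
#' test portion is never resampled — and every fold is audited: no test row
#' may appear as a parent or partner in the resampled training set's
#' provenance.
#'
#' @param data a [labeled_dataset()], or a single-channel `segment_set`
#'   (flattened to windows for resampling).
#' @param resampler resampler name from [resampler_registry()].
#' @param classifier `"knn"` (1-nearest-neighbour, fast) or `"onednet"`
#'   (train the network of `graph` each fold).
#' @param n_folds number of evaluation rounds (default 5).
#' @param test_frac test fraction per round (default 0.2).
#' @param seed integer seed; fold splits and resampler draws derive from it.
#' @param cfg a [resample_config()] (its `seed` is overridden per fold).
#' @param mode `"monte-carlo"` (default) or `"kfold"`.
#' @param graph,hp model graph and hyperparameters for
#'   `classifier = "onednet"`.
#' @return an `eval_report`: per-fold metrics, their means, fold seeds,
#'   per-fold synthetic counts and the leakage audit result.
#' @export
cross_validate <- function(data, resampler = "none", classifier = "knn",
                           n_folds = 5L, test_frac = 0.2, seed = 1L,
                           cfg = resample_config(),
                           mode = c("monte-carlo", "kfold"),
                           graph = NULL, hp = train_hyperparams()) {
  mode <- match.arg(mode)
  classifier <- match.arg(classifier, c("knn", "onednet"))
  segs <- NULL
  if (inherits(data, "segment_set")) {
    segs <- data
    data <- segments_to_dataset(data)
  }
  assert_that(inherits(data, "labeled_dataset"), "data must be a labeled_dataset")
  if (classifier == "onednet") {
    assert_that(!is.null(segs) && !is.null(graph),
                "classifier 'onednet' needs a segment_set and a model graph")
  }
  rs_fun <- get_resampler(resampler)
  n <- nrow(data$X)
  y <- data$y
  assert_that(sum(y == 1L) >= 2L && sum(y == 0L) >= 2L,
              "need at least two samples of each class")
  fold_assign <- if (mode == "kfold") kfold_assignment(y, n_folds, seed) else NULL

  fold_seeds <- vapply(seq_len(n_folds), function(f) derive_seed(seed, f), 1L)
  rows <- vector("list", n_folds)
  leakage_ok <- logical(n_folds)
  for (f in seq_len(n_folds)) {
    test_idx <- if (mode == "kfold") which(fold_assign == f)
                else stratified_split(y, test_frac, fold_seeds[f])
    train_idx <- setdiff(seq_len(n), test_idx)
    if (length(unique(y[train_idx])) < 2L) {
      stop(sprintf("fold %d: training split lacks a class", f), call. = FALSE)
    }
    if (!any(y[test_idx] == 1L)) {
      warning(sprintf("fold %d: test split has no positive samples; recall set to 0 by convention", f),
              call. = FALSE)
    }
    train <- labeled_dataset(data$X[train_idx, , drop = FALSE], y[train_idx])
    cfg_f <- cfg
    cfg_f$seed <- derive_seed(seed, 10000L + f)
    res <- rs_fun(train, cfg_f)

    # leakage audit: provenance rows index the fold's training subset; map
    # back to original row ids and require disjointness from the test set
    parent_orig <- train_idx[res$provenance$parent]
    partner_orig <- train_idx[res$provenance$partner]
    leakage_ok[f] <- length(intersect(c(parent_orig, partner_orig),
                                      test_idx)) == 0L

    if (classifier == "knn") {
      pred <- knn_classifier(res$dataset, data$X[test_idx, , drop = FALSE])
    } else {
      train_segs <- dataset_to_segs(res$dataset, segs)
      fit <- train_model(graph, train_segs, hp)
      test_segs <- subset_segs(segs, test_idx)
      pred <- predict(fit, test_segs)$labels
    }
    cm <- confusion_matrix(y[test_idx], pred)
    m <- classification_metrics(cm)
    rows[[f]] <- data.frame(fold = f, n_test = length(test_idx),
                            n_test_pos = sum(y[test_idx] == 1L),
                            n_synth = res$n_synth,
                            accuracy = m["accuracy"], recall = m["recall"],
                            precision = m["precision"], f1 = m["f1"],
                            row.names = NULL)
  }
  folds <- do.call(rbind, rows)
  means <- colMeans(folds[c("accuracy", "recall", "precision", "f1")])
  structure(list(folds = folds, means = means, resampler = resampler,
                 classifier = classifier, n_folds = n_folds,
                 test_frac = test_frac, seed = seed, mode = mode,
                 fold_seeds = fold_seeds, leakage_ok = leakage_ok),
            class = "eval_report")
}

# rebuild a single-channel segment_set from (possibly resampled) flattened
# windows, keeping the template's geometry
dataset_to_segs <- function(data, template) {
  win <- dim(template$segments)[3]
  n_ch <- dim(template$segments)[2]
  assert_that(ncol(data$X) == win * n_ch, "flattened width mismatch")
  segs <- template
  arr <- array(data$X, c(nrow(data$X), n_ch, win))
  segs$segments <- arr
  segs$labels <- data$y
  segs$offsets <- rep(NA_real_, nrow(data$X))
  segs
}

subset_segs <- function(segs, idx) {
  out <- segs
  out$segments <- segs$segments[idx, , , drop = FALSE]
  out$labels <- segs$labels[idx]
  out$offsets <- segs$offsets[idx]
  out
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %s + %s | %d x %s (test %.0f%%) | leakage-free: %s\n",
              x$resampler, x$classifier, x$n_folds, x$mode,
              100 * x$test_frac, all(x$leakage_ok)))
  cat(sprintf("  mean: Acc %.4f  Rec %.4f  Pre %.4f  F1 %.4f\n",
              x$means["accuracy"], x$means["recall"], x$means["precision"],
              x$means["f1"]))
  invisible(x)
}

#' Serialize an evaluation report to JSON
#'
#' @param report an `eval_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  assert_that(inherits(report, "eval_report"), "need an eval_report")
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Compare resamplers under a fixed classifier
#'
#' Runs [cross_validate()] once per resampler and tabulates the mean
#' metrics, one row per method (columns Rec / Pre / F1 / Acc, in percent).
#'
#' @param data a [labeled_dataset()] or single-channel `segment_set`.
#' @param resamplers character vector of registry names.
#' @param ... passed on to [cross_validate()].
#' @return list with `table` (data frame) and `reports` (named list of
#'   `eval_report`s).
#' @export
benchmark_resamplers <- function(data,
                                 resamplers = c("none", "ros", "smote",
                                                "blsmote", "svmsmote",
                                                "bnnsmote"),
                                 ...) {
  reports <- lapply(resamplers, function(r) cross_validate(data, resampler = r, ...))
  names(reports) <- resamplers
  tab <- data.frame(
    method = resamplers,
    rec = vapply(reports, function(r) 100 * r$means[["recall"]], 1),
    pre = vapply(reports, function(r) 100 * r$means[["precision"]], 1),
    f1 = vapply(reports, function(r) 100 * r$means[["f1"]], 1),
    acc = vapply(reports, function(r) 100 * r$means[["accuracy"]], 1),
    row.names = NULL
  )
  names(tab) <- c("method", "Rec (%)", "Pre (%)", "F1 (%)", "Acc (%)")
  list(table = tab, reports = reports)
}
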