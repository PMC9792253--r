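# Confusion counts, metric formulas and the cross-validation protocol.

test_that("confusion counts and their symmetries", {
  cm <- confusion_matrix(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(c(cm$TP, cm$TN, cm$FP, cm$FN), c(2, 2, 0, 0))
  # flipping all predictions swaps TP<->FN and TN<->FP
  y <- rbinom(200, 1, 0.3); p <- rbinom(200, 1, 0.5)
  a <- confusion_matrix(y, p); b <- confusion_matrix(y, 1 - p)
  expect_equal(a$TP, b$FN); expect_equal(a$TN, b$FP)
  expect_equal(a$FP, b$TN); expect_equal(a$FN, b$TP)
})

test_that("metric values on worked examples", {
  m <- classification_metrics(structure(list(TP = 2, FP = 1, FN = 1, TN = 6),
                                        class = "confusion_matrix"))
  expect_equal(unname(m), c(0.8, 2 / 3, 2 / 3, 2 / 3))
  perfect <- classification_metrics(
    structure(list(TP = 5, FP = 0, FN = 0, TN = 5), class = "confusion_matrix"))
  expect_equal(unname(perfect), c(1, 1, 1, 1))
  # harmonic mean: precision 1, recall 0.5 -> F1 = 2/3
  m2 <- classification_metrics(
    structure(list(TP = 1, FP = 0, FN = 1, TN = 0), class = "confusion_matrix"))
  expect_equal(m2[["f1"]], 2 / 3)
  # TP = 0 convention
  m0 <- classification_metrics(
    structure(list(TP = 0, FP = 2, FN = 3, TN = 5), class = "confusion_matrix"))
  expect_equal(unname(m0[c("recall", "precision", "f1")]), c(0, 0, 0))
})

test_that("accuracy is symmetric under label complementation, recall is not", {
  set.seed(50)
  y <- rbinom(300, 1, 0.2); p <- rbinom(300, 1, 0.4)
  m <- classification_metrics(confusion_matrix(y, p))
  mc <- classification_metrics(confusion_matrix(1 - y, 1 - p))
  expect_equal(m[["accuracy"]], mc[["accuracy"]])
  expect_false(isTRUE(all.equal(m[["recall"]], mc[["recall"]])))
})

test_that("stratified folds test the expected number of samples", {
  gen <- make_clusters(cluster_config(n_major = 80, n_minor = 20,
                                      separation = 8, seed = 1))
  rep <- cross_validate(gen$dataset, "none", "knn", n_folds = 5,
                        test_frac = 0.2, seed = 1)
  expect_equal(rep$folds$n_test, rep(20L, 5))       # 16 majority + 4 minority
  expect_equal(rep$folds$n_test_pos, rep(4L, 5))
  expect_true(all(rep$leakage_ok))
})

test_that("the resampler touches only the training split", {
  gen <- make_clusters(cluster_config(n_major = 120, n_minor = 12,
                                      separation = 2, noise_frac = 0.1,
                                      seed = 2))
  for (rs in c("ros", "smote", "bnnsmote")) {
    rep <- suppressWarnings(
      cross_validate(gen$dataset, rs, "knn", n_folds = 5, seed = 3))
    expect_true(all(rep$leakage_ok))
    expect_true(all(rep$folds$n_synth > 0))
  }
})

test_that("identical seeds reproduce the full report", {
  gen <- make_clusters(cluster_config(n_major = 90, n_minor = 12,
                                      separation = 2, seed = 7))
  r1 <- suppressWarnings(cross_validate(gen$dataset, "bnnsmote", "knn", seed = 7))
  r2 <- suppressWarnings(cross_validate(gen$dataset, "bnnsmote", "knn", seed = 7))
  expect_identical(r1$folds, r2$folds)
  expect_identical(r1$means, r2$means)
})

test_that("partitioned k-fold mode covers every sample exactly once", {
  gen <- make_clusters(cluster_config(n_major = 80, n_minor = 20,
                                      separation = 4, seed = 4))
  rep <- cross_validate(gen$dataset, "none", "knn", n_folds = 5, seed = 4,
                        mode = "kfold")
  expect_equal(sum(rep$folds$n_test), 100L)
  expect_true(all(rep$folds$n_test_pos == 4L))
})

test_that("reports serialize to JSON and benchmark tabulates all methods", {
  gen <- make_clusters(cluster_config(n_major = 60, n_minor = 10,
                                      separation = 3, seed = 5))
  bench <- suppressWarnings(
    benchmark_resamplers(gen$dataset, resamplers = c("none", "ros", "bnnsmote"),
                         n_folds = 2, seed = 5))
  expect_equal(bench$table$method, c("none", "ros", "bnnsmote"))
  expect_true(all(bench$table[["F1 (%)"]] >= 0 & bench$table[["F1 (%)"]] <= 100))
  f <- tempfile(fileext = ".json")
  write_report(bench$reports$ros, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$resampler, "ros")
  expect_equal(nrow(back$folds), 2)
})

test_that("cross-validating a segment set trains on resampled windows", {
  segs <- make_imbalanced_segments(ratio = 1 / 8, duration_s = 120, seed = 6)
  rep <- suppressWarnings(
    cross_validate(segs, "bnnsmote", "knn", n_folds = 2, seed = 6))
  expect_true(all(rep$leakage_ok))
  expect_equal(nrow(rep$folds), 2)
})
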