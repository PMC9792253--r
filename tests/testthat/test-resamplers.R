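# Contracts shared by the five resamplers, plus per-method behaviour.

test_that("interpolation endpoints behave as expected", {
  set.seed(21)
  X <- rbind(matrix(rnorm(30), 15, 2), matrix(rnorm(12, mean = 3), 6, 2))
  d <- labeled_dataset(X, c(rep(0, 15), rep(1, 6)))
  syn <- synthesize_samples(d, danger = 16:18, clean_minority = 16:21,
                            n_new = 50, seed = 9)
  # each row is parent + delta * (partner - parent), exactly
  for (i in 1:50) {
    p <- syn$provenance$parent[i]; q <- syn$provenance$partner[i]
    dl <- syn$provenance$delta[i]
    expect_equal(syn$X_synth[i, ], unname(X[p, ] + dl * (X[q, ] - X[p, ])))
    # convexity: inside the axis-aligned bounding box of the pair
    expect_true(all(syn$X_synth[i, ] >= pmin(X[p, ], X[q, ]) - 1e-12))
    expect_true(all(syn$X_synth[i, ] <= pmax(X[p, ], X[q, ]) + 1e-12))
  }
  expect_true(all(syn$provenance$parent %in% 16:18))
  expect_true(all(syn$provenance$partner %in% 16:21))
  expect_true(all(syn$provenance$delta >= 0 & syn$provenance$delta <= 1))
})

test_that("duplicate parent and partner coordinates give the parent back", {
  X <- rbind(matrix(0, 4, 2), matrix(1, 3, 2))   # all minority identical
  d <- labeled_dataset(X, c(0, 0, 0, 0, 1, 1, 1))
  syn <- synthesize_samples(d, danger = 5L, clean_minority = 5:7, n_new = 10,
                            seed = 1)
  expect_true(all(syn$X_synth == 1))
})

test_that("synthesis with a single clean minority sample is refused", {
  X <- rbind(matrix(rnorm(20), 10, 2), c(5, 5))
  d <- labeled_dataset(X, c(rep(0, 10), 1))
  expect_error(synthesize_samples(d, 11L, 11L, 5, seed = 1), "fewer than two")
})

test_that("already balanced input is a no-op for every resampler", {
  set.seed(31)
  X <- matrix(rnorm(80), 40, 2)
  d <- labeled_dataset(X, rep(c(0L, 1L), 20))
  for (nm in c("ros", "smote", "blsmote", "svmsmote", "bnnsmote")) {
    res <- suppressWarnings(get_resampler(nm)(d, resample_config(seed = 1)))
    expect_equal(res$n_synth, 0L)
    expect_equal(nrow(res$provenance), 0L)
  }
})

test_that("inverted imbalance no-ops with a warning", {
  set.seed(32)
  X <- matrix(rnorm(60), 30, 2)
  d <- labeled_dataset(X, c(rep(0L, 10), rep(1L, 20)))
  expect_warning(res <- ros(d, resample_config(seed = 1)), "exceeds")
  expect_equal(res$n_synth, 0L)
})

test_that("ros duplicates real minority rows and replays its seeded draw", {
  set.seed(33)
  X <- rbind(matrix(rnorm(60), 30, 2), matrix(rnorm(6, mean = 4), 3, 2))
  d <- labeled_dataset(X, c(rep(0L, 30), rep(1L, 3)))
  res <- ros(d, resample_config(seed = 5))
  expect_balanced(res)
  synth <- res$dataset$X[res$dataset$y == 1L, ][-(1:3), , drop = FALSE]
  for (i in seq_len(nrow(synth))) {
    expect_true(any(apply(X[31:33, , drop = FALSE], 1,
                          function(r) all(r == synth[i, ]))))
  }
  # replay the documented draw: one uniform index sample
  minority <- 31:33
  expected <- bnnsmote:::with_seed(5L,
    minority[sample.int(3, res$n_synth, replace = TRUE)])
  expect_equal(res$provenance$parent, expected)
  expect_true(all(res$provenance$delta == 0))
  expect_equal(res$provenance$partner, res$provenance$parent)
})

test_that("smote synthesises on segments joining minority kNN pairs", {
  set.seed(34)
  X <- rbind(matrix(rnorm(28), 14, 2), matrix(rnorm(12, mean = 2.5), 6, 2))
  d <- labeled_dataset(X, c(rep(0L, 14), rep(1L, 6)))
  res <- smote(d, resample_config(seed = 2, k_danger = 3))
  expect_balanced(res)
  minority <- 15:20
  nt <- brute_knn(X[minority, , drop = FALSE], k = 3)
  for (i in seq_len(nrow(res$provenance))) {
    p <- res$provenance$parent[i]; q <- res$provenance$partner[i]
    expect_true(p %in% minority)
    expect_true(q %in% minority[nt$indices[match(p, minority), ]])
  }
})

test_that("blsmote danger membership matches the borderline rule", {
  set.seed(35)
  X <- rbind(matrix(rnorm(80, sd = 1), 40, 2),
             matrix(rnorm(24, mean = 2, sd = 1), 12, 2))
  y <- c(rep(0L, 40), rep(1L, 12))
  d <- labeled_dataset(X, y)
  res <- suppressWarnings(blsmote(d, resample_config(seed = 3)))
  expected <- integer(0)
  for (i in which(y == 1L)) {
    dd <- sqrt(rowSums(sweep(X, 2, X[i, ])^2)); dd[i] <- Inf
    nn <- order(dd, seq_along(dd))[1:5]
    m <- sum(y[nn] == 0L)
    if (m >= 2.5 && m < 5) expected <- c(expected, i)
  }
  expect_equal(res$danger_indices, expected)
  if (length(expected)) {
    expect_true(all(res$provenance$parent %in% expected))
  }
})

test_that("blsmote no-ops with a warning when all minority is interior", {
  gen <- make_clusters(cluster_config(n_major = 60, n_minor = 10,
                                      separation = 10, seed = 6))
  expect_warning(res <- blsmote(gen$dataset, resample_config(seed = 1)),
                 "DANGER set empty")
  expect_equal(res$n_synth, 0L)
})

test_that("svmsmote parents are minority support vectors", {
  set.seed(36)
  gen <- make_clusters(cluster_config(n_major = 50, n_minor = 12,
                                      separation = 3, seed = 9))
  d <- gen$dataset
  res <- svmsmote(d, resample_config(seed = 4))
  expect_balanced(res)
  fit <- e1071::svm(x = d$X, y = factor(d$y, levels = c(0, 1)),
                    kernel = "linear", scale = FALSE, cost = 1)
  sv_min <- intersect(fit$index, minority_indices(d))
  expect_setequal(res$danger_indices, sv_min)
  expect_true(all(res$provenance$parent %in% sv_min))
})

test_that("bnnsmote: balanced output, noise excluded from provenance", {
  gen <- make_clusters(cluster_config(n_major = 300, n_minor = 10,
                                      separation = 8, noise_frac = 0.2,
                                      seed = 1))
  res <- suppressWarnings(bnnsmote(gen$dataset, resample_config(seed = 1)))
  expect_equal(sum(res$dataset$y == 1L), 300L)
  expect_equal(sum(res$dataset$y == 0L), 300L)
  expect_setequal(res$noise_indices, gen$truth)
  expect_length(intersect(res$provenance$parent, res$noise_indices), 0)
  expect_length(intersect(res$provenance$partner, res$noise_indices), 0)
  # noise rows removed from the output minority
  n_out <- nrow(res$dataset$X)
  expect_equal(n_out, nrow(gen$dataset$X) - length(gen$truth) + res$n_synth)
})

test_that("keep_noise retains flagged rows without using them as parents", {
  gen <- make_clusters(cluster_config(n_major = 100, n_minor = 10,
                                      separation = 8, noise_frac = 0.2,
                                      seed = 2))
  res <- suppressWarnings(
    bnnsmote(gen$dataset, resample_config(seed = 2, keep_noise = TRUE)))
  expect_equal(nrow(res$dataset$X), nrow(gen$dataset$X) + res$n_synth)
  expect_length(intersect(res$provenance$parent, res$noise_indices), 0)
  expect_balanced(res)
})

test_that("majority rows pass through unmodified and in order", {
  for (nm in c("ros", "smote", "blsmote", "svmsmote", "bnnsmote")) {
    gen <- make_clusters(cluster_config(n_major = 60, n_minor = 10,
                                        separation = 2, seed = 42))
    res <- suppressWarnings(get_resampler(nm)(gen$dataset,
                                              resample_config(seed = 1)))
    out_maj <- res$dataset$X[res$dataset$y == 0L, , drop = FALSE]
    in_maj <- gen$dataset$X[gen$dataset$y == 0L, , drop = FALSE]
    expect_identical(unname(out_maj), unname(in_maj))
  }
})

test_that("partner_mode = 'knn' restricts partners to minority neighbours", {
  gen <- make_clusters(cluster_config(n_major = 80, n_minor = 12,
                                      separation = 2, seed = 10))
  cfg <- resample_config(seed = 3, partner_mode = "knn", k_danger = 3)
  res <- suppressWarnings(bnnsmote(gen$dataset, cfg))
  clean <- setdiff(minority_indices(gen$dataset), res$noise_indices)
  nt <- brute_knn(gen$dataset$X[clean, , drop = FALSE], k = 3)
  for (i in seq_len(nrow(res$provenance))) {
    p <- res$provenance$parent[i]
    pool <- clean[nt$indices[match(p, clean), ]]
    expect_true(res$provenance$partner[i] %in% pool)
  }
})

test_that("target_ratio below 1 is honoured up to rounding", {
  gen <- make_clusters(cluster_config(n_major = 200, n_minor = 10,
                                      separation = 2, seed = 11))
  res <- suppressWarnings(
    bnnsmote(gen$dataset, resample_config(seed = 1, target_ratio = 0.5)))
  expect_balanced(res, target_ratio = 0.5)
})

test_that("provenance exports as one JSON record per synthetic row", {
  gen <- make_clusters(cluster_config(n_major = 40, n_minor = 6,
                                      separation = 2, seed = 12))
  res <- suppressWarnings(bnnsmote(gen$dataset, resample_config(seed = 1)))
  f <- tempfile(fileext = ".jsonl")
  write_provenance(res, f)
  lines <- readLines(f)
  expect_length(lines, res$n_synth)
  rec <- jsonlite::fromJSON(lines[1])
  expect_named(rec, c("row", "parent", "partner", "delta"))
})
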