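# The three BNNSMOTE stages on hand-constructed and planted configurations.

test_that("an isolated minority point inside the majority cluster is noise", {
  set.seed(2)
  X_maj <- matrix(rnorm(60, sd = 0.5), 30, 2)
  X_min <- rbind(matrix(rnorm(10, mean = 8, sd = 0.3), 5, 2),
                 c(0, 0))                        # planted deep inside majority
  d <- labeled_dataset(rbind(X_maj, X_min), c(rep(0, 30), rep(1, 6)))
  fl <- filter_noise(d, k_noise = 5)
  expect_equal(fl$noise, 36L)
  expect_setequal(fl$clean_minority, 31:35)
})

test_that("a minority point with a minority nearest neighbour is kept", {
  X <- rbind(matrix(rnorm(40, sd = 0.5), 20, 2),
             c(5, 5), c(5.05, 5))                # minority pair sticks together
  d <- labeled_dataset(X, c(rep(0, 20), 1, 1))
  fl <- filter_noise(d, k_noise = 5)
  expect_length(fl$noise, 0)
  expect_setequal(fl$clean_minority, 21:22)
})

test_that("noise and clean sets partition the minority class", {
  for (s in 1:5) {
    gen <- make_clusters(cluster_config(n_major = 80, n_minor = 12,
                                        separation = runif(1, 0, 4),
                                        noise_frac = 0.25, seed = s))
    fl <- filter_noise(gen$dataset, 5)
    expect_setequal(c(fl$clean_minority, fl$noise), minority_indices(gen$dataset))
    expect_length(intersect(fl$clean_minority, fl$noise), 0)
  }
})

test_that("boundary majority rule matches brute-force membership on a toy set", {
  set.seed(7)
  X <- rbind(matrix(rnorm(40, sd = 1), 20, 2),
             matrix(rnorm(40, mean = 2.5, sd = 1), 20, 2))
  y <- rep(c(0L, 1L), each = 20)
  d <- labeled_dataset(X, y)
  clean <- minority_indices(d)       # no noise in this construction round
  k <- 5
  got <- boundary_majority(d, clean, k)
  # brute force: recompute the rule from pairwise distances
  expected <- integer(0)
  for (i in which(y == 0L)) {
    dd <- sqrt(rowSums(sweep(X, 2, X[i, ])^2)); dd[i] <- Inf
    nn <- order(dd, seq_along(dd))[1:k]
    if (any(y[nn] == 1L)) expected <- c(expected, i)
  }
  expect_equal(got, expected)
})

test_that("k_boundary spanning the whole set returns every majority point", {
  gen <- make_clusters(cluster_config(n_major = 15, n_minor = 5,
                                      separation = 6, seed = 3))
  d <- gen$dataset
  got <- boundary_majority(d, minority_indices(d), k_boundary = 19)
  expect_setequal(got, majority_indices(d))
})

test_that("well-separated clusters yield an empty or edge-only boundary", {
  gen <- make_clusters(cluster_config(n_major = 60, n_minor = 10,
                                      separation = 10, seed = 5))
  d <- gen$dataset
  got <- boundary_majority(d, minority_indices(d), 3)
  expect_length(got, 0)  # at 10 sd nothing is within reach
})

test_that("danger set equals hand enumeration on an interleaved boundary", {
  set.seed(13)
  X <- rbind(matrix(rnorm(60, sd = 0.8), 30, 2),
             matrix(rnorm(20, mean = 2, sd = 0.8), 10, 2))
  y <- c(rep(0L, 30), rep(1L, 10))
  d <- labeled_dataset(X, y)
  clean <- minority_indices(d)
  k <- 4
  bm <- boundary_majority(d, clean, k)
  got <- danger_minority(d, clean, bm, k)
  # brute force the union of boundary-majority neighbourhoods
  expected <- integer(0)
  for (b in bm) {
    dd <- sqrt(rowSums(sweep(X, 2, X[b, ])^2)); dd[b] <- Inf
    nn <- order(dd, seq_along(dd))[1:k]
    expected <- union(expected, intersect(nn, clean))
  }
  expect_equal(got, sort(expected))
  expect_true(all(got %in% clean))
})

test_that("empty boundary set triggers the borderline fallback", {
  set.seed(4)
  # all minority interior: fallback should find nothing either
  gen <- make_clusters(cluster_config(n_major = 60, n_minor = 10,
                                      separation = 10, seed = 4))
  d <- gen$dataset
  clean <- minority_indices(d)
  expect_length(danger_minority(d, clean, integer(0), 5), 0)
  # interleaved: fallback equals the borderline rule computed by hand
  gen2 <- make_clusters(cluster_config(n_major = 60, n_minor = 12,
                                       separation = 1.5, seed = 8))
  d2 <- gen2$dataset
  clean2 <- filter_noise(d2, 5)$clean_minority
  got <- danger_minority(d2, clean2, integer(0), 5)
  keep <- sort(c(majority_indices(d2), clean2))
  expected <- integer(0)
  for (i in clean2) {
    dd <- sqrt(rowSums(sweep(d2$X[keep, ], 2, d2$X[i, ])^2))
    dd[keep == i] <- Inf
    nn <- keep[order(dd, seq_along(dd))[1:5]]
    m <- sum(d2$y[nn] == 0L)
    if (m >= 2.5 && m < 5) expected <- c(expected, i)
  }
  expect_equal(got, sort(expected))
})
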