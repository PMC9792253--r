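#' Noise filtering for minority samples
#'
#' First stage of BNNSMOTE: a minority (seizure) sample is flagged as noise
#' when *all* of its `k_noise` nearest neighbours in the full dataset are
#' majority class, i.e. it lies isolated inside the majority region and would
#' only propagate label noise if used as a synthesis parent.
#'
#' @param data a [labeled_dataset()].
#' @param k_noise neighbourhood size for the noise test.
#' @return list with integer vectors `clean_minority` and `noise`
#'   (disjoint, union = all minority row indices).
#' @export
filter_noise <- function(data, k_noise = 5L) {
  assert_that(inherits(data, "labeled_dataset"), "data must be a labeled_dataset")
  minority <- minority_indices(data)
  assert_that(length(minority) > 0L, "no minority samples to filter")
  nt <- compute_neighbors(data$X, NULL, k = k_noise)
  all_majority <- vapply(minority, function(i) {
    all(data$y[nt$indices[i, ]] == 0L)
  }, logical(1))
  list(clean_minority = minority[!all_majority], noise = minority[all_majority])
}

#' Boundary majority identification
#'
#' Second stage of BNNSMOTE: identifies the majority (nonseizure) samples
#' that sit near the class boundary, defined as majority samples whose
#' `k_boundary` nearest neighbours — computed within the dataset with
#' noise-flagged minority rows excluded — contain at least one clean minority
#' sample. The minority samples adjacent to these are the hard-to-learn set.
#'
#' @param data a [labeled_dataset()].
#' @param clean_minority row indices of minority samples that passed
#'   [filter_noise()].
#' @param k_boundary neighbourhood size.
#' @return integer vector of majority row indices (possibly empty).
#' @export
boundary_majority <- function(data, clean_minority, k_boundary = 5L) {
  assert_that(inherits(data, "labeled_dataset"), "data must be a labeled_dataset")
  assert_that(length(clean_minority) > 0L, "clean_minority must be nonempty")
  majority <- majority_indices(data)
  keep <- sort(c(majority, as.integer(clean_minority)))
  nt <- compute_neighbors(data$X[keep, , drop = FALSE], NULL,
                          k = min(k_boundary, length(keep) - 1L))
  is_clean_min <- keep %in% clean_minority
  maj_pos <- which(keep %in% majority)
  hit <- vapply(maj_pos, function(p) any(is_clean_min[nt$indices[p, ]]), logical(1))
  keep[maj_pos[hit]]
}

#' Hard-to-learn (danger) minority set
#'
#' Third stage of BNNSMOTE: the clean minority samples that appear among the
#' `k_danger` nearest neighbours of at least one boundary-majority sample.
#' These boundary-adjacent seizure samples are the ones a classifier finds
#' hard to learn, and become the synthesis parents.
#'
#' If `boundary_maj` is empty the borderline rule is used as a fallback:
#' clean minority samples whose `k_danger`-neighbourhoods contain at least
#' `k_danger / 2` but fewer than `k_danger` majority samples.
#'
#' @param data a [labeled_dataset()].
#' @param clean_minority row indices from [filter_noise()].
#' @param boundary_maj row indices from [boundary_majority()].
#' @param k_danger neighbourhood size.
#' @return integer vector of danger minority row indices (subset of
#'   `clean_minority`; possibly empty).
#' @export
danger_minority <- function(data, clean_minority, boundary_maj, k_danger = 5L) {
  assert_that(inherits(data, "labeled_dataset"), "data must be a labeled_dataset")
  assert_that(length(clean_minority) > 0L, "clean_minority must be nonempty")
  majority <- majority_indices(data)
  keep <- sort(c(majority, as.integer(clean_minority)))
  nt <- compute_neighbors(data$X[keep, , drop = FALSE], NULL,
                          k = min(k_danger, length(keep) - 1L))
  if (length(boundary_maj) > 0L) {
    b_pos <- match(as.integer(boundary_maj), keep)
    hit_pos <- unique(as.integer(nt$indices[b_pos, , drop = FALSE]))
    hits <- keep[hit_pos]
    sort(intersect(hits, clean_minority))
  } else {
    # borderline fallback: minority with half-to-all-but-one majority neighbours
    c_pos <- match(as.integer(clean_minority), keep)
    k_eff <- ncol(nt$indices)
    m_prime <- vapply(c_pos, function(p) {
      sum(data$y[keep[nt$indices[p, ]]] == 0L)
    }, integer(1))
    danger <- m_prime >= k_eff / 2 & m_prime < k_eff
    sort(as.integer(clean_minority)[danger])
  }
}

safe_sample1 <- function(x) x[sample.int(length(x), 1L)]

#' Synthesise minority samples by convex interpolation
#'
#' Each synthetic sample is `x_p + delta * (x_q - x_p)` with the parent `p`
#' drawn uniformly from the danger set, the partner `q` drawn uniformly from
#' the clean minority set excluding `p` (or from the parent's `k_danger`
#' minority nearest neighbours when `partner_mode = "knn"`), and
#' `delta ~ Uniform(0, 1)`. Per synthetic row the random draws are consumed
#' in the documented order parent, partner, delta, so runs are replayable
#' from the seed.
#'
#' @param data a [labeled_dataset()].
#' @param danger parent candidate row indices; if empty, `clean_minority`
#'   is used as the parent pool (with a warning).
#' @param clean_minority partner candidate row indices.
#' @param n_new number of samples to synthesise.
#' @param seed optional integer seed (see [resample_config()]).
#' @param partner_mode `"uniform"` or `"knn"`.
#' @param k_danger neighbour pool size for `partner_mode = "knn"`.
#' @return list with `X_synth` (numeric matrix `n_new x d`) and `provenance`
#'   (data frame with columns `parent`, `partner`, `delta`).
#' @export
synthesize_samples <- function(data, danger, clean_minority, n_new,
                               seed = NULL, partner_mode = "uniform",
                               k_danger = 5L) {
  assert_that(inherits(data, "labeled_dataset"), "data must be a labeled_dataset")
  assert_that(is_count(n_new) && n_new >= 0L, "n_new must be a nonnegative integer")
  clean_minority <- as.integer(clean_minority)
  danger <- as.integer(danger)
  if (length(clean_minority) < 2L) {
    stop("synthesis impossible: fewer than two clean minority samples",
         call. = FALSE)
  }
  parents_pool <- danger
  if (length(parents_pool) == 0L) {
    warning("danger set empty; synthesising from all clean minority samples",
            call. = FALSE)
    parents_pool <- clean_minority
  }

  knn_pools <- NULL
  if (partner_mode == "knn") {
    k_eff <- min(k_danger, length(clean_minority) - 1L)
    nt <- compute_neighbors(data$X[clean_minority, , drop = FALSE], NULL, k = k_eff)
    knn_pools <- lapply(seq_along(clean_minority), function(i) {
      clean_minority[nt$indices[i, ]]
    })
    names(knn_pools) <- as.character(clean_minority)
  }

  d <- ncol(data$X)
  X_synth <- matrix(NA_real_, n_new, d)
  parent <- integer(n_new); partner <- integer(n_new); delta <- numeric(n_new)
  with_seed(seed, {
    for (i in seq_len(if (n_new > 0L) n_new else 0L)) {
      p <- safe_sample1(parents_pool)
      pool <- if (is.null(knn_pools)) setdiff(clean_minority, p)
              else setdiff(knn_pools[[as.character(p)]], p)
      if (length(pool) == 0L) pool <- setdiff(clean_minority, p)
      q <- safe_sample1(pool)
      dl <- stats::runif(1)
      X_synth[i, ] <- data$X[p, ] + dl * (data$X[q, ] - data$X[p, ])
      parent[i] <- p; partner[i] <- q; delta[i] <- dl
    }
  })
  list(X_synth = X_synth,
       provenance = data.frame(parent = parent, partner = partner, delta = delta))
}

#' BNNSMOTE oversampling
#'
#' The borderline nearest-neighbour synthetic minority oversampling
#' technique. Composes three stages: (1) noise minority samples — those
#' with all-majority neighbourhoods — are filtered out; (2) boundary
#' majority samples are identified via nearest neighbours and the clean
#' minority samples adjacent to them form the hard-to-learn set; (3) new
#' minority samples are synthesised by convex interpolation between a
#' hard-to-learn parent and a randomly chosen clean minority partner, until
#' the minority/majority ratio reaches `cfg$target_ratio`.
#'
#' Noise rows are removed from the output (set `keep_noise = TRUE` in the
#' config to retain them for ablation); they are never used as parents or
#' partners. Majority rows pass through unmodified, in their original order.
#'
#' @param data a [labeled_dataset()]; label 1 = seizure/minority.
#' @param cfg a [resample_config()].
#' @return a `resample_result` with elements `dataset`, `n_synth`,
#'   `noise_indices`, `danger_indices`, `provenance` (indices refer to rows
#'   of the input `data`), `method` and `config`.
#' @examples
#' gen <- make_clusters(cluster_config(n_major = 60, n_minor = 8, seed = 1))
#' res <- bnnsmote(gen$dataset, resample_config(seed = 1))
#' res
#' @export
bnnsmote <- function(data, cfg = resample_config()) {
  guard <- resample_guard(data, cfg, "bnnsmote")
  n_maj <- sum(data$y == 0L)

  fl <- filter_noise(data, cfg$k_noise)
  clean <- fl$clean_minority
  noise <- fl$noise
  if (!is.null(guard)) {
    # balanced or inverted input: no synthesis, but noise is still filtered
    return(noop_result(data, "bnnsmote", cfg, noise_indices = noise,
                       drop_noise = !cfg$keep_noise))
  }
  if (length(clean) < 2L) {
    stop("bnnsmote: fewer than two clean minority samples after noise filtering",
         call. = FALSE)
  }

  boundary <- boundary_majority(data, clean, cfg$k_boundary)
  danger <- danger_minority(data, clean, boundary, cfg$k_danger)

  n_retained <- length(clean) + if (cfg$keep_noise) length(noise) else 0L
  n_new <- n_synth_needed(n_retained, n_maj, cfg$target_ratio)

  syn <- synthesize_samples(data, danger, clean, n_new, seed = cfg$seed,
                            partner_mode = cfg$partner_mode,
                            k_danger = cfg$k_danger)

  keep_rows <- if (cfg$keep_noise) seq_len(nrow(data$X))
               else setdiff(seq_len(nrow(data$X)), noise)
  out <- bind_synthetic(data, keep_rows, syn$X_synth)
  new_resample_result(out, n_new, noise, danger, syn$provenance,
                      "bnnsmote", cfg)
}
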