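# Reference resamplers: random oversampling, SMOTE, Borderline-SMOTE-1 and
# SVM-SMOTE. All share the exact kNN backend, the balance contract
# (minority count -> round(target_ratio * majority count)) and the
# provenance format of BNNSMOTE.

#' Random oversampling
#'
#' Balances the dataset by duplicating minority rows uniformly at random
#' with replacement. Duplicates are recorded in the provenance with
#' `partner = parent` and `delta = 0`.
#'
#' @inheritParams bnnsmote
#' @return a `resample_result`.
#' @export
ros <- function(data, cfg = resample_config()) {
  guard <- resample_guard(data, cfg, "ros")
  if (!is.null(guard)) return(guard)
  minority <- minority_indices(data)
  n_new <- n_synth_needed(length(minority), sum(data$y == 0L), cfg$target_ratio)
  parent <- with_seed(cfg$seed,
    minority[sample.int(length(minority), n_new, replace = TRUE)])
  X_synth <- data$X[parent, , drop = FALSE]
  prov <- data.frame(parent = parent, partner = parent,
                     delta = rep(0, n_new))
  out <- bind_synthetic(data, seq_len(nrow(data$X)), X_synth)
  new_resample_result(out, n_new, integer(0), integer(0), prov, "ros", cfg)
}

# Shared SMOTE-style synthesis: parents drawn uniformly from `parent_pool`,
# partner from the parent's k nearest neighbours within the minority class,
# delta ~ U(0,1). Draw order per row: parent, partner, delta.
smote_synthesize <- function(data, parent_pool, minority, n_new, k, seed) {
  if (length(minority) < 2L) {
    stop("synthesis impossible: fewer than two minority samples", call. = FALSE)
  }
  k_eff <- min(k, length(minority) - 1L)
  nt <- compute_neighbors(data$X[minority, , drop = FALSE], NULL, k = k_eff)
  pools <- lapply(seq_along(minority), function(i) minority[nt$indices[i, ]])
  names(pools) <- as.character(minority)

  d <- ncol(data$X)
  X_synth <- matrix(NA_real_, n_new, d)
  parent <- integer(n_new); partner <- integer(n_new); delta <- numeric(n_new)
  with_seed(seed, {
    for (i in seq_len(if (n_new > 0L) n_new else 0L)) {
      p <- safe_sample1(parent_pool)
      q <- safe_sample1(pools[[as.character(p)]])
      dl <- stats::runif(1)
      X_synth[i, ] <- data$X[p, ] + dl * (data$X[q, ] - data$X[p, ])
      parent[i] <- p; partner[i] <- q; delta[i] <- dl
    }
  })
  list(X_synth = X_synth,
       provenance = data.frame(parent = parent, partner = partner, delta = delta))
}

#' SMOTE oversampling
#'
#' Classic synthetic minority oversampling: each synthetic row interpolates
#' between a minority parent (drawn uniformly from all minority rows) and
#' one of its `k_danger` minority-class nearest neighbours, with
#' `delta ~ Uniform(0, 1)`.
#'
#' @inheritParams bnnsmote
#' @return a `resample_result`.
#' @export
smote <- function(data, cfg = resample_config()) {
  guard <- resample_guard(data, cfg, "smote")
  if (!is.null(guard)) return(guard)
  minority <- minority_indices(data)
  n_new <- n_synth_needed(length(minority), sum(data$y == 0L), cfg$target_ratio)
  syn <- smote_synthesize(data, minority, minority, n_new, cfg$k_danger, cfg$seed)
  out <- bind_synthetic(data, seq_len(nrow(data$X)), syn$X_synth)
  new_resample_result(out, n_new, integer(0), integer(0), syn$provenance,
                      "smote", cfg)
}

#' Borderline-SMOTE oversampling
#'
#' Borderline-SMOTE-1: only minority samples near the class boundary are
#' oversampled. A minority sample is in the DANGER set when `m'`, the number
#' of majority samples among its `k_danger` nearest neighbours in the full
#' dataset, satisfies `k_danger / 2 <= m' < k_danger`. Samples with
#' `m' = k_danger` are treated as noise-like and never used as parents.
#' Parents are drawn uniformly from DANGER; partners from the parent's
#' minority nearest neighbours. An empty DANGER set yields a no-op with a
#' warning.
#'
#' @inheritParams bnnsmote
#' @return a `resample_result` (with `danger_indices` filled in).
#' @export
blsmote <- function(data, cfg = resample_config()) {
  guard <- resample_guard(data, cfg, "blsmote")
  if (!is.null(guard)) return(guard)
  minority <- minority_indices(data)
  nt <- compute_neighbors(data$X, NULL, k = cfg$k_danger)
  m_prime <- vapply(minority, function(i) sum(data$y[nt$indices[i, ]] == 0L),
                    integer(1))
  danger <- minority[m_prime >= cfg$k_danger / 2 & m_prime < cfg$k_danger]
  if (length(danger) == 0L) {
    warning("blsmote: DANGER set empty; no samples synthesised", call. = FALSE)
    return(noop_result(data, "blsmote", cfg))
  }
  n_new <- n_synth_needed(length(minority), sum(data$y == 0L), cfg$target_ratio)
  syn <- smote_synthesize(data, danger, minority, n_new, cfg$k_danger, cfg$seed)
  out <- bind_synthetic(data, seq_len(nrow(data$X)), syn$X_synth)
  new_resample_result(out, n_new, integer(0), danger, syn$provenance,
                      "blsmote", cfg)
}

#' SVM-SMOTE oversampling
#'
#' Approximates the class boundary with the support vectors of a soft-margin
#' linear-kernel support vector machine trained on the input: the
#' minority-class support vectors are the synthesis parents, and synthetic
#' rows interpolate from a parent towards one of its minority nearest
#' neighbours (the interpolation-only variant).
#'
#' @inheritParams bnnsmote
#' @param cost soft-margin cost parameter passed to the SVM fit.
#' @return a `resample_result` (with `danger_indices` = minority support
#'   vector rows).
#' @export
svmsmote <- function(data, cfg = resample_config(), cost = 1) {
  guard <- resample_guard(data, cfg, "svmsmote")
  if (!is.null(guard)) return(guard)
  minority <- minority_indices(data)
  fit <- tryCatch(
    e1071::svm(x = data$X, y = factor(data$y, levels = c(0L, 1L)),
               kernel = "linear", scale = FALSE, cost = cost),
    error = function(e) {
      stop("svmsmote: support vector machine fit failed: ",
           conditionMessage(e), call. = FALSE)
    })
  sv_rows <- fit$index
  parents <- intersect(sv_rows, minority)
  if (length(parents) == 0L) {
    warning("svmsmote: no minority support vectors; using all minority rows",
            call. = FALSE)
    parents <- minority
  }
  n_new <- n_synth_needed(length(minority), sum(data$y == 0L), cfg$target_ratio)
  syn <- smote_synthesize(data, parents, minority, n_new, cfg$k_danger, cfg$seed)
  out <- bind_synthetic(data, seq_len(nrow(data$X)), syn$X_synth)
  new_resample_result(out, n_new, integer(0), sort(parents), syn$provenance,
                      "svmsmote", cfg)
}

#' Resampler registry
#'
#' Name-to-function registry used for dispatch by [cross_validate()],
#' [run_pipeline()] and the command-line interface. `"none"` is the
#' identity resampler (pass-through, no synthesis).
#'
#' @return named list of resampler functions, each with signature
#'   `function(data, cfg)`.
#' @export
resampler_registry <- function() {
  list(
    none = function(data, cfg = resample_config()) {
      noop_result(data, "none", cfg)
    },
    ros = ros, smote = smote, blsmote = blsmote,
    svmsmote = svmsmote, bnnsmote = bnnsmote
  )
}

#' @rdname resampler_registry
#' @param name resampler name, one of
#'   `"none"`, `"ros"`, `"smote"`, `"blsmote"`, `"svmsmote"`, `"bnnsmote"`.
#' @export
get_resampler <- function(name) {
  reg <- resampler_registry()
  if (!name %in% names(reg)) {
    stop(sprintf("unknown resampler '%s' (available: %s)", name,
                 paste(names(reg), collapse = ", ")), call. = FALSE)
  }
  reg[[name]]
}
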