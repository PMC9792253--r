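# Trainer for model graphs: parameter initialisation, full forward /
# backward over the op list, Adam updates, and the user-facing
# train_model() / predict() pair.

# He-normal initialisation for convs, small-uniform for the head.
nn_init <- function(graph, seed = 1L) {
  with_seed(seed, {
    params <- vector("list", length(graph$ops))
    bn_state <- vector("list", length(graph$ops))
    for (i in seq_along(graph$ops)) {
      op <- graph$ops[[i]]
      if (op$kind == "conv") {
        fan_in <- op$kernel * (op$in_ch %/% op$groups)
        sd <- sqrt(2 / fan_in)
        if (op$groups == 1L) {
          params[[i]] <- list(W = matrix(stats::rnorm(op$out_ch * op$in_ch * op$kernel,
                                                      sd = sd),
                                         op$out_ch, op$in_ch * op$kernel))
        } else {
          params[[i]] <- list(w = matrix(stats::rnorm(op$in_ch * op$kernel, sd = sd),
                                         op$in_ch, op$kernel))
        }
      } else if (op$kind == "bn") {
        params[[i]] <- list(gamma = rep(1, op$out_ch), beta = rep(0, op$out_ch))
        bn_state[[i]] <- list(mean = rep(0, op$out_ch), var = rep(1, op$out_ch))
      } else if (op$kind == "linear") {
        lim <- sqrt(1 / op$in_ch)
        params[[i]] <- list(W = matrix(stats::runif(op$out_ch * op$in_ch, -lim, lim),
                                       op$out_ch, op$in_ch),
                            b = rep(0, op$out_ch))
      }
    }
    list(params = params, bn_state = bn_state)
  })
}

# Forward pass. x: (C, L, N). Returns logits (K, N) and, when
# keep_cache = TRUE, the per-op caches needed for the backward pass.
nn_forward <- function(graph, params, bn_state, x, training = FALSE,
                       keep_cache = FALSE, momentum = 0.1) {
  caches <- if (keep_cache) vector("list", length(graph$ops)) else NULL
  skip <- NULL
  for (i in seq_along(graph$ops)) {
    op <- graph$ops[[i]]
    if (op$kind == "conv") {
      if (op$groups == 1L) {
        r <- conv1d_fwd(x, params[[i]]$W, op$kernel, op$stride)
      } else {
        r <- dwconv1d_fwd(x, params[[i]]$w, op$kernel, op$stride)
      }
      x <- r$y
      if (keep_cache) caches[[i]] <- r$cache
    } else if (op$kind == "bn") {
      r <- bn_fwd(x, params[[i]]$gamma, params[[i]]$beta, bn_state[[i]],
                  training, momentum)
      x <- r$y
      bn_state[[i]] <- r$state
      if (keep_cache) caches[[i]] <- r$cache
    } else if (op$kind == "relu6") {
      r <- relu6_fwd(x)
      x <- r$y
      if (keep_cache) caches[[i]] <- r$cache
    } else if (op$kind == "res_save") {
      skip <- x
    } else if (op$kind == "res_add") {
      x <- x + skip
    } else if (op$kind == "avgpool") {
      r <- avgpool_fwd(x)
      x <- r$y
      if (keep_cache) caches[[i]] <- r$cache
    } else if (op$kind == "linear") {
      r <- linear_fwd(x, params[[i]]$W, params[[i]]$b)
      x <- r$y
      if (keep_cache) caches[[i]] <- r$cache
    }
  }
  list(logits = x, caches = caches, bn_state = bn_state)
}

# Backward pass; returns gradients in the same structure as params.
nn_backward <- function(graph, params, caches, dlogits) {
  grads <- vector("list", length(graph$ops))
  dx <- dlogits
  dskip <- NULL
  for (i in rev(seq_along(graph$ops))) {
    op <- graph$ops[[i]]
    if (op$kind == "linear") {
      r <- linear_bwd(dx, params[[i]]$W, caches[[i]])
      grads[[i]] <- list(W = r$dW, b = r$db)
      dx <- r$dx
    } else if (op$kind == "avgpool") {
      dx <- avgpool_bwd(dx, caches[[i]])
    } else if (op$kind == "res_add") {
      dskip <- dx                      # gradient flows to both branches
    } else if (op$kind == "res_save") {
      dx <- dx + dskip
      dskip <- NULL
    } else if (op$kind == "relu6") {
      dx <- relu6_bwd(dx, caches[[i]])
    } else if (op$kind == "bn") {
      r <- bn_bwd(dx, params[[i]]$gamma, caches[[i]])
      grads[[i]] <- list(gamma = r$dgamma, beta = r$dbeta)
      dx <- r$dx
    } else if (op$kind == "conv") {
      if (op$groups == 1L) {
        r <- conv1d_bwd(dx, params[[i]]$W, caches[[i]])
        grads[[i]] <- list(W = r$dW)
      } else {
        r <- dwconv1d_bwd(dx, params[[i]]$w, caches[[i]])
        grads[[i]] <- list(w = r$dw)
      }
      dx <- r$dx
    }
  }
  grads
}

adam_init <- function(params) {
  lapply(params, function(p) {
    if (is.null(p)) return(NULL)
    lapply(p, function(a) list(m = a * 0, v = a * 0))
  })
}

adam_step <- function(params, grads, state, lr, t, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  for (i in seq_along(params)) {
    if (is.null(params[[i]])) next
    for (nm in names(params[[i]])) {
      g <- grads[[i]][[nm]]
      st <- state[[i]][[nm]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g^2
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      params[[i]][[nm]] <- params[[i]][[nm]] - lr * mhat / (sqrt(vhat) + eps)
      state[[i]][[nm]] <- st
    }
  }
  list(params = params, state = state)
}

#' Training hyperparameters
#'
#' Defaults: adaptive-moment (Adam) optimisation at learning rate 1e-3,
#' batch size 64, 30 epochs.
#'
#' @param epochs,batch_size,lr,seed the usual suspects.
#' @return a named list.
#' @export
train_hyperparams <- function(epochs = 30L, batch_size = 64L, lr = 1e-3,
                              seed = 1L) {
  list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
       lr = lr, seed = as.integer(seed))
}

# segment_set (single channel) -> (C, L, N) array
segs_to_input <- function(segs) {
  d <- dim(segs$segments)
  assert_that(d[2] == 1L,
              "the network consumes single-channel windows; use segment_channel()")
  aperm(segs$segments, c(2, 3, 1))
}

#' Train a network on labeled EEG windows
#'
#' Minimises the two-class cross-entropy of the instantiated model on
#' single-channel fixed-length windows with Adam, deterministically for a
#' given seed. Windows are standardised by the training set's global mean
#' and standard deviation (stored in the fitted model).
#'
#' @param graph a `model_graph` from [build_model()]; its spec's
#'   `input_length` must match the window length of `train_segs`.
#' @param train_segs a single-channel `segment_set` containing both classes.
#' @param hp hyperparameters from [train_hyperparams()].
#' @param verbose print per-epoch loss.
#' @return an object of class `onednet_fit` with elements `graph`,
#'   `params`, `bn_state`, `norm`, `loss_history` (mean cross-entropy per
#'   epoch) and `hp`.
#' @export
train_model <- function(graph, train_segs, hp = train_hyperparams(),
                        verbose = FALSE) {
  assert_that(inherits(graph, "model_graph"), "graph must be a model_graph")
  assert_that(inherits(train_segs, "segment_set"), "train_segs must be a segment_set")
  if (length(unique(train_segs$labels)) < 2L) {
    stop("training data must contain both classes", call. = FALSE)
  }
  x_all <- segs_to_input(train_segs)
  assert_that(dim(x_all)[2] == graph$spec$input_length,
              "window length does not match the model's input_length")
  mu <- mean(x_all); sdv <- stats::sd(x_all)
  if (sdv == 0) sdv <- 1
  x_all <- (x_all - mu) / sdv
  labels <- train_segs$labels + 1L           # class index 1 = nonictal, 2 = ictal
  n <- dim(x_all)[3]

  init <- nn_init(graph, seed = hp$seed)
  params <- init$params
  bn_state <- init$bn_state
  opt <- adam_init(params)
  loss_hist <- numeric(hp$epochs)
  t_step <- 0L

  with_seed(derive_seed(hp$seed, 1L), {
    for (ep in seq_len(hp$epochs)) {
      ord <- sample.int(n)
      losses <- c()
      for (b0 in seq(1L, n, by = hp$batch_size)) {
        idx <- ord[b0:min(b0 + hp$batch_size - 1L, n)]
        xb <- x_all[, , idx, drop = FALSE]
        fw <- nn_forward(graph, params, bn_state, xb, training = TRUE,
                         keep_cache = TRUE)
        bn_state <- fw$bn_state
        ce <- softmax_ce(fw$logits, labels[idx])
        grads <- nn_backward(graph, params, fw$caches, ce$dlogits)
        t_step <- t_step + 1L
        upd <- adam_step(params, grads, opt, hp$lr, t_step)
        params <- upd$params
        opt <- upd$state
        losses <- c(losses, ce$loss)
      }
      loss_hist[ep] <- mean(losses)
      if (verbose) message(sprintf("epoch %d/%d  loss %.4f", ep, hp$epochs,
                                   loss_hist[ep]))
    }
  })

  structure(list(graph = graph, params = params, bn_state = bn_state,
                 norm = c(mean = mu, sd = sdv), hp = hp,
                 loss_history = loss_hist),
            class = "onednet_fit")
}

#' Predict seizure scores for EEG windows
#'
#' @param object an `onednet_fit` from [train_model()].
#' @param segs a single-channel `segment_set` with matching window length.
#' @param ... unused.
#' @return list with `scores` (probability of the seizure class, in
#'   `[0, 1]`) and `labels` (`scores >= 0.5`).
#' @export
predict.onednet_fit <- function(object, segs, ...) {
  x <- segs_to_input(segs)
  x <- (x - object$norm["mean"]) / object$norm["sd"]
  fw <- nn_forward(object$graph, object$params, object$bn_state, x,
                   training = FALSE)
  ce_z <- fw$logits
  z <- ce_z - matrix(apply(ce_z, 2, max), nrow(ce_z), ncol(ce_z), byrow = TRUE)
  p <- exp(z)
  p <- p / matrix(colSums(p), nrow(p), ncol(p), byrow = TRUE)
  scores <- p[2, ]
  list(scores = scores, labels = as.integer(scores >= 0.5))
}

#' @export
print.onednet_fit <- function(x, ...) {
  cat(sprintf("<onednet_fit> %.0f parameters | %d epochs, final loss %.4f\n",
              x$graph$n_params, length(x$loss_history),
              x$loss_history[length(x$loss_history)]))
  invisible(x)
}

#' 1-nearest-neighbour reference classifier
#'
#' Dependency-free surrogate classifier used for fast resampler evaluation:
#' each test point inherits the label of its nearest training point (exact
#' search through [compute_neighbors()]).
#'
#' @param train a [labeled_dataset()].
#' @param test_X numeric matrix of test points.
#' @return integer vector of predicted 0/1 labels.
#' @export
knn_classifier <- function(train, test_X) {
  assert_that(inherits(train, "labeled_dataset"), "train must be a labeled_dataset")
  nt <- compute_neighbors(train$X, as.matrix(test_X), k = 1L)
  train$y[nt$indices[, 1L]]
}
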