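# Reverse-mode primitives for the 1D network trainer. Activations are
# arrays of dim (channels, length, batch); convolutions use "same" padding
# (pad = (kernel - 1) / 2). Standard convolutions go through an im2col
# matrix multiplication; depthwise convolutions are accumulated tap by tap
# with channel-wise recycling. All functions are internal.

pad1d <- function(x, p) {
  if (p == 0L) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1], d[2] + 2L * p, d[3]))
  xp[, (p + 1L):(p + d[2]), ] <- x
  xp
}

# im2col: (C, Lp, N) -> (C*k, L_out*N); column layout channel-fastest.
im2col <- function(xp, k, starts) {
  d <- dim(xp)
  L_out <- length(starts)
  cols <- array(0, c(d[1], k, L_out, d[3]))
  for (j in seq_len(k)) {
    cols[, j, , ] <- xp[, starts + j - 1L, , drop = FALSE]
  }
  dim(cols) <- c(d[1] * k, L_out * d[3])
  cols
}

# W: matrix (C_out) x (C_in*k), column index c + C_in*(j-1)
conv1d_fwd <- function(x, W, kernel, stride) {
  d <- dim(x)
  p <- (kernel - 1L) %/% 2L
  xp <- pad1d(x, p)
  L_out <- conv_out_len(d[2], kernel, stride)
  starts <- seq(1L, by = stride, length.out = L_out)
  Xc <- im2col(xp, kernel, starts)
  out <- W %*% Xc
  dim(out) <- c(nrow(W), L_out, d[3])
  list(y = out, cache = list(Xc = Xc, in_dim = d, kernel = kernel,
                             stride = stride, starts = starts, p = p))
}

conv1d_bwd <- function(dY, W, cache) {
  d <- cache$in_dim
  k <- cache$kernel
  L_out <- length(cache$starts)
  dY_mat <- matrix(dY, nrow = nrow(W))
  dW <- dY_mat %*% t(cache$Xc)
  dXc <- t(W) %*% dY_mat                      # (C_in*k) x (L_out*N)
  dim(dXc) <- c(d[1], k, L_out, d[3])
  dxp <- array(0, c(d[1], d[2] + 2L * cache$p, d[3]))
  for (j in seq_len(k)) {
    idx <- cache$starts + j - 1L
    sl <- dXc[, j, , , drop = FALSE]
    dim(sl) <- c(d[1], L_out, d[3])
    dxp[, idx, ] <- dxp[, idx, , drop = FALSE] + sl
  }
  dx <- if (cache$p > 0L) dxp[, (cache$p + 1L):(cache$p + d[2]), , drop = FALSE]
        else dxp
  list(dx = dx, dW = dW)
}

# depthwise: w matrix (C x k)
dwconv1d_fwd <- function(x, w, kernel, stride) {
  d <- dim(x)
  p <- (kernel - 1L) %/% 2L
  xp <- pad1d(x, p)
  L_out <- conv_out_len(d[2], kernel, stride)
  starts <- seq(1L, by = stride, length.out = L_out)
  out <- array(0, c(d[1], L_out, d[3]))
  for (j in seq_len(kernel)) {
    out <- out + w[, j] * xp[, starts + j - 1L, , drop = FALSE]
  }
  list(y = out, cache = list(xp = xp, in_dim = d, kernel = kernel,
                             stride = stride, starts = starts, p = p))
}

dwconv1d_bwd <- function(dY, w, cache) {
  d <- cache$in_dim
  C <- d[1]
  dw <- matrix(0, C, cache$kernel)
  dxp <- array(0, dim(cache$xp))
  for (j in seq_len(cache$kernel)) {
    idx <- cache$starts + j - 1L
    sl <- cache$xp[, idx, , drop = FALSE]
    dw[, j] <- rowSums(matrix(dY * sl, C))
    dxp[, idx, ] <- dxp[, idx, , drop = FALSE] + w[, j] * dY
  }
  dx <- if (cache$p > 0L) dxp[, (cache$p + 1L):(cache$p + d[2]), , drop = FALSE]
        else dxp
  list(dx = dx, dw = dw)
}

bn_fwd <- function(x, gamma, beta, state, training, momentum = 0.1,
                   eps = 1e-5) {
  C <- dim(x)[1]
  if (training) {
    xm <- matrix(x, C)
    mu <- rowMeans(xm)
    v <- rowMeans((xm - mu)^2)
    state$mean <- (1 - momentum) * state$mean + momentum * mu
    state$var <- (1 - momentum) * state$var + momentum * v
  } else {
    mu <- state$mean
    v <- state$var
  }
  ivar <- 1 / sqrt(v + eps)
  xhat <- (x - mu) * ivar
  y <- gamma * xhat + beta
  list(y = y, state = state,
       cache = list(xhat = xhat, ivar = ivar, C = C))
}

bn_bwd <- function(dY, gamma, cache) {
  C <- cache$C
  M <- length(dY) / C
  dY_m <- matrix(dY, C)
  xhat_m <- matrix(cache$xhat, C)
  dgamma <- rowSums(dY_m * xhat_m)
  dbeta <- rowSums(dY_m)
  dxhat <- dY * gamma
  dxhat_m <- matrix(dxhat, C)
  s1 <- rowSums(dxhat_m)
  s2 <- rowSums(dxhat_m * xhat_m)
  dx <- (cache$ivar / M) * (M * dxhat - s1 - cache$xhat * s2)
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

relu6_fwd <- function(x) {
  y <- pmin(pmax(x, 0), 6)
  list(y = y, cache = (x > 0) & (x < 6))
}

relu6_bwd <- function(dY, mask) dY * mask

avgpool_fwd <- function(x) {
  d <- dim(x)
  y <- apply(x, c(1, 3), mean)        # (C, N)
  list(y = y, cache = d)
}

avgpool_bwd <- function(dY, d) {
  aperm(array(dY / d[2], c(d[1], d[3], d[2])), c(1, 3, 2))
}

linear_fwd <- function(x, W, b) {
  list(y = W %*% x + b, cache = x)
}

linear_bwd <- function(dY, W, x) {
  list(dx = t(W) %*% dY, dW = dY %*% t(x), db = rowSums(dY))
}

# softmax cross-entropy; labels are 1-based class indices, logits (K, N)
softmax_ce <- function(logits, labels) {
  K <- nrow(logits); N <- ncol(logits)
  z <- logits - matrix(apply(logits, 2, max), K, N, byrow = TRUE)
  ez <- exp(z)
  p <- ez / matrix(colSums(ez), K, N, byrow = TRUE)
  sel <- cbind(labels, seq_len(N))
  loss <- -mean(log(pmax(p[sel], 1e-12)))
  dlogits <- p
  dlogits[sel] <- dlogits[sel] - 1
  list(loss = loss, p = p, dlogits = dlogits / N)
}
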