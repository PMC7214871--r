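# Internal layer primitives for the rollout ANN.
#
# Activations of spatial nodes are arrays (batch, H, W, channels); flat
# nodes use (batch, features) matrices. Convolutions are implemented by
# im2col + matrix multiply; the im2col column order is offset-major,
# channel-minor (for offset o and input channel c, column (o-1)*C + c),
# which rescaling relies on when scaling rows per source channel.

# X: (B, H, W, C) -> M: (B*H*W, k*k*C); zero padding, stride 1.
# Thin wrapper over the compiled unrolling kernel.
im2col <- function(X, k = 3L) {
  im2col_cpp(X, dim(X), as.integer(k))
}

conv_forward_pre <- function(X, W, b, k = 3L) {
  d <- dim(X)
  Z <- im2col(X, k) %*% W
  Z <- Z + rep(b, each = nrow(Z))
  dim(Z) <- c(d[1], d[2], d[3], ncol(W))
  Z
}

# Rearrange conv weights (k^2*C_in, C_out) into the adjoint layout
# (k^2*C_out, C_in) with spatial offsets reversed, so the data gradient is
# itself a convolution: dX = im2col(dZ) %*% flip_conv_weights(W).
flip_conv_weights <- function(W, C_in, k = 3L) {
  n_off <- k * k
  C_out <- ncol(W)
  arr <- array(W, dim = c(C_in, n_off, C_out))
  arr <- arr[, rev(seq_len(n_off)), , drop = FALSE]
  arr <- aperm(arr, c(3L, 2L, 1L))
  dim(arr) <- c(C_out * n_off, C_in)
  arr
}

conv_backward <- function(X, dZ, W, k = 3L) {
  d <- dim(X)
  M <- im2col(X, k)
  dZm <- dZ; dim(dZm) <- c(d[1] * d[2] * d[3], ncol(W))
  dX <- im2col(dZ, k) %*% flip_conv_weights(W, d[4], k)
  dim(dX) <- d
  list(dW = crossprod(M, dZm), db = colSums(dZm), dX = dX)
}

# 2x2 average pooling, stride 2 (even spatial size required upstream).
avgpool2 <- function(X) {
  d <- dim(X)
  i1 <- seq(1L, d[2], by = 2L); i2 <- i1 + 1L
  j1 <- seq(1L, d[3], by = 2L); j2 <- j1 + 1L
  (X[, i1, j1, , drop = FALSE] + X[, i2, j1, , drop = FALSE] +
     X[, i1, j2, , drop = FALSE] + X[, i2, j2, , drop = FALSE]) / 4
}

avgpool2_backward <- function(dY, H, W) {
  d <- dim(dY)
  dX <- array(0, dim = c(d[1], H, W, d[4]))
  i1 <- seq(1L, H, by = 2L); j1 <- seq(1L, W, by = 2L)
  g <- dY / 4
  dX[, i1, j1, ] <- g
  dX[, i1 + 1L, j1, ] <- g
  dX[, i1, j1 + 1L, ] <- g
  dX[, i1 + 1L, j1 + 1L, ] <- g
  dX
}

# Global average pooling: (B, H, W, C) -> (B, C).
gap_forward <- function(X) {
  d <- dim(X)
  Xm <- X; dim(Xm) <- c(d[1], d[2] * d[3], d[4])
  out <- matrix(0, d[1], d[4])
  for (c in seq_len(d[4])) out[, c] <- rowSums(Xm[, , c, drop = FALSE])
  out / (d[2] * d[3])
}

gap_backward <- function(dG, H, W) {
  d <- dim(dG)
  dX <- array(0, dim = c(d[1], H, W, d[2]))
  for (c in seq_len(d[2])) dX[, , , c] <- dG[, c] / (H * W)
  dX
}

relu <- function(x) { x[x < 0] <- 0; x }

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

# Concatenate along the channel (last) dimension.
concat_spatial <- function(parts) {
  if (length(parts) == 1L) return(parts[[1L]])
  d <- dim(parts[[1L]])
  mats <- lapply(parts, function(p) { dim(p) <- c(d[1] * d[2] * d[3], dim(p)[4]); p })
  out <- do.call(cbind, mats)
  dim(out) <- c(d[1], d[2], d[3], ncol(out))
  out
}

split_channels <- function(X, sizes) {
  d <- dim(X)
  out <- vector("list", length(sizes))
  at <- 0L
  for (i in seq_along(sizes)) {
    out[[i]] <- X[, , , at + seq_len(sizes[i]), drop = FALSE]
    at <- at + sizes[i]
  }
  out
}
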