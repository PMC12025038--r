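# Layer primitives: 2-D cross-correlation ("convolution" in the CNN sense),
# ReLU, max pooling, dropout, nearest upsampling, global average pooling and
# dense layers. Each op has a forward and a matching reverse-mode backward;
# tensors are base arrays in (batch, row, col, channel) order so the inner
# loops reduce to BLAS matrix products.

as_batch <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("input must be an array")
  if (length(d) == 2L) x <- array(x, c(1L, d, 1L))
  else if (length(d) == 3L) x <- array(x, c(1L, d))
  x
}

# im2col: unfold (N,H,W,C) into (N*H*W, k*k*C) patch rows under same
# padding; column order matches the column-major flattening of a
# (k, k, C, C_out) kernel, so convolution is a single GEMM.
im2col <- function(x, k, dilation = 1L) {
  im2col_cpp(x, dim(x), as.integer(k), as.integer(dilation))
}

conv_fwd <- function(x, W, b, dilation = 1L, want_cols = FALSE) {
  x <- as_batch(x)
  dx <- dim(x)
  kw <- dim(W)
  if (length(kw) != 4L || kw[3] != dx[4])
    stop(sprintf("shape mismatch: input is (%s) but kernel is (%s)",
                 paste(dx, collapse = "x"), paste(kw, collapse = "x")),
         call. = FALSE)
  k <- kw[1]; Cout <- kw[4]
  cols <- im2col(x, k, dilation)
  Zm <- cols %*% matrix(W, k * k * kw[3], Cout)
  Zm <- sweep(Zm, 2L, b, "+")
  dim(Zm) <- c(dx[1], dx[2], dx[3], Cout)
  if (want_cols) list(z = Zm, cols = cols, xdim = dx) else Zm
}

#' 2-D same-padding convolution, stride 1
#'
#' Cross-correlates a batch of feature maps with a kernel tensor under
#' zero ('Same') padding, adding a per-output-channel bias: the linear map
#' `z = W * a + b` of a convolutional layer. Supports dilated kernels.
#'
#' @param x Array `(N, H, W, C_in)` (a 2-D or 3-D array is promoted to a
#'   batch of one).
#' @param W Kernel array `(k, k, C_in, C_out)`, `k` odd.
#' @param b Numeric bias of length `C_out`.
#' @param dilation Integer kernel dilation (default 1).
#' @return Pre-activation array `(N, H, W, C_out)`.
#' @export
conv2d_forward <- function(x, W, b, dilation = 1L) {
  conv_fwd(x, W, b, dilation)
}

# Gradients of the convolution. `cache` is the list returned by
# conv_fwd(..., want_cols = TRUE) plus W and dilation; the input gradient
# is itself a same-padding convolution of dz with the rotated kernel.
conv2d_backward <- function(dz, cache, want_dx = TRUE) {
  kw <- dim(cache$W); k <- kw[1]; Cin <- kw[3]; Cout <- kw[4]
  dzm <- dz
  dim(dzm) <- c(prod(dim(dz)[1:3]), Cout)
  dWm <- crossprod(cache$cols, dzm)
  dim(dWm) <- kw
  dx <- NULL
  if (want_dx) {
    Wr <- aperm(cache$W[k:1, k:1, , , drop = FALSE], c(1L, 2L, 4L, 3L))
    dx <- conv_fwd(dz, Wr, numeric(Cin), cache$dilation)
  }
  list(dx = dx, dW = dWm, db = colSums(dzm))
}

#' Rectified linear unit
#'
#' Elementwise `max(0, z)`; output shape equals input shape.
#' @param z Numeric vector, matrix or array.
#' @return Same shape as `z`.
#' @export
relu <- function(z) pmax(z, 0)

relu_backward <- function(da, z) da * (z > 0)

#' Max pooling over square windows
#'
#' Non-overlapping `window x window` pooling with stride `window`; output
#' spatial dims follow the floor rule `floor(H / window)` (trailing rows and
#' columns that do not fill a window are dropped). This floor rule is what
#' realizes the 46 -> 23 -> 11 -> 5 plane sequence of the multi-stream
#' architecture.
#'
#' @param a Array `(N, H, W, C)` (2-D/3-D promoted as in
#'   [conv2d_forward()]).
#' @param window Pooling window size (default 2); must not exceed the
#'   spatial dims.
#' @return Pooled array `(N, floor(H/w), floor(W/w), C)`.
#' @export
maxpool <- function(a, window = 2L) maxpool_forward(a, window)$out

maxpool_forward <- function(a, window = 2L) {
  a <- as_batch(a)
  da <- dim(a)
  w <- as.integer(window)
  if (w < 1L) stop("`window` must be >= 1")
  if (w > da[2] || w > da[3])
    stop(sprintf("pooling window %d larger than input plane %dx%d",
                 w, da[2], da[3]), call. = FALSE)
  Ho <- da[2] %/% w; Wo <- da[3] %/% w
  res <- maxpool_cpp(a, da, w)
  out <- res$out
  dim(out) <- c(da[1], Ho, Wo, da[4])
  list(out = out, argflat = res$argflat, window = w, in_dim = da)
}

maxpool_backward <- function(dout, cache) {
  dx <- numeric(prod(cache$in_dim))
  dx[cache$argflat] <- dout   # windows are disjoint: no collisions
  dim(dx) <- cache$in_dim
  dx
}

# Inverted dropout; identity when not training or rate == 0.
dropout_forward <- function(x, rate, train) {
  if (!train || rate <= 0)
    return(list(out = x, mask = NULL, rate = rate))
  keep <- array(stats::runif(length(x)) >= rate, dim(x))
  list(out = x * keep / (1 - rate), mask = keep, rate = rate)
}

dropout_backward <- function(dout, cache) {
  if (is.null(cache$mask)) return(dout)
  dout * cache$mask / (1 - cache$rate)
}

# Nearest-neighbor upsampling to (out_h, out_w).
upsample_forward <- function(x, out_h, out_w) {
  d <- dim(x)
  ridx <- as.integer(floor((seq_len(out_h) - 1) * d[2] / out_h) + 1L)
  cidx <- as.integer(floor((seq_len(out_w) - 1) * d[3] / out_w) + 1L)
  list(out = x[, ridx, cidx, , drop = FALSE], ridx = ridx, cidx = cidx,
       in_dim = d)
}

upsample_backward <- function(dout, cache) {
  dx <- upsample_backward_cpp(dout, dim(dout), cache$ridx, cache$cidx,
                              cache$in_dim)
  dim(dx) <- cache$in_dim
  dx
}

# Global max pooling (N,H,W,C) -> (N,C); gradient routes to the first
# argmax cell per (sample, channel).
gmp_forward <- function(x) {
  d <- dim(x)
  m <- x
  dim(m) <- c(d[1], d[2] * d[3], d[4])
  out <- matrix(0, d[1], d[4])
  amax <- matrix(0L, d[1], d[4])
  for (ci in seq_len(d[4])) {
    sl <- m[, , ci, drop = FALSE]
    dim(sl) <- c(d[1], d[2] * d[3])
    amax[, ci] <- max.col(sl, ties.method = "first")
    out[, ci] <- sl[cbind(seq_len(d[1]), amax[, ci])]
  }
  list(out = out, amax = amax, in_dim = d)
}

gmp_backward <- function(dout, cache) {
  d <- cache$in_dim
  dx <- array(0, d)
  dim(dx) <- c(d[1], d[2] * d[3], d[4])
  for (ci in seq_len(d[4]))
    dx[cbind(seq_len(d[1]), cache$amax[, ci], ci)] <- dout[, ci]
  dim(dx) <- d
  dx
}

# Global average pooling (N,H,W,C) -> (N,C).
gap_forward <- function(x) {
  d <- dim(x)
  m <- x
  dim(m) <- c(d[1], d[2] * d[3], d[4])
  out <- matrix(0, d[1], d[4])
  for (ci in seq_len(d[4])) {
    sl <- m[, , ci, drop = FALSE]
    dim(sl) <- c(d[1], d[2] * d[3])
    out[, ci] <- rowMeans(sl)
  }
  list(out = out, in_dim = d)
}

gap_backward <- function(dout, cache) {
  d <- cache$in_dim
  dx <- array(0, d)
  sc <- 1 / (d[2] * d[3])
  for (ci in seq_len(d[4])) dx[, , , ci] <- sc * dout[, ci]
  dx
}

# Batch normalization over the rows of an (N, C) feature matrix. Training
# uses batch statistics and returns updated running statistics; evaluation
# uses the stored running statistics (deterministic).
bn_forward <- function(x, gamma, beta, running, train, momentum = 0.1,
                       eps = 1e-3) {
  if (train && nrow(x) > 1L) {
    mu <- colMeans(x)
    v <- colMeans(sweep(x, 2L, mu)^2)
    new_running <- list(mean = (1 - momentum) * running$mean + momentum * mu,
                        var = (1 - momentum) * running$var + momentum * v)
    used_batch <- TRUE
  } else {
    mu <- running$mean
    v <- running$var
    new_running <- running
    used_batch <- FALSE
  }
  s <- sqrt(v + eps)
  xhat <- sweep(sweep(x, 2L, mu), 2L, s, "/")
  out <- sweep(sweep(xhat, 2L, gamma, "*"), 2L, beta, "+")
  list(out = out, xhat = xhat, s = s, gamma = gamma,
       used_batch = used_batch, new_running = new_running)
}

bn_backward <- function(dout, cache) {
  dgamma <- colSums(dout * cache$xhat)
  dbeta <- colSums(dout)
  dxhat <- sweep(dout, 2L, cache$gamma, "*")
  if (cache$used_batch) {
    t1 <- sweep(dxhat, 2L, colMeans(dxhat))
    t2 <- sweep(cache$xhat, 2L, colMeans(dxhat * cache$xhat), "*")
    dx <- sweep(t1 - t2, 2L, cache$s, "/")
  } else {
    dx <- sweep(dxhat, 2L, cache$s, "/")
  }
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

dense_forward <- function(x, W, b) sweep(x %*% W, 2L, b, "+")

dense_backward <- function(dout, x, W) {
  list(dx = dout %*% t(W), dW = crossprod(x, dout), db = colSums(dout))
}

# Softmax cross-entropy over rows of a logit matrix; gradient w.r.t. logits.
softmax_ce <- function(logits, truth_idx) {
  p <- softmax_mat(logits)
  n <- nrow(p)
  picked <- p[cbind(seq_len(n), as.integer(truth_idx))]
  loss <- -mean(log(pmax(picked, 1e-12)))
  d <- p
  i <- cbind(seq_len(n), as.integer(truth_idx))
  d[i] <- d[i] - 1
  list(loss = loss, dlogits = d / n, probs = p)
}
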