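# Shared fixtures and independent oracles for the test suite.

# Brute-force nested-loop cross-correlation with zero 'same' padding,
# stride 1, arbitrary dilation. Independent of the package's GEMM path.
conv_oracle <- function(x, W, b, dilation = 1) {
  dx <- dim(x)
  kw <- dim(W)
  k <- kw[1]
  half <- (k - 1) / 2
  out <- array(0, c(dx[1], dx[2], dx[3], kw[4]))
  for (n in seq_len(dx[1])) for (o in seq_len(kw[4]))
    for (i in seq_len(dx[2])) for (j in seq_len(dx[3])) {
      acc <- b[o]
      for (a in seq_len(k)) for (bb in seq_len(k)) for (c in seq_len(dx[4])) {
        r <- i + dilation * (a - 1 - half)
        cc <- j + dilation * (bb - 1 - half)
        if (r >= 1 && r <= dx[2] && cc >= 1 && cc <= dx[3])
          acc <- acc + x[n, r, cc, c] * W[a, bb, c, o]
      }
      out[n, i, j, o] <- acc
    }
  out
}

# Exhaustive window-scan max pooling (floor rule).
maxpool_oracle <- function(x, w) {
  dx <- dim(x)
  Ho <- dx[2] %/% w
  Wo <- dx[3] %/% w
  out <- array(0, c(dx[1], Ho, Wo, dx[4]))
  for (n in seq_len(dx[1])) for (c in seq_len(dx[4]))
    for (i in seq_len(Ho)) for (j in seq_len(Wo))
      out[n, i, j, c] <- max(x[n, (i - 1) * w + seq_len(w),
                               (j - 1) * w + seq_len(w), c])
  out
}

# Two-pass population standard deviation.
pop_sd_oracle <- function(v) {
  m <- sum(v) / length(v)
  sqrt(sum((v - m)^2) / length(v))
}

# Explicit double-sum cross-entropy.
ce_oracle <- function(probs, truth_idx) {
  y <- matrix(0, nrow(probs), ncol(probs))
  y[cbind(seq_len(nrow(probs)), truth_idx)] <- 1
  acc <- 0
  for (i in seq_len(nrow(probs)))
    for (c in seq_len(ncol(probs)))
      acc <- acc - y[i, c] * log(max(probs[i, c], 1e-12))
  acc / nrow(probs)
}

# Small multi-stream model on a 12x12 plane for fast training tests.
tiny_spec <- function(dropout = 0.25) {
  multi_stream_spec(channels = c(2L, 2L, 2L, 2L), input_size = 12L,
                    dropout = dropout)
}

tiny_dataset <- function(n = 16, seed = 5) {
  generate_dataset(n, rep(0.25, 4), tiny_phantom_spec(), seed = seed)
}

tiny_phantom_spec <- function() {
  phantom_spec(image_size = 12L, kidney_axes = c(4, 3),
               lesion_params = list(
                 cyst = list(radius = c(1.5, 2.5), offset = -0.25),
                 stone = list(radius = c(1, 1.5), offset = 0.4),
                 tumor = list(radius = c(1.5, 3), offset = 0.15)))
}
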