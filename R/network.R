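# Network architectures: single-stream CNN (four same-padding 3x3 conv+ReLU
# layers) and the multi-stream network (plain + dilated pathways, stage
# planes 46 -> 23 -> 11 -> 5 by floor-division 2x2 max pooling), each with a
# per-pixel segmentation head and a per-image classification head.

pool_stage_sizes <- function(input_size, n_pools = 3L) {
  out <- integer(n_pools + 1L)
  out[1] <- as.integer(input_size)
  for (i in seq_len(n_pools)) out[i + 1L] <- out[i] %/% 2L
  out
}

#' Single-stream network specification
#'
#' Four 3x3, stride-1, same-padding convolution layers with ReLU; spatial
#' size is preserved end to end (no pooling). The channel sequence is a
#' package choice (the architecture's published description fixes layer
#' count, kernel, stride and padding but not widths).
#'
#' @param channels Output channels of the four conv layers.
#' @param in_channels Input image channels (grayscale default 1).
#' @param input_size Expected square input side (documentation default 46;
#'   the layers themselves are size-agnostic).
#' @param n_classes Image-level classes (default 4).
#' @param n_seg_classes Per-pixel classes (default 2: background/lesion).
#' @param dropout Dropout rate used after pooling stages; the single stream
#'   has no pooling, so this only documents the default.
#' @param allow_nonstandard Permit a channel sequence of length other than
#'   four (otherwise rejected, keeping the canonical four-layer form).
#' @return A `network_spec` (arch "single").
#' @export
single_stream_spec <- function(channels = c(16L, 32L, 64L, 128L),
                               in_channels = 1L, input_size = 46L,
                               n_classes = 4L, n_seg_classes = 2L,
                               dropout = 0.25, allow_nonstandard = FALSE) {
  structure(list(arch = "single", channels = as.integer(channels),
                 in_channels = as.integer(in_channels),
                 input_size = as.integer(input_size),
                 n_classes = as.integer(n_classes),
                 n_seg_classes = as.integer(n_seg_classes),
                 dropout = dropout, dilations = 1L,
                 allow_nonstandard = isTRUE(allow_nonstandard)),
            class = "network_spec")
}

#' Multi-stream network specification
#'
#' Two (or more) parallel convolutional pathways over the same input: stream
#' 1 uses plain 3x3 convs, later streams dilated (dilation 2) convs, giving
#' the network both local and wider-context receptive fields. Default stage
#' shapes follow the published 46x46x256 -> 23x23x138 -> 11x11x128 ->
#' 5x5x64 sequence per stream (pooling by 2x2 windows with floor division:
#' 46 -> 23 -> 11 -> 5); the unconventional 138-channel stage is kept
#' verbatim as the default and is overridable here. Stream outputs are
#' fused by channel concatenation and feed a classification head (global
#' average + global max pooled features into a dense layer) and a
#' segmentation head (nearest upsampling to the input plane + one 3x3
#' conv).
#'
#' The `"desk"` profile keeps the architecture but shrinks channel widths
#' to `(16, 12, 12, 8)` so desk-scale CPU experiments finish quickly; the
#' published widths remain the documented default.
#'
#' @param channels Per-stream stage channels (default the published
#'   `c(256, 138, 128, 64)`).
#' @param n_streams Number of pathways (>= 2).
#' @param dilations Per-stream kernel dilation; default `c(1, 2, 2, ...)`.
#' @param stage_sizes Optional expected spatial sides per stage; rejected if
#'   they cannot be realized by the floor-division pool rule.
#' @param profile `"paper"` (default widths) or `"desk"` (reduced widths).
#' @inheritParams single_stream_spec
#' @return A `network_spec` (arch "multi").
#' @export
multi_stream_spec <- function(channels = c(256L, 138L, 128L, 64L),
                              n_streams = 2L, dilations = NULL,
                              in_channels = 1L, input_size = 46L,
                              n_classes = 4L, n_seg_classes = 2L,
                              dropout = 0.25, stage_sizes = NULL,
                              profile = c("paper", "desk")) {
  profile <- match.arg(profile)
  if (profile == "desk" && missing(channels)) channels <- c(16L, 12L, 12L, 8L)
  n_streams <- as.integer(n_streams)
  dilations <- dilations %||% c(1L, rep(2L, max(0L, n_streams - 1L)))
  if (length(dilations) != n_streams)
    stop("`dilations` must have one entry per stream")
  expected <- pool_stage_sizes(input_size)
  if (!is.null(stage_sizes) && !identical(as.integer(stage_sizes), expected))
    stop(sprintf(paste0("stage sizes (%s) cannot be realized from input %d by ",
                        "2x2 floor-division pooling (which gives %s)"),
                 paste(stage_sizes, collapse = ","), input_size,
                 paste(expected, collapse = ",")), call. = FALSE)
  structure(list(arch = "multi", channels = as.integer(channels),
                 n_streams = n_streams, dilations = as.integer(dilations),
                 in_channels = as.integer(in_channels),
                 input_size = as.integer(input_size),
                 n_classes = as.integer(n_classes),
                 n_seg_classes = as.integer(n_seg_classes),
                 dropout = dropout, stage_sizes = expected,
                 profile = profile),
            class = "network_spec")
}

new_conv_layer <- function(k, cin, cout, dilation = 1L, prunable = TRUE) {
  sd <- sqrt(2 / (k * k * cin))       # He initialization for ReLU nets
  list(W = array(stats::rnorm(k * k * cin * cout, 0, sd), c(k, k, cin, cout)),
       b = numeric(cout), dilation = as.integer(dilation), type = "conv",
       prunable = prunable, mask = NULL)
}

new_bn_layer <- function(c) {
  list(W = rep(1, c), b = rep(0, c), dilation = 1L, type = "bn",
       prunable = FALSE, mask = NULL,
       running_mean = rep(0, c), running_var = rep(1, c))
}

new_dense_layer <- function(cin, cout, prunable = FALSE) {
  sd <- sqrt(2 / cin)
  list(W = matrix(stats::rnorm(cin * cout, 0, sd), cin, cout),
       b = numeric(cout), dilation = 1L, type = "dense",
       prunable = prunable, mask = NULL)
}

# Seed the first filters of an input-facing conv layer with classical
# blob/smoothing kernels: +/- Laplacian (dark-blob and bright-blob
# center-surround detectors) and a Gaussian mean. Random initialization
# discovers center-surround structure only slowly at a small learning
# rate, and hypodense lesions (cysts) are invisible to purely positive
# filters under ReLU; remaining filters stay He-random.
structure_first_conv <- function(layer) {
  lap <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  gauss <- matrix(c(1, 2, 1, 2, 4, 2, 1, 2, 1), 3, 3) / 16
  seeds <- list(0.4 * lap, -0.4 * lap, gauss)
  for (i in seq_len(min(length(seeds), dim(layer$W)[4])))
    layer$W[, , 1, i] <- seeds[[i]]
  layer
}

stream_layer_names <- function(spec, s) {
  sprintf("s%d_conv%d", s, seq_along(spec$channels))
}

#' Build the single-stream model
#'
#' @param spec A [single_stream_spec()].
#' @param seed Seed for weight initialization (He-scaled normal).
#' @return An `msnn_model`.
#' @export
build_single_stream <- function(spec = single_stream_spec(), seed = 1) {
  stopifnot(inherits(spec, "network_spec"), spec$arch == "single")
  if (length(spec$channels) != 4L && !spec$allow_nonstandard)
    stop(paste0("the single-stream architecture has exactly four convolution ",
                "layers; pass allow_nonstandard = TRUE to override"),
         call. = FALSE)
  with_rng(seed, {
    layers <- list()
    cin <- spec$in_channels
    for (l in seq_along(spec$channels)) {
      ly <- new_conv_layer(3L, cin, spec$channels[l])
      if (l == 1L) ly <- structure_first_conv(ly)
      layers[[sprintf("s1_conv%d", l)]] <- ly
      cin <- spec$channels[l]
    }
    layers[["seg_conv"]] <- new_conv_layer(3L, cin, spec$n_seg_classes,
                                           prunable = FALSE)
    layers[["cls_bn"]] <- new_bn_layer(2L * cin)
    layers[["cls_dense"]] <- new_dense_layer(2L * cin, spec$n_classes)
    structure(list(spec = spec, layers = layers, init_seed = seed),
              class = "msnn_model")
  })
}

#' Build the multi-stream model
#'
#' @param spec A [multi_stream_spec()].
#' @param seed Seed for weight initialization.
#' @return An `msnn_model`.
#' @export
build_multi_stream <- function(spec = multi_stream_spec(), seed = 1) {
  stopifnot(inherits(spec, "network_spec"), spec$arch == "multi")
  if (spec$n_streams < 2L)
    stop("a multi-stream network needs at least 2 streams", call. = FALSE)
  with_rng(seed, {
    layers <- list()
    for (s in seq_len(spec$n_streams)) {
      cin <- spec$in_channels
      for (l in seq_along(spec$channels)) {
        ly <- new_conv_layer(3L, cin, spec$channels[l],
                             dilation = spec$dilations[s])
        if (l == 1L) ly <- structure_first_conv(ly)
        layers[[sprintf("s%d_conv%d", s, l)]] <- ly
        cin <- spec$channels[l]
      }
    }
    fused <- spec$n_streams * spec$channels[length(spec$channels)]
    layers[["seg_conv"]] <- new_conv_layer(3L, fused, spec$n_seg_classes,
                                           prunable = FALSE)
    layers[["cls_bn"]] <- new_bn_layer(2L * fused)
    layers[["cls_dense"]] <- new_dense_layer(2L * fused, spec$n_classes)
    structure(list(spec = spec, layers = layers, init_seed = seed),
              class = "msnn_model")
  })
}

#' @export
print.msnn_model <- function(x, ...) {
  cat(sprintf("<msnn_model> arch '%s', %d parameter(s), sparsity %.3f\n",
              x$spec$arch, n_parameters(x), model_sparsity(x)))
  invisible(x)
}

#' Count model parameters
#'
#' @param model An `msnn_model`.
#' @param active_only Count only weights not removed by pruning.
#' @return Integer parameter count (weights + biases).
#' @export
n_parameters <- function(model, active_only = FALSE) {
  sum(vapply(model$layers, function(l) {
    nw <- if (active_only && !is.null(l$mask)) sum(l$mask) else length(l$W)
    nw + length(l$b)
  }, numeric(1)))
}

# Fraction of prunable weights currently zeroed by a mask.
model_sparsity <- function(model) {
  tot <- 0; pruned <- 0
  for (l in model$layers) {
    if (!isTRUE(l$prunable)) next
    tot <- tot + length(l$W)
    if (!is.null(l$mask)) pruned <- pruned + sum(l$mask == 0)
  }
  if (tot == 0) 0 else pruned / tot
}

#' Linear (convolutional) layer transform
#'
#' Applies the layer's linear map `z = W * a + b` to an activation tensor:
#' for convolution layers this is same-padding cross-correlation over the
#' plane. The ReLU of the layer is applied separately via [relu()].
#'
#' @param input Activation tensor `(H, W, C_in)` or `(N, H, W, C_in)`.
#' @param layer A layer as stored in `msnn_model$layers` (fields `W`, `b`,
#'   `dilation`).
#' @return Pre-activation tensor with `C_out` channels.
#' @export
affine_forward <- function(input, layer) {
  conv2d_forward(input, layer$W, layer$b, layer$dilation %||% 1L)
}

# ---- forward/backward tape ------------------------------------------------

run_stream_forward <- function(model, names_s, x, train, keep = TRUE) {
  spec <- model$spec
  tape <- list()
  h <- x
  for (l in seq_along(names_s)) {
    if (spec$arch == "multi" && l > 1L) {
      pc <- maxpool_forward(h, 2L)
      if (keep) tape[[length(tape) + 1L]] <- list(op = "pool", cache = pc)
      h <- pc$out
      dc <- dropout_forward(h, spec$dropout, train)
      if (keep) tape[[length(tape) + 1L]] <- list(op = "dropout", cache = dc)
      h <- dc$out
    }
    ly <- model$layers[[names_s[l]]]
    if (keep) {
      cf <- conv_fwd(h, ly$W, ly$b, ly$dilation, want_cols = TRUE)
      tape[[length(tape) + 1L]] <- list(op = "conv", name = names_s[l],
                                        cols = cf$cols, z = cf$z)
      h <- relu(cf$z)
    } else {
      h <- relu(conv_fwd(h, ly$W, ly$b, ly$dilation))
    }
  }
  list(out = h, tape = tape)
}

run_stream_backward <- function(model, tape, dout) {
  grads <- list()
  d <- dout
  for (i in rev(seq_along(tape))) {
    step <- tape[[i]]
    if (step$op == "conv") {
      ly <- model$layers[[step$name]]
      d <- relu_backward(d, step$z)
      # the stream's first conv sees the raw input: its input gradient is
      # never consumed, so skip the transposed convolution
      bk <- conv2d_backward(d, list(cols = step$cols, W = ly$W,
                                    dilation = ly$dilation),
                            want_dx = (i > 1L))
      grads[[step$name]] <- list(dW = bk$dW, db = bk$db)
      d <- bk$dx
    } else if (step$op == "pool") {
      d <- maxpool_backward(d, step$cache)
    } else {
      d <- dropout_backward(d, step$cache)
    }
  }
  list(dx = d, grads = grads)
}

#' Forward pass of an `msnn_model`
#'
#' @param model An `msnn_model`.
#' @param x Input array `(N, H, W, C_in)` (2-D/3-D inputs promoted).
#' @param train Logical; enables dropout (draws from the current RNG
#'   stream). Evaluation (`train = FALSE`) is deterministic.
#' @param keep_cache Keep intermediate tensors for a backward pass.
#' @return List with `class_logits` `(N, n_classes)`, `seg_logits`
#'   `(N, H, W, n_seg_classes)` and, if requested, `cache`.
#' @export
model_forward <- function(model, x, train = FALSE, keep_cache = FALSE) {
  stopifnot(inherits(model, "msnn_model"))
  x <- as_batch(x)
  spec <- model$spec
  n_streams <- if (spec$arch == "multi") spec$n_streams else 1L
  streams <- vector("list", n_streams)
  for (s in seq_len(n_streams))
    streams[[s]] <- run_stream_forward(model, stream_layer_names(spec, s), x,
                                       train, keep = keep_cache)
  # fuse by channel concatenation
  outs <- lapply(streams, `[[`, "out")
  dims <- dim(outs[[1]])
  cch <- vapply(outs, function(o) dim(o)[4], numeric(1))
  fused <- array(0, c(dims[1:3], sum(cch)))
  off <- 0L
  for (s in seq_len(n_streams)) {
    fused[, , , off + seq_len(cch[s])] <- outs[[s]]
    off <- off + cch[s]
  }
  # classification head: global average + global max pooled features,
  # batch-normalized, then dense. Max pooling keeps evidence of small
  # lesions (a stone covers a handful of pixels) that plane-wide averaging
  # would dilute away; the normalization keeps the head trainable at the
  # small protocol learning rate by giving its inputs unit scale.
  g <- gap_forward(fused)
  mx <- gmp_forward(fused)
  feats_raw <- cbind(g$out, mx$out)
  bn <- model$layers$cls_bn
  bnc <- bn_forward(feats_raw, bn$W, bn$b,
                    list(mean = bn$running_mean, var = bn$running_var), train)
  cls_logits <- dense_forward(bnc$out, model$layers$cls_dense$W,
                              model$layers$cls_dense$b)
  # segmentation head: nearest upsample to input plane + 3x3 conv
  up <- upsample_forward(fused, dim(x)[2], dim(x)[3])
  seg_cf <- conv_fwd(up$out, model$layers$seg_conv$W,
                     model$layers$seg_conv$b,
                     model$layers$seg_conv$dilation,
                     want_cols = keep_cache)
  seg_logits <- if (keep_cache) seg_cf$z else seg_cf
  res <- list(class_logits = cls_logits, seg_logits = seg_logits,
              bn_running = bnc$new_running)
  if (keep_cache)
    res$cache <- list(streams = streams, fused = fused, gap = g, gmp = mx,
                      bn = bnc, up = up, seg_cols = seg_cf$cols,
                      cch = cch, x = x)
  res
}

model_backward <- function(model, fwd, dcls_logits, dseg_logits) {
  cache <- fwd$cache
  grads <- list()
  # classification head
  db_cls <- dense_backward(dcls_logits, cache$bn$out, model$layers$cls_dense$W)
  grads$cls_dense <- list(dW = db_cls$dW, db = db_cls$db)
  bb <- bn_backward(db_cls$dx, cache$bn)
  grads$cls_bn <- list(dW = bb$dgamma, db = bb$dbeta)
  nf <- ncol(cache$gap$out)
  dfused <- gap_backward(bb$dx[, seq_len(nf), drop = FALSE], cache$gap) +
    gmp_backward(bb$dx[, nf + seq_len(nf), drop = FALSE], cache$gmp)
  # segmentation head
  bk_seg <- conv2d_backward(dseg_logits,
                            list(cols = cache$seg_cols,
                                 W = model$layers$seg_conv$W,
                                 dilation = model$layers$seg_conv$dilation))
  grads$seg_conv <- list(dW = bk_seg$dW, db = bk_seg$db)
  dfused <- dfused + upsample_backward(bk_seg$dx, cache$up)
  # split back into streams
  off <- 0L
  for (s in seq_along(cache$streams)) {
    dstream <- dfused[, , , off + seq_len(cache$cch[s]), drop = FALSE]
    off <- off + cache$cch[s]
    sb <- run_stream_backward(model, cache$streams[[s]]$tape, dstream)
    grads <- c(grads, sb$grads)
  }
  grads
}

# Joint loss (pixel cross-entropy + image cross-entropy) and its gradients.
model_loss_backward <- function(model, x, y_class, y_mask, train = TRUE) {
  x <- as_batch(x)
  fwd <- model_forward(model, x, train = train, keep_cache = TRUE)
  cls <- softmax_ce(fwd$class_logits, y_class)
  d <- dim(fwd$seg_logits)
  seg_mat <- matrix(fwd$seg_logits, d[1] * d[2] * d[3], d[4])
  seg <- softmax_ce(seg_mat, as.integer(y_mask) + 1L)
  grads <- model_backward(model, fwd,
                          cls$dlogits, array(seg$dlogits, d))
  list(seg_loss = seg$loss, class_loss = cls$loss, grads = grads,
       bn_running = fwd$bn_running)
}

#' Predict from an `msnn_model`
#'
#' @param object An `msnn_model`.
#' @param x Input array or list of `labeled_sample`s.
#' @param ... Unused.
#' @return List with `class_probs` `(N, n_classes)`, `class_pred` (integer
#'   1-based class index), `seg_probs` `(N, H, W, n_seg_classes)` and
#'   `seg_pred` (0/1 array).
#' @export
predict.msnn_model <- function(object, x, ...) {
  if (is.list(x) && !is.array(x)) x <- assemble_batch(x)$x
  fwd <- model_forward(object, x, train = FALSE)
  cp <- softmax_mat(fwd$class_logits)
  d <- dim(fwd$seg_logits)
  sp <- array(softmax_mat(matrix(fwd$seg_logits, prod(d[1:3]), d[4])), d)
  list(class_probs = cp,
       class_pred = max.col(cp, ties.method = "first"),
       seg_probs = sp,
       seg_pred = array(as.integer(sp[, , , 2] > sp[, , , 1]), d[1:3]))
}

# Raw (pre-batch-norm) pooled classification features for a batch; cheap
# forward without backward caches, used for batch-norm recalibration.
pooled_features <- function(model, x, train = FALSE) {
  x <- as_batch(x)
  spec <- model$spec
  n_streams <- if (spec$arch == "multi") spec$n_streams else 1L
  outs <- lapply(seq_len(n_streams), function(s)
    run_stream_forward(model, stream_layer_names(spec, s), x, train,
                       keep = FALSE)$out)
  dims <- dim(outs[[1]])
  cch <- vapply(outs, function(o) dim(o)[4], numeric(1))
  fused <- array(0, c(dims[1:3], sum(cch)))
  off <- 0L
  for (s in seq_len(n_streams)) {
    fused[, , , off + seq_len(cch[s])] <- outs[[s]]
    off <- off + cch[s]
  }
  cbind(gap_forward(fused)$out, gmp_forward(fused)$out)
}

# ---- weight archive -------------------------------------------------------

#' Save / load model weights
#'
#' Weights are written as a single-file archive of named numeric arrays
#' (`<path>.rds`) with a JSON sidecar (`<path>.json`) recording the network
#' specification, so an archive is self-describing.
#'
#' @param model An `msnn_model`.
#' @param path Path prefix (without extension).
#' @return `save_model` invisibly returns `path`; `load_model` returns the
#'   rebuilt `msnn_model`.
#' @export
save_model <- function(model, path) {
  arrays <- list()
  for (nm in names(model$layers)) {
    l <- model$layers[[nm]]
    arrays[[paste0(nm, ".W")]] <- l$W
    arrays[[paste0(nm, ".b")]] <- l$b
    if (!is.null(l$mask)) arrays[[paste0(nm, ".mask")]] <- l$mask
    if (l$type == "bn") {
      arrays[[paste0(nm, ".running_mean")]] <- l$running_mean
      arrays[[paste0(nm, ".running_var")]] <- l$running_var
    }
  }
  saveRDS(arrays, paste0(path, ".rds"))
  side <- model$spec
  class(side) <- NULL
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  arrays <- readRDS(paste0(path, ".rds"))
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  spec_args <- side[setdiff(names(side), c("arch", "stage_sizes", "allow_nonstandard"))]
  if (side$arch == "multi") {
    spec <- do.call(multi_stream_spec, spec_args[names(spec_args) %in%
                      names(formals(multi_stream_spec))])
    model <- build_multi_stream(spec, seed = 1)
  } else {
    spec <- do.call(single_stream_spec, spec_args[names(spec_args) %in%
                      names(formals(single_stream_spec))])
    model <- build_single_stream(spec, seed = 1)
  }
  for (nm in names(model$layers)) {
    model$layers[[nm]]$W <- arrays[[paste0(nm, ".W")]]
    model$layers[[nm]]$b <- as.numeric(arrays[[paste0(nm, ".b")]])
    mk <- arrays[[paste0(nm, ".mask")]]
    if (!is.null(mk)) model$layers[[nm]]$mask <- mk
    if (model$layers[[nm]]$type == "bn") {
      model$layers[[nm]]$running_mean <-
        as.numeric(arrays[[paste0(nm, ".running_mean")]])
      model$layers[[nm]]$running_var <-
        as.numeric(arrays[[paste0(nm, ".running_var")]])
    }
  }
  model
}

# Stack a list of labeled_samples into batch arrays.
assemble_batch <- function(samples) {
  n <- length(samples)
  d <- dim(samples[[1]]$image)
  x <- array(0, c(n, d[1], d[2], 1L))
  y_mask <- array(0L, c(n, d[1], d[2]))
  y_class <- integer(n)
  for (i in seq_len(n)) {
    x[i, , , 1] <- samples[[i]]$image
    y_mask[i, , ] <- samples[[i]]$mask
    y_class[i] <- match(samples[[i]]$label, kidney_classes)
  }
  list(x = x, y_class = y_class, y_mask = y_mask)
}
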