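# Layer primitives against brute-force oracles, architecture contracts,
# and the reverse-mode gradients against finite differences.

test_that("convolution matches the nested-loop oracle", {
  set.seed(1)
  x1 <- array(rnorm(25), c(1, 5, 5, 1))
  W1 <- array(rnorm(9), c(3, 3, 1, 1))
  expect_lt(max(abs(conv2d_forward(x1, W1, 0.3) -
                      conv_oracle(x1, W1, 0.3))), 1e-6)

  x2 <- array(rnorm(2 * 8 * 8 * 3), c(2, 8, 8, 3))
  W2 <- array(rnorm(9 * 3 * 4), c(3, 3, 3, 4))
  b2 <- rnorm(4)
  for (d in 1:2)
    expect_lt(max(abs(conv2d_forward(x2, W2, b2, dilation = d) -
                        conv_oracle(x2, W2, b2, dilation = d))), 1e-6)
})

test_that("convolution limiting cases and shape errors", {
  x <- array(runif(36), c(1, 6, 6, 1))
  Wz <- array(0, c(3, 3, 1, 2))
  z <- conv2d_forward(x, Wz, c(1.5, -2))
  expect_true(all(z[, , , 1] == 1.5) && all(z[, , , 2] == -2))

  Wid <- array(0, c(3, 3, 1, 1))
  Wid[2, 2, 1, 1] <- 1
  expect_equal(conv2d_forward(x, Wid, 0)[1, , , 1], x[1, , , 1])

  Wbad <- array(0, c(3, 3, 2, 1))   # fan-in mismatch
  expect_error(conv2d_forward(x, Wbad, 0), "1x6x6x1.*3x3x2x1")
})

test_that("relu clamps negatives and is idempotent", {
  expect_identical(relu(c(-1, 0, 2)), c(0, 0, 2))
  expect_identical(relu(c(-3, -0.5)), c(0, 0))
  z <- rnorm(50)
  expect_identical(relu(relu(z)), relu(z))
})

test_that("max pooling matches the exhaustive window scan", {
  expect_identical(maxpool(matrix(c(1, 3, 2, 4), 2, 2))[1, 1, 1, 1], 4)
  const <- array(0.7, c(1, 4, 4, 2))
  expect_true(all(maxpool(const) == 0.7))

  set.seed(2)
  x <- array(rnorm(2 * 6 * 6 * 3), c(2, 6, 6, 3))
  for (w in 2:3)
    expect_equal(maxpool(x, w), maxpool_oracle(x, w), tolerance = 1e-12)
  # floor rule drops trailing rows/cols
  x7 <- array(rnorm(7 * 7), c(1, 7, 7, 1))
  expect_identical(dim(maxpool(x7, 2)), c(1L, 3L, 3L, 1L))
  expect_error(maxpool(array(rnorm(4), c(1, 2, 2, 1)), 3), "window")
})

test_that("same-padding stride-1 stacks preserve spatial size", {
  model <- build_single_stream(single_stream_spec(channels = c(2, 2, 2, 2)),
                               seed = 1)
  for (side in c(8L, 11L, 16L)) {
    x <- array(rnorm(side^2), c(1, side, side, 1))
    fwd <- model_forward(model, x)
    expect_identical(dim(fwd$seg_logits), c(1L, side, side, 2L))
  }
})

test_that("single-stream architecture has four 3x3 conv layers", {
  model <- build_single_stream(seed = 1)
  convs <- grep("^s1_conv", names(model$layers), value = TRUE)
  expect_length(convs, 4)
  for (nm in convs)
    expect_identical(dim(model$layers[[nm]]$W)[1:2], c(3L, 3L))

  expect_error(build_single_stream(single_stream_spec(channels = c(8, 8, 8))),
               "four convolution layers")
  expect_silent(build_single_stream(
    single_stream_spec(channels = c(8, 8, 8), allow_nonstandard = TRUE),
    seed = 1))
})

test_that("parameter count matches the closed-form sum", {
  ch <- c(5L, 7L, 3L, 4L)
  model <- build_single_stream(single_stream_spec(channels = ch), seed = 1)
  cin <- c(1L, ch[-4])
  closed <- sum(3 * 3 * cin * ch + ch)
  counted <- sum(vapply(grep("^s1_conv", names(model$layers), value = TRUE),
                        function(nm) length(model$layers[[nm]]$W) +
                          length(model$layers[[nm]]$b), numeric(1)))
  expect_identical(counted, as.numeric(closed))
})

test_that("multi-stream model reproduces the printed stage shapes", {
  model <- build_multi_stream(multi_stream_spec(), seed = 1)
  x <- array(rnorm(2 * 46 * 46), c(2, 46, 46, 1))
  fwd <- model_forward(model, x, keep_cache = TRUE)
  expect_identical(dim(fwd$class_logits), c(2L, 4L))
  expect_identical(dim(fwd$seg_logits), c(2L, 46L, 46L, 2L))
  for (s in 1:2) {
    zs <- lapply(Filter(function(e) e$op == "conv",
                        fwd$cache$streams[[s]]$tape), `[[`, "z")
    expect_identical(lapply(zs, function(z) dim(z)[2:4]),
                     list(c(46L, 46L, 256L), c(23L, 23L, 138L),
                          c(11L, 11L, 128L), c(5L, 5L, 64L)))
  }
  expect_identical(fssmr:::pool_stage_sizes(46L), c(46L, 23L, 11L, 5L))
})

test_that("multi-stream spec validation", {
  expect_error(build_multi_stream(multi_stream_spec(n_streams = 1)),
               "at least 2")
  expect_error(multi_stream_spec(stage_sizes = c(46, 23, 12, 6)),
               "floor-division")
  expect_silent(multi_stream_spec(stage_sizes = c(46, 23, 11, 5)))
})

test_that("reverse-mode gradients match central finite differences", {
  spec <- multi_stream_spec(channels = c(2, 3, 2, 2), input_size = 12,
                            dropout = 0)
  model <- build_multi_stream(spec, seed = 2)
  set.seed(4)
  x <- array(rnorm(3 * 12 * 12), c(3, 12, 12, 1))
  ycl <- c(1L, 3L, 2L)
  ym <- array(rbinom(3 * 12 * 12, 1, 0.3), c(3, 12, 12))
  lb <- fssmr:::model_loss_backward(model, x, ycl, ym, train = TRUE)
  loss_at <- function(m) {
    fwd <- model_forward(m, x, train = TRUE)
    cls <- fssmr:::softmax_ce(fwd$class_logits, ycl)
    d <- dim(fwd$seg_logits)
    seg <- fssmr:::softmax_ce(matrix(fwd$seg_logits, prod(d[1:3]), d[4]),
                              as.integer(ym) + 1L)
    cls$loss + seg$loss
  }
  eps <- 1e-5
  for (nm in names(lb$grads)) {
    l <- model$layers[[nm]]
    for (i in sample(length(l$W), min(4, length(l$W)))) {
      mp <- model; mp$layers[[nm]]$W[i] <- l$W[i] + eps
      mm <- model; mm$layers[[nm]]$W[i] <- l$W[i] - eps
      fd <- (loss_at(mp) - loss_at(mm)) / (2 * eps)
      an <- lb$grads[[nm]]$dW[i]
      expect_lt(abs(fd - an) / max(1e-8, abs(fd) + abs(an)), 1e-4)
    }
    i <- sample(length(l$b), 1)
    mp <- model; mp$layers[[nm]]$b[i] <- l$b[i] + eps
    mm <- model; mm$layers[[nm]]$b[i] <- l$b[i] - eps
    fd <- (loss_at(mp) - loss_at(mm)) / (2 * eps)
    expect_lt(abs(fd - lb$grads[[nm]]$db[i]) /
                max(1e-8, abs(fd) + abs(lb$grads[[nm]]$db[i])), 1e-4)
  }
})

test_that("evaluation forward passes are deterministic; dropout is seeded", {
  model <- build_multi_stream(tiny_spec(), seed = 3)
  x <- array(runif(2 * 12 * 12), c(2, 12, 12, 1))
  f1 <- model_forward(model, x)
  f2 <- model_forward(model, x)
  expect_identical(f1$class_logits, f2$class_logits)
  expect_identical(f1$seg_logits, f2$seg_logits)

  set.seed(9); t1 <- model_forward(model, x, train = TRUE)
  set.seed(9); t2 <- model_forward(model, x, train = TRUE)
  expect_identical(t1$class_logits, t2$class_logits)
})

test_that("weight archives round-trip through save/load", {
  model <- build_multi_stream(tiny_spec(), seed = 6)
  model <- apply_pruning(model, 0.4)$model
  path <- file.path(withr::local_tempdir(), "model")
  save_model(model, path)
  back <- load_model(path)
  x <- array(runif(2 * 12 * 12), c(2, 12, 12, 1))
  expect_equal(predict(back, x), predict(model, x), tolerance = 1e-12)
  expect_identical(back$layers$s1_conv1$mask, model$layers$s1_conv1$mask)
})

test_that("pruned forward equals a dense model with manually zeroed weights", {
  model <- build_multi_stream(tiny_spec(dropout = 0), seed = 8)
  pruned <- apply_pruning(model, 0.7)$model
  manual <- model
  for (nm in names(model$layers)) {
    mk <- pruned$layers[[nm]]$mask
    if (!is.null(mk)) manual$layers[[nm]]$W <- manual$layers[[nm]]$W * mk
  }
  x <- array(runif(2 * 12 * 12), c(2, 12, 12, 1))
  fp <- model_forward(pruned, x)
  fm <- model_forward(manual, x)
  expect_equal(fp$class_logits, fm$class_logits, tolerance = 1e-12)
  expect_equal(fp$seg_logits, fm$seg_logits, tolerance = 1e-12)
})
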