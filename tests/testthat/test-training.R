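# Training orchestration: schedule, optimizer step, splits, evaluation
# consistency, stopping behavior and reproducibility.

test_that("the learning-rate schedule follows the step decay", {
  cfg <- train_config()
  expect_identical(lr_schedule(0, cfg), 0.001)
  expect_equal(lr_schedule(10, cfg), 0.0009, tolerance = 1e-15)
  expect_equal(lr_schedule(25, cfg), 0.00081, tolerance = 1e-15)
  expect_error(lr_schedule(-1, cfg), ">= 0")
})

test_that("SGD-momentum reduces to plain gradient descent in the limit", {
  up <- sgd_momentum_step(1, 0.5, 0, lr = 0.1, momentum = 0, l2_coeff = 0)
  expect_equal(up$w, 0.95, tolerance = 1e-15)

  up2 <- sgd_momentum_step(c(1, 2), c(0, 0), c(0, 0), lr = 0.1,
                           momentum = 0.9, l2_coeff = 0)
  expect_identical(up2$w, c(1, 2))

  expect_error(sgd_momentum_step(matrix(0, 2, 2), numeric(3), 0, 0.1),
               "shapes")
})

test_that("splits are stratified and reproducible", {
  ds <- tiny_dataset(n = 40, seed = 2)
  sp <- split_dataset(ds, seed = 3)
  labs <- function(x) table(factor(vapply(x, `[[`, character(1), "label"),
                                   levels = kidney_classes))
  expect_identical(as.integer(labs(sp$train)), rep(8L, 4))  # 70% of 10
  expect_identical(as.integer(labs(sp$val)), rep(1L, 4))
  expect_identical(as.integer(labs(sp$test)), rep(1L, 4))
  sp2 <- split_dataset(ds, seed = 3)
  expect_identical(sp, sp2)
  expect_error(split_dataset(ds, ratios = c(0.5, 0.2, 0.2)), "sum to 1")
})

test_that("model evaluation agrees with direct metric computation", {
  ds <- tiny_dataset(n = 16, seed = 8)
  sp <- split_dataset(ds, seed = 1)
  model <- build_multi_stream(tiny_spec(), seed = 2)
  rep <- evaluate_model(model, sp$train, l2_coeff = 1e-4)

  arrs <- fssmr:::assemble_batch(sp$train)
  pr <- predict(model, arrs$x)
  manual <- evaluate_predictions(pr$class_probs, arrs$y_class, pr$seg_probs,
                                 arrs$y_mask)
  for (col in names(manual))
    expect_identical(rep[[col]], manual[[col]])
  expect_identical(rep$total_loss,
                   total_loss(rep$seg_loss, rep$class_loss, rep$aux_loss))
})

test_that("a non-improving run stops with the patience rule after patience epochs", {
  ds <- tiny_dataset(n = 12, seed = 4)
  sp <- split_dataset(ds, ratios = c(0.5, 0.5, 0), seed = 1)
  cfg <- train_config(epochs = 20, lr0 = 1e-12, batch_size = 8,
                      patience = 10, min_delta = 0.01, sigma_mult = 0,
                      prune = FALSE, augment_copies = 0, seed = 1)
  run <- train_model(build_multi_stream(tiny_spec(dropout = 0), seed = 1),
                     sp, cfg)
  expect_identical(run$stop_epoch, 11L)
  expect_identical(run$stop_reason, "patience")
})

test_that("a short run completes with one record per epoch", {
  ds <- tiny_dataset(n = 12, seed = 4)
  sp <- split_dataset(ds, ratios = c(0.5, 0.5, 0), seed = 1)
  cfg <- train_config(epochs = 3, batch_size = 8, prune = FALSE,
                      augment_copies = 0, seed = 1)
  run <- train_model(build_multi_stream(tiny_spec(), seed = 1), sp, cfg)
  expect_identical(nrow(run$epochs), 3L)
  expect_identical(run$stop_reason, "completed")
  expect_identical(run$epochs$lr,
                   vapply(0:2, lr_schedule, numeric(1), config = cfg))
})

test_that("training memorizes a tiny set: loss decreases over 10 epochs", {
  ds <- tiny_dataset(n = 20, seed = 6)
  sp <- list(train = ds$samples, val = ds$samples)
  cfg <- train_config(epochs = 10, lr0 = 0.01, batch_size = 10,
                      patience = 50, prune = FALSE, augment_copies = 0,
                      l2_coeff = 0, seed = 2)
  run <- train_model(build_multi_stream(tiny_spec(dropout = 0), seed = 2),
                     sp, cfg)
  expect_lt(run$epochs$train_total_loss[10], run$epochs$train_total_loss[1])
  expect_lt(run$epochs$val_total_loss[10], run$epochs$val_total_loss[1])
})

test_that("runs are bit-reproducible under a fixed seed", {
  ds <- tiny_dataset(n = 16, seed = 7)
  sp <- split_dataset(ds, ratios = c(0.6, 0.4, 0), seed = 2)
  cfg <- train_config(epochs = 4, batch_size = 8, prune = TRUE,
                      prune_warmup = 2, prune_every = 2,
                      augment_copies = 1, seed = 11)
  r1 <- train_model(build_multi_stream(tiny_spec(), seed = 3), sp, cfg)
  r2 <- train_model(build_multi_stream(tiny_spec(), seed = 3), sp, cfg)
  expect_identical(r1$epochs, r2$epochs)
  for (nm in names(r1$model$layers))
    expect_identical(r1$model$layers[[nm]]$W, r2$model$layers[[nm]]$W)
  expect_true(any(r1$epochs$sparsity > 0))
})

test_that("diagnostic plots build without rendering errors", {
  ds <- tiny_dataset(n = 12, seed = 4)
  sp <- split_dataset(ds, ratios = c(0.5, 0.5, 0), seed = 1)
  cfg <- train_config(epochs = 2, batch_size = 8, prune = FALSE,
                      augment_copies = 0, seed = 1)
  run <- train_model(build_multi_stream(tiny_spec(), seed = 1), sp, cfg)
  expect_s3_class(plot_training_curves(run), "ggplot")
  expect_s3_class(ggplot2::autoplot(run), "ggplot")
  res <- firefly_optimize(function(x) x^2, swarm_config(n = 4, iterations = 3,
                                                        bounds = c(-1, 1),
                                                        seed = 1))
  expect_s3_class(plot_swarm_trace(res), "ggplot")
  expect_s3_class(plot_phantom(ds$samples[[1]]), "ggplot")
  expect_identical(nrow(tibble::as_tibble(run)), 2L)
})

test_that("pruning during training never resurrects a masked weight", {
  ds <- tiny_dataset(n = 16, seed = 9)
  sp <- split_dataset(ds, ratios = c(0.6, 0.4, 0), seed = 2)
  cfg <- train_config(epochs = 5, batch_size = 8, prune = TRUE,
                      prune_warmup = 2, prune_every = 2, alpha = 0.8,
                      augment_copies = 0, seed = 5)
  run <- train_model(build_multi_stream(tiny_spec(), seed = 5), sp, cfg)
  for (nm in names(run$model$layers)) {
    l <- run$model$layers[[nm]]
    if (!is.null(l$mask))
      expect_true(all(l$W[l$mask == 0] == 0))
  }
})
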