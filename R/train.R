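# Training orchestration: SGD with momentum under a step learning-rate
# decay, joint segmentation + classification loss, FSS early stopping and
# MWR pruning events with the surrogate-gradient alpha update.

#' Training configuration
#'
#' Defaults follow the study protocol: batch size 32, 50 epochs, initial
#' learning rate 0.001 multiplied by 0.9 every 10 epochs, SGD with momentum
#' (0.9), dropout and L2 regularization, early stopping when validation
#' loss fails to improve by at least 0.01 for 10 epochs.
#'
#' @param batch_size Mini-batch size (default 32).
#' @param epochs Maximum epochs (default 50).
#' @param lr0 Initial learning rate (default 0.001).
#' @param lr_decay Multiplicative decay factor (default 0.9).
#' @param lr_step Epochs between decays (default 10).
#' @param momentum SGD momentum coefficient (default 0.9); set
#'   `use_momentum = FALSE` for plain gradient descent.
#' @param l2_coeff L2 weight-penalty coefficient (default 1e-4); enters the
#'   update as decoupled weight decay and the reported auxiliary loss as
#'   `0.5 * l2_coeff * sum(w^2)`.
#' @param dropout Dropout rate after pooling stages (default 0.25).
#' @param alpha Initial MWR pruning multiplier (default 0.5).
#' @param sigma_mult FSS dispersion multiplier (default 0.3, calibrated so
#'   that a steadily declining loss does not trip the dispersion rule; the
#'   methods vignette derives the bound).
#' @param patience,min_delta,window,eta_theta Early-stopping parameters,
#'   see [early_stop_state()].
#' @param prune Enable MWR pruning events (default TRUE).
#' @param prune_every Epochs between pruning events (default 5).
#' @param prune_warmup First epoch at which pruning may occur (default 10;
#'   magnitude pruning before weight importance has emerged removes
#'   capacity essentially at random).
#' @param alpha_max Upper clamp for the surrogate-updated alpha (default 5).
#' @param augment_copies Number of randomly augmented copies of each
#'   training sample added once at the start of training (default 4),
#'   using the protocol's rotation/scaling/flipping/translation ops; 0
#'   disables augmentation.
#' @param use_momentum Logical (default TRUE).
#' @param seed Seed controlling augmentation, shuffling, dropout and any
#'   other training randomness.
#' @return A `train_config`.
#' @export
train_config <- function(batch_size = 32L, epochs = 50L, lr0 = 0.001,
                         lr_decay = 0.9, lr_step = 10L, momentum = 0.9,
                         l2_coeff = 1e-4, dropout = 0.25, alpha = 0.5,
                         sigma_mult = 0.3, patience = 10L, min_delta = 0.01,
                         window = 10L, eta_theta = 0.1, prune = TRUE,
                         prune_every = 5L, prune_warmup = 10L, alpha_max = 5,
                         augment_copies = 4L, use_momentum = TRUE, seed = 1L) {
  if (batch_size < 1) stop("`batch_size` must be >= 1")
  if (epochs < 1) stop("`epochs` must be >= 1")
  if (lr0 <= 0) stop("`lr0` must be > 0")
  if (lr_decay <= 0 || lr_decay > 1) stop("`lr_decay` must be in (0, 1]")
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), lr0 = lr0, lr_decay = lr_decay,
                 lr_step = as.integer(lr_step), momentum = momentum,
                 l2_coeff = l2_coeff, dropout = dropout, alpha = alpha,
                 sigma_mult = sigma_mult, patience = as.integer(patience),
                 min_delta = min_delta, window = as.integer(window),
                 eta_theta = eta_theta, prune = isTRUE(prune),
                 prune_every = as.integer(prune_every),
                 prune_warmup = as.integer(prune_warmup),
                 alpha_max = alpha_max,
                 augment_copies = as.integer(augment_copies),
                 use_momentum = isTRUE(use_momentum),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Step-decay learning-rate schedule
#'
#' `lr0 * lr_decay^floor(epoch / lr_step)` with `epoch` 0-based: 0.001 at
#' epoch 0, 0.0009 at epoch 10, 0.00081 at epoch 25 under the defaults.
#'
#' @param epoch 0-based epoch index.
#' @param config A [train_config()].
#' @return Learning rate for that epoch.
#' @export
lr_schedule <- function(epoch, config) {
  if (epoch < 0) stop("`epoch` must be >= 0")
  config$lr0 * config$lr_decay^(epoch %/% config$lr_step)
}

#' One SGD-with-momentum parameter update
#'
#' `v <- momentum * v - lr * (g + l2_coeff * w); w <- w + v`. With
#' `momentum = 0` and `l2_coeff = 0` this reduces to plain gradient descent
#' `w - lr * g`. Positions zeroed by a pruning mask receive no update and
#' stay zero.
#'
#' @param w,g,v Weight, gradient and velocity arrays of identical shape.
#' @param lr Learning rate.
#' @param momentum Momentum coefficient.
#' @param l2_coeff L2 penalty coefficient.
#' @param mask Optional 0/1 pruning mask.
#' @return List with updated `w` and `v`.
#' @export
sgd_momentum_step <- function(w, g, v, lr, momentum = 0, l2_coeff = 0,
                              mask = NULL) {
  if (!identical(dim(w) %||% length(w), dim(g) %||% length(g)))
    stop("weight and gradient shapes do not match")
  v <- momentum * v - lr * (g + l2_coeff * w)
  w <- w + v
  if (!is.null(mask)) {
    w <- w * mask
    v <- v * mask
  }
  list(w = w, v = v)
}

# 0.5 * l2 * sum of squared weights (the reported auxiliary loss).
l2_penalty <- function(model, l2_coeff) {
  if (l2_coeff <= 0) return(0)
  0.5 * l2_coeff * sum(vapply(model$layers, function(l)
    if (l$type == "bn") 0 else sum(l$W^2), numeric(1)))
}

# Seg/class/aux/total losses of a model on pre-assembled arrays (no dropout).
compute_losses <- function(model, arrs, l2_coeff) {
  fwd <- model_forward(model, arrs$x, train = FALSE)
  cls <- softmax_ce(fwd$class_logits, arrs$y_class)
  d <- dim(fwd$seg_logits)
  seg <- softmax_ce(matrix(fwd$seg_logits, prod(d[1:3]), d[4]),
                    as.integer(arrs$y_mask) + 1L)
  aux <- l2_penalty(model, l2_coeff)
  list(seg = seg$loss, class = cls$loss, aux = aux,
       total = total_loss(seg$loss, cls$loss, aux))
}

# One random augmentation (rotation, scaling, flip or translation) drawn
# from the current RNG stream.
random_augment <- function(sample) {
  op <- sample(c("rotate", "scale", "flip", "translate"), 1)
  switch(op,
    rotate = augment(sample, "rotate", angle = stats::runif(1, -15, 15)),
    scale = augment(sample, "scale", factor = stats::runif(1, 0.9, 1.1)),
    flip = augment(sample, "flip",
                   axis = sample(c("horizontal", "vertical"), 1)),
    translate = augment(sample, "translate", dx = sample(-3:3, 1),
                        dy = sample(-3:3, 1)))
}

# Replace the head batch-norm running statistics with the exact moments of
# the pooled features over the training inputs.
recalibrate_bn <- function(model, train_arrs) {
  raw <- pooled_features(model, train_arrs$x)
  model$layers$cls_bn$running_mean <- colMeans(raw)
  model$layers$cls_bn$running_var <-
    colMeans(sweep(raw, 2L, colMeans(raw))^2)
  model
}

# Validation total loss under masks built at a trial alpha (on a copy).
val_loss_at_alpha <- function(model, alpha, arrs, l2_coeff) {
  trial <- apply_pruning(model, alpha)$model
  compute_losses(trial, arrs, l2_coeff)$total
}

#' Stratified train/validation/test split
#'
#' Splits by label with ratios 70/15/15 by default; remainders go to the
#' training split.
#'
#' @param dataset A `phantom_dataset` or plain list of `labeled_sample`s.
#' @param ratios Length-3 proportions summing to 1.
#' @param seed Shuffle seed.
#' @return List of sample lists: `train`, `val`, `test`.
#' @export
split_dataset <- function(dataset, ratios = c(0.7, 0.15, 0.15), seed = 1) {
  samples <- if (inherits(dataset, "phantom_dataset")) dataset$samples else dataset
  if (abs(sum(ratios) - 1) > 1e-9 || any(ratios < 0))
    stop("`ratios` must be non-negative and sum to 1")
  labels <- vapply(samples, `[[`, character(1), "label")
  out <- list(train = list(), val = list(), test = list())
  with_rng(seed, {
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      n <- length(idx)
      n_val <- floor(ratios[2] * n)
      n_test <- floor(ratios[3] * n)
      n_train <- n - n_val - n_test
      out$train <- c(out$train, samples[idx[seq_len(n_train)]])
      out$val <- c(out$val, samples[idx[n_train + seq_len(n_val)]])
      out$test <- c(out$test, samples[idx[n_train + n_val + seq_len(n_test)]])
    }
  })
  out
}

#' Evaluate a model on a sample split
#'
#' Deterministic given the weights (dropout off). Image-level metrics come
#' from argmax class predictions (multi-class accuracy, macro one-vs-rest
#' precision/recall/F1, the `1 - A^2` score); pixel accuracy and the
#' segmentation loss are reported separately for the segmentation head.
#'
#' @param model An `msnn_model`.
#' @param samples Non-empty list of `labeled_sample`s.
#' @param l2_coeff L2 coefficient for the reported auxiliary loss.
#' @return One-row tibble metrics report (see [evaluate_predictions()]),
#'   with `aux_loss` and `total_loss` columns added.
#' @export
evaluate_model <- function(model, samples, l2_coeff = 0) {
  if (length(samples) == 0) stop("evaluation split is empty")
  arrs <- assemble_batch(samples)
  pr <- predict(model, arrs$x)
  rep <- evaluate_predictions(pr$class_probs, arrs$y_class, pr$seg_probs,
                              arrs$y_mask)
  rep$aux_loss <- l2_penalty(model, l2_coeff)
  rep$total_loss <- total_loss(rep$seg_loss, rep$class_loss, rep$aux_loss)
  rep
}

#' Train a model with FSS early stopping and MWR pruning
#'
#' Runs the joint segmentation + classification loop: per batch, forward
#' both heads, backward, one [sgd_momentum_step()] per parameter (pruned
#' positions frozen at zero); per epoch, evaluate the validation split,
#' update the loss-dispersion statistic and adaptive threshold, query
#' [should_stop()], and on the pruning cadence apply [apply_pruning()]
#' followed by the surrogate-gradient update of the pruning multiplier
#' alpha (central finite difference of validation loss under masks built at
#' `alpha * (1 +/- 0.1)`). Fully reproducible from `config$seed`.
#'
#' @param model An `msnn_model`.
#' @param splits List with non-empty `train` and `val` sample lists
#'   (optional `test`), e.g. from [split_dataset()].
#' @param config A [train_config()].
#' @return A `run_report`: `epochs` (tibble of per-epoch records),
#'   `stop_epoch`, `stop_reason` (`"fss_threshold"`, `"patience"` or
#'   `"completed"`), `final_metrics`, `prune_reports` (one tibble row per
#'   layer per pruning event), `test_metrics` (if a test split was given),
#'   `model`, `config`, `seed`, `wall_time_s`, `skipped_batches`.
#' @export
train_model <- function(model, splits, config = train_config()) {
  stopifnot(inherits(model, "msnn_model"), inherits(config, "train_config"))
  if (length(splits$train) == 0 || length(splits$val) == 0)
    stop("train and validation splits must be non-empty")
  t0 <- proc.time()[["elapsed"]]
  es <- early_stop_state(sigma_mult = config$sigma_mult,
                         patience = config$patience,
                         min_delta = config$min_delta,
                         window = config$window,
                         eta_theta = config$eta_theta)
  val_arrs <- assemble_batch(splits$val)
  velocity <- lapply(model$layers, function(l)
    list(W = array(0, dim(l$W) %||% length(l$W)), b = numeric(length(l$b))))
  history <- numeric(0)
  records <- list()
  prune_reports <- list()
  skipped <- 0L
  alpha <- config$alpha
  stop_reason <- "completed"
  stop_epoch <- config$epochs
  with_rng(config$seed, {
    if (config$augment_copies > 0L) {
      aug <- vector("list", config$augment_copies * length(splits$train))
      k <- 0L
      for (cp in seq_len(config$augment_copies))
        for (s in splits$train) {
          k <- k + 1L
          aug[[k]] <- random_augment(s)
        }
      splits$train <- c(splits$train, aug)
    }
    # fixed subset for batch-norm recalibration (moment estimates only)
    recal_idx <- unique(round(seq(1, length(splits$train),
                                  length.out = min(256L, length(splits$train)))))
    train_arrs <- assemble_batch(splits$train[recal_idx])
    for (ep in seq_len(config$epochs)) {
      lr <- lr_schedule(ep - 1L, config)
      idx <- sample(length(splits$train))
      batches <- split(idx, ceiling(seq_along(idx) / config$batch_size))
      tr_seg <- 0; tr_cls <- 0
      for (b in batches) {
        arrs <- assemble_batch(splits$train[b])
        lb <- model_loss_backward(model, arrs$x, arrs$y_class, arrs$y_mask,
                                  train = TRUE)
        finite <- all(vapply(lb$grads, function(g)
          all(is.finite(g$dW)) && all(is.finite(g$db)), logical(1)))
        if (!finite) {            # reject the step, keep training
          skipped <- skipped + 1L
          next
        }
        model$layers$cls_bn$running_mean <- lb$bn_running$mean
        model$layers$cls_bn$running_var <- lb$bn_running$var
        for (nm in names(lb$grads)) {
          l <- model$layers[[nm]]
          up <- sgd_momentum_step(l$W, lb$grads[[nm]]$dW, velocity[[nm]]$W,
                                  lr, if (config$use_momentum) config$momentum else 0,
                                  if (l$type == "bn") 0 else config$l2_coeff,
                                  l$mask)
          model$layers[[nm]]$W <- up$w
          velocity[[nm]]$W <- up$v
          upb <- sgd_momentum_step(l$b, lb$grads[[nm]]$db, velocity[[nm]]$b,
                                   lr, if (config$use_momentum) config$momentum else 0,
                                   0)
          model$layers[[nm]]$b <- upb$w
          velocity[[nm]]$b <- upb$v
        }
        tr_seg <- tr_seg + lb$seg_loss * length(b)
        tr_cls <- tr_cls + lb$class_loss * length(b)
      }
      n_tr <- length(splits$train)
      # recalibrate the head batch-norm with exact training-set feature
      # moments (few batches per epoch make running averages stale)
      model <- recalibrate_bn(model, train_arrs)
      val <- compute_losses(model, val_arrs, config$l2_coeff)
      if (!is.finite(val$total))
        stop(sprintf("validation loss became non-finite at epoch %d", ep))
      history <- c(history, val$total)
      disp <- loss_stddev(history, min(es$window, length(history)))
      theta <- compute_threshold(es, disp)
      decision <- should_stop(es, history)
      pruned_now <- FALSE
      if (config$prune && ep >= config$prune_warmup &&
          (ep - config$prune_warmup) %% config$prune_every == 0L) {
        if (alpha > 0) {
          delta <- 0.1 * alpha
          g_sur <- (val_loss_at_alpha(model, alpha + delta, val_arrs, config$l2_coeff) -
                    val_loss_at_alpha(model, max(alpha - delta, 0), val_arrs, config$l2_coeff)) /
                   (2 * delta)
        } else g_sur <- 0
        pruned <- apply_pruning(model, alpha)
        model <- pruned$model
        pruned$report$epoch <- ep
        prune_reports[[length(prune_reports) + 1L]] <- pruned$report
        model <- recalibrate_bn(model, train_arrs)  # features shift under the mask
        alpha <- threshold_step(alpha, g_sur, config$eta_theta, config$alpha_max)
        pruned_now <- TRUE
      }
      vm <- evaluate_model(model, splits$val, config$l2_coeff)
      records[[ep]] <- tibble::tibble(
        epoch = ep, lr = lr,
        train_seg_loss = tr_seg / n_tr, train_class_loss = tr_cls / n_tr,
        train_total_loss = (tr_seg + tr_cls) / n_tr +
          l2_penalty(model, config$l2_coeff),
        val_seg_loss = val$seg, val_class_loss = val$class,
        val_aux_loss = val$aux, val_total_loss = val$total,
        sigma_loss = disp, theta = theta, alpha = alpha,
        sparsity = model_sparsity(model), pruned = pruned_now,
        val_accuracy = vm$accuracy, val_precision = vm$precision,
        val_recall = vm$recall, val_f1 = vm$f1, val_mse = vm$mse,
        val_pixel_accuracy = vm$pixel_accuracy)
      if (decision$stop) {
        stop_reason <- decision$reason
        stop_epoch <- ep
        break
      }
      stop_epoch <- ep
    }
  })
  final <- evaluate_model(model, splits$val, config$l2_coeff)
  out <- list(epochs = do.call(rbind, records), stop_epoch = stop_epoch,
              stop_reason = stop_reason, final_metrics = final,
              prune_reports = if (length(prune_reports))
                do.call(rbind, prune_reports),
              model = model, config = config, seed = config$seed,
              wall_time_s = proc.time()[["elapsed"]] - t0,
              skipped_batches = skipped)
  if (length(splits$test %||% list()) > 0)
    out$test_metrics <- evaluate_model(model, splits$test, config$l2_coeff)
  structure(out, class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf(paste0("<run_report> %d epoch(s), stop reason '%s', ",
                     "val accuracy %.3f, val total loss %.4f, sparsity %.3f\n"),
              nrow(x$epochs), x$stop_reason, x$final_metrics$accuracy,
              x$final_metrics$total_loss,
              x$epochs$sparsity[nrow(x$epochs)]))
  invisible(x)
}

#' Per-epoch records of a run as a tibble
#' @param x A `run_report`.
#' @param ... Unused.
#' @export
as_tibble.run_report <- function(x, ...) x$epochs
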