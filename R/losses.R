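# Loss functions and evaluation metrics.

check_prediction_batch <- function(probs, labels, tol = 1e-6) {
  probs <- as.matrix(probs)
  if (any(probs < 0)) stop("probabilities must be non-negative")
  rs <- rowSums(probs)
  if (any(abs(rs - 1) > tol))
    stop(sprintf("probability rows must sum to 1 within %g (worst deviation %g)",
                 tol, max(abs(rs - 1))), call. = FALSE)
  if (is.matrix(labels)) {
    if (!identical(dim(labels), dim(probs)))
      stop("one-hot labels must match the probability matrix shape")
    if (any(rowSums(labels) != 1))
      stop("exactly one true class per row is required")
    y <- labels
  } else {
    y <- one_hot(as.integer(labels), ncol(probs))
  }
  list(probs = probs, y = y)
}

#' Cross-entropy segmentation loss
#'
#' Mean over samples of the negative log predicted probability of the true
#' class (natural logarithm): `-(1/N) * sum_i sum_c y_ic log p_ic`. For the
#' segmentation head each pixel is one sample `i`; the identical form over
#' image-level class probabilities is the classification loss
#' ([class_loss()]). Probabilities are clamped to `[1e-12, 1]` before the
#' log, so the loss is always finite and non-negative.
#'
#' @param probs `N x C` matrix of predicted probabilities (rows sum to 1
#'   within `tol`).
#' @param labels Integer true-class indices (length `N`) or an `N x C`
#'   one-hot matrix.
#' @param tol Row-sum tolerance (default 1e-6); violations are rejected.
#' @return Scalar loss, `>= 0`.
#' @export
seg_loss <- function(probs, labels, tol = 1e-6) {
  b <- check_prediction_batch(probs, labels, tol)
  p <- clamp(b$probs, 1e-12, 1)
  -sum(b$y * log(p)) / nrow(p)
}

#' Cross-entropy classification loss
#'
#' Same functional form as [seg_loss()], applied to per-image class
#' probabilities.
#' @inheritParams seg_loss
#' @return Scalar loss, `>= 0`.
#' @export
class_loss <- function(probs, labels, tol = 1e-6) seg_loss(probs, labels, tol)

#' Total training loss
#'
#' Sum of segmentation, classification and auxiliary losses. The auxiliary
#' component defaults to 0; in training it carries the L2 weight penalty.
#'
#' @param seg,class_,aux Non-negative finite loss components.
#' @return `seg + class_ + aux`.
#' @export
total_loss <- function(seg, class_, aux = 0) {
  v <- c(seg, class_, aux)
  if (any(!is.finite(v))) stop("loss components must be finite")
  if (any(v < 0)) stop("loss components must be non-negative")
  seg + class_ + aux
}

#' Confusion counts
#'
#' Container for binary (or one-vs-rest) confusion counts.
#'
#' @param TP,TN,FP,FN Non-negative integer counts.
#' @return A `confusion_counts` object.
#' @export
confusion_counts <- function(TP, TN, FP, FN) {
  v <- c(TP = TP, TN = TN, FP = FP, FN = FN)
  if (any(v < 0) || any(v != floor(v))) stop("counts must be non-negative integers")
  structure(as.list(v), class = "confusion_counts")
}

#' Accuracy from confusion counts
#'
#' `(TP + TN) / (TP + TN + FP + FN)`.
#' @param counts A [confusion_counts()].
#' @return Fraction in `[0, 1]`.
#' @export
accuracy <- function(counts) {
  tot <- counts$TP + counts$TN + counts$FP + counts$FN
  if (tot == 0) stop("total count must be positive")
  (counts$TP + counts$TN) / tot
}

#' Precision, recall and F1 from confusion counts
#'
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)`,
#' `F1 = 2 P R / (P + R)`. A zero denominator yields the sentinel value 0
#' for that metric, with its name recorded in `degenerate` (never an
#' error).
#'
#' @param counts A [confusion_counts()].
#' @return List with `precision`, `recall`, `f1` and character vector
#'   `degenerate` naming any sentinel-valued metrics.
#' @export
precision_recall_f1 <- function(counts) {
  flags <- character()
  if (counts$TP + counts$FP == 0) { p <- 0; flags <- c(flags, "precision") }
  else p <- counts$TP / (counts$TP + counts$FP)
  if (counts$TP + counts$FN == 0) { r <- 0; flags <- c(flags, "recall") }
  else r <- counts$TP / (counts$TP + counts$FN)
  if (p + r == 0) { f1 <- 0; flags <- c(flags, "f1") }
  else f1 <- 2 * p * r / (p + r)
  list(precision = p, recall = r, f1 = f1, degenerate = flags)
}

#' Accuracy-derived error score
#'
#' The complement `1 - A^2` of squared accuracy, reported alongside the
#' other metrics (the source work labels this quantity "MSE"; it is an
#' accuracy transform, monotone decreasing in `A`, not a squared residual).
#'
#' @param A Accuracy fraction in `[0, 1]`.
#' @return `1 - A^2`.
#' @export
mse_metric <- function(A) {
  if (!is.numeric(A) || length(A) != 1 || !is.finite(A) || A < 0 || A > 1)
    stop("`A` must be a single accuracy value in [0, 1]")
  1 - A^2
}

#' Multi-class confusion matrix
#'
#' @param pred,truth Integer class indices (same length) or factors.
#' @param n_classes Number of classes.
#' @return `n_classes x n_classes` matrix, rows = truth, cols = predicted.
#' @export
confusion_matrix <- function(pred, truth, n_classes) {
  m <- matrix(0L, n_classes, n_classes)
  for (i in seq_along(pred))
    m[truth[i], pred[i]] <- m[truth[i], pred[i]] + 1L
  m
}

# One-vs-rest counts for class k of a confusion matrix.
ovr_counts <- function(cm, k) {
  tp <- cm[k, k]
  fp <- sum(cm[-k, k])
  fn <- sum(cm[k, -k])
  tn <- sum(cm) - tp - fp - fn
  confusion_counts(tp, tn, fp, fn)
}

#' Evaluate image-level predictions (and optionally pixel masks)
#'
#' Builds the multi-class confusion matrix, reports overall accuracy
#' (correct / total), macro-averaged one-vs-rest precision/recall/F1, the
#' `1 - A^2` error score, and, when segmentation probabilities and truth
#' masks are supplied, pixel accuracy and the segmentation loss.
#'
#' @param class_probs `N x C` matrix of class probabilities.
#' @param class_truth Integer true class indices (1-based).
#' @param seg_probs Optional `(N, H, W, 2)` pixel probability array.
#' @param masks Optional `(N, H, W)` 0/1 truth array.
#' @return One-row tibble (a metrics report).
#' @export
evaluate_predictions <- function(class_probs, class_truth,
                                 seg_probs = NULL, masks = NULL) {
  nC <- ncol(class_probs)
  pred <- max.col(class_probs, ties.method = "first")
  cm <- confusion_matrix(pred, class_truth, nC)
  acc <- sum(diag(cm)) / sum(cm)
  per <- lapply(seq_len(nC), function(k) precision_recall_f1(ovr_counts(cm, k)))
  out <- tibble::tibble(
    accuracy = acc,
    precision = mean(vapply(per, `[[`, numeric(1), "precision")),
    recall = mean(vapply(per, `[[`, numeric(1), "recall")),
    f1 = mean(vapply(per, `[[`, numeric(1), "f1")),
    mse = mse_metric(acc),
    class_loss = class_loss(class_probs, class_truth),
    n = length(class_truth)
  )
  if (!is.null(seg_probs) && !is.null(masks)) {
    d <- dim(seg_probs)
    pm <- matrix(seg_probs, prod(d[1:3]), d[4])
    out$pixel_accuracy <- mean((pm[, 2] > pm[, 1]) == (as.integer(masks) == 1L))
    out$seg_loss <- seg_loss(pm, as.integer(masks) + 1L)
  }
  out
}
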