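# MagWeight Rank (MWR): per-layer mean absolute weight, the pruning
# threshold alpha * mean|W|, mask construction/application, and magnitude
# ranking. Biases are never pruned.

#' Mean absolute weight of a layer
#'
#' `(1/n) * sum |w_i|` over currently active (unmasked) weights only, so
#' repeated pruning events use a well-defined statistic.
#'
#' @param weights Numeric weight array.
#' @param mask Optional 0/1 array of the same shape (1 = active); `NULL`
#'   means all active.
#' @return Mean absolute value; error if no weight is active.
#' @export
layer_mean_abs <- function(weights, mask = NULL) {
  if (is.null(mask)) return(mean(abs(weights)))
  stopifnot(identical(dim(mask), dim(weights)) || length(mask) == length(weights))
  act <- mask != 0
  if (!any(act)) stop("all weights in the layer are masked")
  mean(abs(weights[act]))
}

#' Pruning threshold
#'
#' `alpha * mean_abs`: the magnitude below which weights are pruned.
#'
#' @param mean_abs Mean absolute weight, `>= 0`.
#' @param alpha Non-negative hyperparameter.
#' @return Threshold value (linear in `alpha`).
#' @export
pruning_threshold <- function(mean_abs, alpha) {
  if (!is.finite(alpha) || alpha < 0) stop("`alpha` must be >= 0")
  if (!is.finite(mean_abs) || mean_abs < 0) stop("`mean_abs` must be >= 0")
  alpha * mean_abs
}

#' Build a pruning mask
#'
#' Keeps a weight iff `|w| >= threshold` AND it was previously kept, so
#' masks only grow sparser. A magnitude exactly equal to the threshold is
#' kept (the conservative boundary reading).
#'
#' @param weights Numeric weight array.
#' @param threshold Non-negative pruning threshold.
#' @param existing Optional previous 0/1 mask (`NULL` = all kept).
#' @return 0/1 array shaped like `weights` (1 = keep).
#' @export
build_mask <- function(weights, threshold, existing = NULL) {
  if (!is.finite(threshold) || threshold < 0) stop("`threshold` must be >= 0")
  keep <- abs(weights) >= threshold
  if (!is.null(existing)) keep <- keep & (existing != 0)
  m <- array(as.numeric(keep), dim(weights) %||% length(weights))
  if (is.matrix(weights)) dim(m) <- dim(weights)
  m
}

#' Prune a model by magnitude
#'
#' For every prunable layer: compute the mean absolute value of the active
#' weights, the threshold `alpha * mean|W|`, tighten the layer mask, and
#' zero the pruned weights. If a threshold would remove every weight in a
#' layer, the single largest-magnitude weight (first flat index on ties) is
#' kept and the layer is flagged in the report. Convolution layers are
#' prunable by default; the segmentation/classification heads only when
#' `include_heads = TRUE`.
#'
#' @param model An `msnn_model`.
#' @param alpha Non-negative pruning hyperparameter (default 0.5).
#' @param include_heads Also prune the head layers.
#' @return List with the pruned `model` and `report`, a tibble with one row
#'   per pruned layer (layer, mean_abs, alpha, threshold, n_total,
#'   n_pruned, newly_pruned, sparsity, kept_singleton).
#' @export
apply_pruning <- function(model, alpha = 0.5, include_heads = FALSE) {
  stopifnot(inherits(model, "msnn_model"))
  if (!is.finite(alpha) || alpha < 0) stop("`alpha` must be >= 0")
  rows <- list()
  prunable <- names(model$layers)[vapply(model$layers, function(l)
    isTRUE(l$prunable) || (include_heads && l$type %in% c("conv", "dense")),
    logical(1))]
  if (length(prunable) == 0) stop("model has no prunable layer")
  for (nm in prunable) {
    l <- model$layers[[nm]]
    prev <- l$mask %||% build_mask(l$W, 0)
    before_pruned <- sum(prev == 0)
    ma <- layer_mean_abs(l$W, prev)
    thr <- pruning_threshold(ma, alpha)
    mask <- build_mask(l$W, thr, prev)
    kept_singleton <- FALSE
    if (sum(mask) == 0) {
      keep_idx <- order(-abs(as.numeric(l$W)), seq_along(l$W))[1]
      mask[keep_idx] <- 1
      kept_singleton <- TRUE
    }
    l$mask <- mask
    l$W <- l$W * mask
    model$layers[[nm]] <- l
    n_total <- length(l$W)
    n_pruned <- sum(mask == 0)
    rows[[nm]] <- tibble::tibble(
      layer = nm, mean_abs = ma, alpha = alpha, threshold = thr,
      n_total = n_total, n_pruned = n_pruned,
      newly_pruned = n_pruned - before_pruned,
      sparsity = n_pruned / n_total, kept_singleton = kept_singleton)
  }
  list(model = model, report = do.call(rbind, rows))
}

#' Rank weights by magnitude
#'
#' Flat (1-based, column-major) indices ordered by descending `|w|`; ties
#' broken by ascending flat index. Rank 1 is the largest magnitude. The
#' ranking is invariant under sign flips. Exposed as a diagnostic of which
#' connections MWR considers most important.
#'
#' @param weights Numeric array.
#' @return Integer vector of flat indices in rank order.
#' @export
rank_weights <- function(weights) {
  w <- as.numeric(weights)
  order(-abs(w), seq_along(w))
}
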