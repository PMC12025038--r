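# ggplot2 helpers for run and swarm diagnostics.

#' Training curves of a run
#'
#' Validation loss components, the adaptive threshold and validation
#' accuracy across epochs.
#'
#' @param run A `run_report`.
#' @return A ggplot object.
#' @export
plot_training_curves <- function(run) {
  e <- run$epochs
  long <- rbind(
    data.frame(epoch = e$epoch, value = e$val_total_loss, what = "val total loss"),
    data.frame(epoch = e$epoch, value = e$val_seg_loss, what = "val seg loss"),
    data.frame(epoch = e$epoch, value = e$val_class_loss, what = "val class loss"),
    data.frame(epoch = e$epoch, value = e$val_accuracy, what = "val accuracy"),
    data.frame(epoch = e$epoch, value = e$theta, what = "FSS threshold"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~what, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL,
                  title = sprintf("Training run (stop: %s)", run$stop_reason)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.run_report <- function(object, ...) plot_training_curves(object)

#' Best-so-far trace of a firefly search
#'
#' @param result A `firefly_result`.
#' @return A ggplot object.
#' @export
plot_swarm_trace <- function(result) {
  ggplot2::ggplot(result$trace,
                  ggplot2::aes(x = .data$iteration, y = .data$best_value)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "iteration", y = "best objective value",
                  title = "Firefly search: best-so-far") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.firefly_result <- function(object, ...) plot_swarm_trace(object)

#' Display a phantom and its lesion mask
#'
#' @param sample A `labeled_sample`.
#' @return A ggplot object (image and mask side by side).
#' @export
plot_phantom <- function(sample) {
  d <- dim(sample$image)
  grid <- expand.grid(row = seq_len(d[1]), col = seq_len(d[2]))
  df <- rbind(
    cbind(grid, value = as.vector(sample$image), panel = "image"),
    cbind(grid, value = as.vector(sample$mask + 0), panel = "mask"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::facet_wrap(~panel) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("phantom: %s", sample$label),
                  x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}
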