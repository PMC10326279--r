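#' Plot a hypnogram
#'
#' Conventional hypnogram rendering: time in hours on the x axis, stages
#' on the y axis ordered W, REM, N1, N2, N3 from top to bottom.
#'
#' @param object a [hypnogram].
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot hypnogram
#' @export
autoplot.hypnogram <- function(object, ...) {
  ord <- rev(c("W", "REM", "N1", "N2", "N3", "UNSCORED"))
  df <- tibble(hours = object$epoch * epoch_length_s / 3600,
               stage = factor(as.character(object$stage), levels = ord))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$hours, y = .data$stage, group = 1)) +
    ggplot2::geom_step(linewidth = 0.3) +
    ggplot2::labs(x = "time (h)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a confusion matrix
#'
#' Row-normalised tile plot: each cell shows the percentage of epochs of
#' the human-scored row stage predicted as the column stage.
#'
#' @param object a [confusion_matrix()].
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot confusion_matrix
#' @export
autoplot.confusion_matrix <- function(object, ...) {
  pr <- row_normalize(object)
  df <- tidyr::expand_grid(truth = sleep_stages, predicted = sleep_stages)
  df$prop <- as.numeric(t(pr))[match(paste(df$truth, df$predicted),
                                     as.vector(outer(sleep_stages, sleep_stages, paste)))]
  df$truth <- factor(df$truth, levels = rev(sleep_stages))
  df$predicted <- factor(df$predicted, levels = sleep_stages)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                   fill = .data$prop)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f", 100 * .data$prop)), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue", limits = c(0, 1)) +
    ggplot2::labs(x = "predicted", y = "human-scored", fill = "row %") +
    ggplot2::theme_minimal()
}

#' Plot training history
#'
#' Shows the two branch losses, the combined loss and the mixing factor
#' alpha over iterations, plus validation macro-F1 when available.
#'
#' @param object a `stagenet_fit`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot stagenet_fit
#' @export
autoplot.stagenet_fit <- function(object, ...) {
  h <- object$history
  long <- tidyr::pivot_longer(
    h[, c("iteration", "loss_ep", "loss_seq", "loss", "alpha")],
    cols = -"iteration", names_to = "series", values_to = "value")
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$iteration, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~series, scales = "free_y") +
    ggplot2::labs(x = "iteration", y = NULL) +
    ggplot2::theme_minimal()
  p
}
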