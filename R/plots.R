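#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a training history
#'
#' @param object A `cq_fit`.
#' @param ... Unused.
#' @return A ggplot of accuracy (and validation accuracy, when present)
#'   against epoch.
#' @export
autoplot.cq_fit <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history,
                           cols = c("train_accuracy", "val_accuracy"),
                           names_to = "series", values_to = "accuracy")
  h <- h[!is.na(h$accuracy), ]
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$accuracy,
                                  colour = .data$series)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "epoch", y = "accuracy", colour = NULL,
                  title = sprintf("%s model (%s)", object$model$cfg$variant,
                                  object$cfg$optimizer)) +
    ggplot2::theme_minimal()
}

#' Plot multi-run convergence curves
#'
#' @param object A `cq_convergence`.
#' @param ... Unused.
#' @return A ggplot of per-run training-accuracy curves annotated with the
#'   one-way ANOVA F statistic and p-value.
#' @export
autoplot.cq_convergence <- function(object, ...) {
  ggplot2::ggplot(object$curves,
                  ggplot2::aes(x = .data$epoch, y = .data$train_accuracy,
                               colour = factor(.data$run))) +
    ggplot2::geom_line() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "epoch", y = "training accuracy", colour = "run",
                  subtitle = sprintf("ANOVA F = %.3g, p = %.3g",
                                     object$anova_f, object$anova_p)) +
    ggplot2::theme_minimal()
}

#' Display a 2D slice or phantom image
#'
#' @param img A numeric matrix in `[0, 1]`.
#' @param title Optional plot title.
#' @return A ggplot raster image.
#' @export
plot_image <- function(img, title = NULL) {
  df <- tidyr::expand_grid(row = seq_len(nrow(img)), col = seq_len(ncol(img)))
  df$value <- img[cbind(df$row, df$col)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white", limits = c(0, 1)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = title, x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_void()
}
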