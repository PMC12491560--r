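#' Tidiers for fitted networks and reports
#'
#' `tidy()` on a fit returns the per-epoch run history; `glance()` returns a
#' one-row summary (best epoch, best validation loss, final metrics,
#' parameter total). `tidy()` on a parameter report returns the component
#' table.
#'
#' @param x an `lmsaunet_fit`, `lmsa_history`, or `lmsa_param_report`.
#' @param ... unused.
#' @return A tibble.
#' @export
tidy.lmsaunet_fit <- function(x, ...) {
  tibble::as_tibble(x$history)
}

#' @rdname tidy.lmsaunet_fit
#' @export
glance.lmsaunet_fit <- function(x, ...) {
  h <- x$history
  best <- h[h$epoch == x$best_epoch, ]
  p <- count_parameters(x$network)
  tibble::tibble(
    epochs_run = nrow(h),
    best_epoch = x$best_epoch,
    stopped_early = x$stopped_early,
    best_val_loss = best$val_loss[1],
    dice = best$dice[1],
    iou = best$iou[1],
    accuracy = best$accuracy[1],
    fwiou = best$fwiou[1],
    params_millions = attr(p, "total_millions"))
}

#' @rdname tidy.lmsaunet_fit
#' @export
tidy.lmsa_param_report <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Plot a training run
#'
#' Loss curves (training and validation) and the validation Dice trajectory
#' over epochs.
#'
#' @param object an `lmsa_history` or `lmsaunet_fit`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.lmsa_history <- function(object, ...) {
  h <- tibble::as_tibble(object)
  long <- tidyr::pivot_longer(
    h[, c("epoch", "train_loss", "val_loss", "dice")],
    cols = -"epoch", names_to = "series", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value,
                                     color = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~ .data$series, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, color = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.lmsa_history
#' @export
autoplot.lmsaunet_fit <- function(object, ...) {
  autoplot.lmsa_history(object$history, ...)
}

#' @rdname autoplot.lmsa_history
#' @export
autoplot.lmsa_param_report <- function(object, ...) {
  tb <- tibble::as_tibble(object)
  ggplot2::ggplot(tb, ggplot2::aes(x = stats::reorder(.data$component,
                                                      .data$params),
                                   y = .data$params, fill = .data$kind)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "trainable scalars", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a sample or prediction as an image
#'
#' @param sample a `3 x H x W` image array in `[0, 1]`.
#' @param title optional plot title.
#' @return A ggplot object rendering the image.
#' @export
plot_image <- function(sample, title = NULL) {
  d <- dim(sample)
  df <- tidyr::expand_grid(y = seq_len(d[2]), x = seq_len(d[3]))
  df$fill <- grDevices::rgb(as.numeric(t(sample[1, , ])),
                            as.numeric(t(sample[2, , ])),
                            as.numeric(t(sample[3, , ])))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(fill = df$fill) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = title, x = NULL, y = NULL) +
    ggplot2::theme_void()
}
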