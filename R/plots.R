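#' Plot methods
#'
#' `autoplot()` methods for the package's result types: recordings (signal
#' traces with fetal R-peak marks), training histories (loss and validation
#' F1 per epoch), attention traces (Grad-CAM values over the window), and
#' cost tables (per-layer FLOPs).
#'
#' @name octqrs-plots
NULL

#' @rdname octqrs-plots
#' @param object The object to plot.
#' @param window_s Time span in seconds to display for recordings.
#' @param ... Unused.
#' @export
autoplot.octqrs_recording <- function(object, window_s = 5, ...) {
  df <- as_tibble(object)
  df <- df[df$time_s < window_s, ]
  fq <- object$fqrs[object$fqrs < window_s * object$sampling_rate] /
    object$sampling_rate
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$amplitude_uv)) +
    ggplot2::geom_vline(xintercept = fq, colour = "tomato",
                        linetype = "dashed", alpha = 0.6) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$channel)) +
    ggplot2::labs(x = "time (s)", y = "amplitude (µV)",
                  title = object$record_id,
                  subtitle = "dashed: fetal R peaks") +
    ggplot2::theme_minimal()
}

#' @rdname octqrs-plots
#' @export
autoplot.octqrs_fit <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history,
                           c("train_loss", "val_f1"),
                           names_to = "metric", values_to = "value")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = "dotted") +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric), scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL,
                  subtitle = "dotted: selected (best validation F1) epoch") +
    ggplot2::theme_minimal()
}

#' @rdname octqrs-plots
#' @export
autoplot.octqrs_attention <- function(object, ...) {
  df <- tibble(sample = seq_along(object$values) - 1L,
               attention = object$values)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample, y = .data$attention)) +
    ggplot2::geom_area(fill = "steelblue", alpha = 0.7) +
    ggplot2::labs(x = "sample (ms)", y = "attention") +
    ggplot2::theme_minimal()
}

#' @rdname octqrs-plots
#' @export
autoplot.octqrs_cost <- function(object, ...) {
  df <- object[object$role %in% c("conv", "shortcut"), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$layer, y = .data$flops / 1e6,
                                   fill = .data$role)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "MFLOPs (multiply-accumulates)") +
    ggplot2::theme_minimal()
}
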