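#' Plot a fitted background model over the intensity histogram
#'
#' Overlays the plug-in density of a fitted model on the irregular histogram
#' of the regular-probe intensities — the standard visual check of model fit.
#'
#' @param object A `"bg_fit"`.
#' @param data The array the model was fitted to ([array_data()] or probe
#'   table).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot bg_fit
#' @export
autoplot.bg_fit <- function(object, data, ...) {
  d <- as_array_data(data)
  h <- irregular_histogram(d$regular)
  fx <- as_density_function(object$params)
  xs <- seq(min(h$breaks), max(h$breaks), length.out = 512)
  ggplot2::ggplot() +
    ggplot2::geom_rect(
      data = tidy(h),
      ggplot2::aes(xmin = .data$bin_lo, xmax = .data$bin_hi,
                   ymin = 0, ymax = .data$height),
      fill = "grey85", colour = "grey60"
    ) +
    ggplot2::geom_line(
      data = tibble(x = xs, y = fx(xs)),
      ggplot2::aes(.data$x, .data$y), colour = "#7B3294", linewidth = 0.8
    ) +
    ggplot2::labs(x = "intensity", y = "density",
                  title = sprintf("plug-in density (%s)", object$method))
}

#' @method autoplot irregular_histogram
#' @export
autoplot.irregular_histogram <- function(object, ...) {
  ggplot2::ggplot(tidy(object)) +
    ggplot2::geom_rect(
      ggplot2::aes(xmin = .data$bin_lo, xmax = .data$bin_hi,
                   ymin = 0, ymax = .data$height),
      fill = "grey85", colour = "grey60"
    ) +
    ggplot2::labs(x = "intensity", y = "density")
}

#' @method autoplot ad_profile
#' @export
autoplot.ad_profile <- function(object, ...) {
  ggplot2::ggplot(object$binned, ggplot2::aes(.data$log_signal, .data$ad)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "log signal", y = sprintf("absolute deviation (%s scale)",
                                                object$scale),
                  title = object$method)
}

#' @method autoplot op_chars
#' @export
autoplot.op_chars <- function(object, ...) {
  long <- tidyr::pivot_longer(object$curves, c("mean_log2", "sd_log2"),
                              names_to = "panel", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$log2_ref, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(x = "log2 reference", y = NULL)
}
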