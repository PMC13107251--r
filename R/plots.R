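# ggplot2 displays for the package's result types.

dt_labels <- c(sdi25 = "SDI 25 mm", sdi37 = "SDI 37 mm",
               sdphi25 = "SDφ 25 mm", sdphi37 = "SDφ 37 mm",
               dsi = "DSI", dsphi = "DSφ")

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a folded functional trace
#'
#' @param object A `ds_folded` trace.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ds_folded <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$t_cycle, .data$mean,
                                       color = .data$data_type)) +
    ggplot2::geom_line() +
    ggplot2::scale_color_discrete(labels = dt_labels, name = NULL) +
    ggplot2::labs(x = "time in cycle (s)",
                  y = expression(Delta * mu[a] ~ (mm^-1)),
                  title = "Folding-averaged response") +
    ggplot2::theme_minimal()
}

#' Plot retrieved absorption changes across a sweep
#'
#' @param object A `campaign_result`.
#' @param ... Unused.
#' @return A ggplot of `dmua` versus `L1`, one line per data type,
#'   faceted by the varied parameter value when present.
#' @export
autoplot.campaign_result <- function(object, ...) {
  p <- ggplot2::ggplot(dplyr::filter(object, .data$ok),
                       ggplot2::aes(.data$L1, .data$dmua,
                                    color = .data$data_type)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::scale_color_discrete(labels = dt_labels, name = NULL) +
    ggplot2::labs(x = expression(L[1] ~ (mm)),
                  y = expression(Delta * mu[a][","][M] ~ (mm^-1))) +
    ggplot2::theme_minimal()
  if (!all(is.na(object$value)))
    p <- p + ggplot2::facet_wrap(~value)
  p
}

#' Plot a layer-sensitivity matrix
#'
#' @param sensitivity A `layer_sensitivity`.
#' @return A ggplot bar chart of the superficial and deep sensitivity
#'   fractions per data type.
#' @export
plot_sensitivity <- function(sensitivity) {
  d <- tidy.layer_sensitivity(sensitivity)
  d$data_type <- factor(d$data_type, levels = DATA_TYPES)
  ggplot2::ggplot(d, ggplot2::aes(.data$data_type, .data$sensitivity,
                                  fill = .data$layer)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_x_discrete(labels = dt_labels) +
    ggplot2::labs(x = NULL, y = "sensitivity fraction") +
    ggplot2::theme_minimal()
}

#' Plot a synthetic functional time series
#'
#' @param object A `ds_timeseries`.
#' @param ... Unused.
#' @return A ggplot of the retrieved effective absorption change over time.
#' @export
autoplot.ds_timeseries <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time_s, .data$dmua,
                                       color = .data$data_type)) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::scale_color_discrete(labels = dt_labels, name = NULL) +
    ggplot2::labs(x = "time (s)", y = expression(Delta * mu[a] ~ (mm^-1))) +
    ggplot2::theme_minimal()
}
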