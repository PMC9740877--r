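#' Plot a detection result
#'
#' Time course of the accumulated variance-change statistic with the
#' calibrated threshold and flagged intervals, optionally over segment
#' annotations.
#'
#' @param object A `tdgv_detection` from [run_detector()].
#' @param segments Optional segment annotations to shade by condition.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tdgv_detection
#' @export
autoplot.tdgv_detection <- function(object, segments = NULL, ...) {
  trace <- object$trace
  p <- ggplot2::ggplot(trace, ggplot2::aes(x = .data$t))
  if (!is.null(segments)) {
    segments <- segment_table(segments)
    p <- p + ggplot2::geom_rect(
      data = segments,
      ggplot2::aes(xmin = .data$start_s, xmax = .data$end_s,
                   ymin = -Inf, ymax = Inf, fill = .data$condition),
      alpha = 0.15, inherit.aes = FALSE)
  }
  if (nrow(object$events) > 0) {
    p <- p + ggplot2::geom_rect(
      data = object$events,
      ggplot2::aes(xmin = .data$start_s, xmax = .data$end_s,
                   ymin = -Inf, ymax = Inf),
      fill = "red", alpha = 0.2, inherit.aes = FALSE)
  }
  p +
    ggplot2::geom_line(ggplot2::aes(y = .data$cum)) +
    ggplot2::geom_hline(yintercept = object$config$threshold, linetype = "dashed") +
    ggplot2::labs(x = "time (s)", y = "accumulated TDGV change",
                  fill = "condition")
}

#' Plot the components of a variance-change trace
#'
#' Faceted time series of the rolling gap standard deviation, its smoothed
#' version, the per-sample change, and the accumulated statistic.
#'
#' @param trace A trace from [compute_tdgv()] or [run_detector()].
#' @return A ggplot object.
#' @export
plot_trace <- function(trace) {
  long <- tidyr::pivot_longer(
    dplyr::select(trace, "t", "sigma", "sigma_smooth", "delta", "cum"),
    -"t", names_to = "series", values_to = "value")
  long$series <- factor(long$series, levels = c("sigma", "sigma_smooth", "delta", "cum"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
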