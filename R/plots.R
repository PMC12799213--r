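#' Publication-style box plot
#'
#' Box-plot convention used throughout the package: boxes span the 25/75
#' percentiles, whiskers the 10/90 percentiles, a central band marks the
#' median, a cross the mean, and individual data points are overlaid.
#'
#' @param data data frame in long format.
#' @param value,group column names (strings).
#' @return a ggplot object; the computed percentiles are attached as
#'   attribute `box_stats`.
#' @export
plot_box_summary <- function(data, value = "value", group = "group") {
  stats <- data |>
    group_by(.data[[group]]) |>
    summarise(describe_values(.data[[value]]), .groups = "drop")
  p <- ggplot2::ggplot(stats, ggplot2::aes(x = .data[[group]])) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$p10, ymax = .data$p90),
                           width = 0.15) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = as.numeric(factor(.data[[group]])) - 0.25,
      xmax = as.numeric(factor(.data[[group]])) + 0.25,
      ymin = .data$p25, ymax = .data$p75), fill = "grey85", colour = "black") +
    ggplot2::geom_segment(ggplot2::aes(
      x = as.numeric(factor(.data[[group]])) - 0.25,
      xend = as.numeric(factor(.data[[group]])) + 0.25,
      y = .data$median, yend = .data$median), linewidth = 0.8) +
    ggplot2::geom_point(ggplot2::aes(y = .data$mean), shape = 4, size = 3) +
    ggplot2::geom_jitter(data = data,
                         ggplot2::aes(x = .data[[group]], y = .data[[value]]),
                         width = 0.08, alpha = 0.4, size = 0.8) +
    ggplot2::labs(x = NULL, y = value) +
    ggplot2::theme_classic()
  attr(p, "box_stats") <- stats
  p
}

#' Histogram of spot volumes
#'
#' @param spots spot tibble(s); a `channel` column separates fills.
#' @param binwidth histogram bin width, µm³.
#' @return a ggplot object.
#' @export
plot_volume_histogram <- function(spots, binwidth = 0.05) {
  ggplot2::ggplot(spots, ggplot2::aes(x = .data$volume, fill = .data$channel)) +
    ggplot2::geom_histogram(binwidth = binwidth, position = "identity",
                            alpha = 0.6, boundary = 0) +
    ggplot2::labs(x = expression(Volume ~ (mu * m^3)), y = "Spots") +
    ggplot2::theme_classic()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an IV relation
#'
#' @param object an `iv_curve` from [extract_iv()].
#' @param density plot current density (pA/pF) instead of current (pA).
#' @param ... ignored.
#' @return a ggplot object.
#' @export
autoplot.iv_curve <- function(object, density = TRUE, ...) {
  yvar <- if (density) "density" else "current"
  ylab <- if (density) "Current density (pA/pF)" else "Current (pA)"
  ggplot2::ggplot(object, ggplot2::aes(x = .data$voltage, y = .data[[yvar]])) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1.5) +
    ggplot2::labs(x = "Voltage (mV)", y = ylab) +
    ggplot2::theme_classic()
}

#' Overlay dF/F traces of ROI groups
#'
#' @param traces tibble with list-column `dFF` plus `class` labels.
#' @param frame_rate Hz (for the time axis).
#' @param protocol optional [stimulus_protocol()] to shade the stimulus.
#' @return a ggplot object.
#' @export
plot_dff_traces <- function(traces, frame_rate = 20, protocol = NULL) {
  long <- purrr::map_dfr(seq_len(nrow(traces)), function(i) {
    dff <- traces$dFF[[i]]
    tibble(roi = i, class = traces$class[i],
           time_s = (seq_along(dff) - 1) / frame_rate, dff = dff)
  })
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$time_s, y = .data$dff,
                                          group = .data$roi,
                                          colour = .data$class)) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::labs(x = "Time (s)", y = expression(Delta * F / F[0])) +
    ggplot2::theme_classic()
  if (!is.null(protocol))
    p <- p + ggplot2::annotate("rect",
      xmin = (protocol$onset_frame - 1) / frame_rate,
      xmax = (protocol$onset_frame - 1 + protocol$duration_frames) / frame_rate,
      ymin = -Inf, ymax = Inf, alpha = 0.1)
  p
}
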