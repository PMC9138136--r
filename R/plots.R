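#' Plot a pH monitoring log
#'
#' pH estimate against elapsed time with the maintenance band shaded;
#' the standard read-out of a monitored culture run. Requires ggplot2.
#'
#' @param ph_log Data frame in pH-log format (see [read_ph_log()]).
#' @param band Length-2 numeric, the target pH band to shade.
#' @return A ggplot object.
#' @export
plot_ph_log <- function(ph_log, band = c(7.2, 7.6)) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_ph_log needs the ggplot2 package")
  ggplot2::ggplot(ph_log, ggplot2::aes(x = elapsed_s / 3600, y = ph_estimate)) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                      ymin = band[1], ymax = band[2],
                      alpha = 0.15, fill = "steelblue") +
    ggplot2::geom_hline(yintercept = mean(band), linetype = 2, colour = "grey40") +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::labs(x = "elapsed time (h)", y = "estimated pH") +
    ggplot2::theme_minimal()
}

#' Plot a calibration line with its points
#'
#' @param points Calibration points (`ph`, `green_intensity`).
#' @param curve Fitted [ph_calibration()].
#' @return A ggplot object.
#' @export
plot_ph_calibration <- function(points, curve) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_ph_calibration needs the ggplot2 package")
  ggplot2::ggplot(points, ggplot2::aes(x = ph, y = green_intensity)) +
    ggplot2::geom_abline(slope = curve$slope, intercept = curve$intercept,
                         colour = "firebrick") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "pH", y = "green intensity (counts)") +
    ggplot2::theme_minimal()
}
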