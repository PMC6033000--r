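# ggplot2 graphics for arrays, tracks, sensitivity tables and period
# regressions.

#' Plot a receiver array
#'
#' @param array Receiver table (`receiver_id`, `x_m`, `y_m`).
#' @return A ggplot.
#' @export
plot_array <- function(array) {
  validate_array(array)
  ggplot2::ggplot(array, ggplot2::aes(.data$x_m, .data$y_m)) +
    ggplot2::geom_point(shape = 17, size = 3) +
    ggplot2::geom_text(ggplot2::aes(label = .data$receiver_id),
                       nudge_y = diff(range(array$y_m)) * 0.05) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m east)", y = "y (m north)", title = "Receiver array")
}

#' Plot an estimated track against a reference
#'
#' @param track Fix table (`time_s`, `x_m`, `y_m`).
#' @param reference Optional reference track or point(s) with
#'   `x_m`/`y_m` (e.g. a GPS track or the true trajectory).
#' @return A ggplot.
#' @export
plot_track <- function(track, reference = NULL) {
  check_track(track)
  p <- ggplot2::ggplot(track, ggplot2::aes(.data$x_m, .data$y_m)) +
    ggplot2::geom_path(colour = "firebrick", alpha = 0.6) +
    ggplot2::geom_point(colour = "firebrick", size = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m east)", y = "y (m north)")
  if (!is.null(reference)) {
    p <- p + ggplot2::geom_path(data = reference, colour = "steelblue",
                                linetype = "dashed") +
      ggplot2::geom_point(data = reference, colour = "steelblue",
                          shape = 15, size = 0.8)
  }
  p
}

#' Plot a thinning sensitivity table
#'
#' Distance travelled, median speed and median turning angle against
#' transmission period, one panel per metric.
#'
#' @param object An `hr_sensitivity` table from [sensitivity_analysis()].
#' @param ... Unused.
#' @return A ggplot (faceted by metric).
#' @method autoplot hr_sensitivity
#' @export
autoplot.hr_sensitivity <- function(object, ...) {
  long <- object |>
    dplyr::select("transmission_period_s", "distance_m", "speed_median",
                  "angle_median") |>
    tidyr::pivot_longer(-"transmission_period_s",
                        names_to = "metric", values_to = "value") |>
    dplyr::mutate(metric = factor(.data$metric,
                                  c("distance_m", "speed_median", "angle_median"),
                                  c("Distance travelled (m)", "Median speed (m/s)",
                                    "Median turning angle (°)")))
  ggplot2::ggplot(long, ggplot2::aes(.data$transmission_period_s, .data$value)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "Transmission period (s)", y = NULL)
}

#' Plot a period regression fit
#'
#' @param object A `period_fit` from [metric_period_regression()].
#' @param ... Unused.
#' @return A ggplot of the (transformed) metric against period with the
#'   fitted line.
#' @method autoplot period_fit
#' @export
autoplot.period_fit <- function(object, ...) {
  df <- stats::model.frame(object$fit)
  ylab <- if (object$transform == "log10") "log10(metric)" else "metric"
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "firebrick") +
    ggplot2::labs(x = "Transmission period (s)", y = ylab)
}
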