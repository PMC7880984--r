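#' Plot a fitted saccade trajectory
#'
#' Window samples (points) with the fitted Hill sigmoid (line); optionally the
#' analytic velocity profile in a second panel row via `what = "velocity"`.
#'
#' @param object A `hill_fit`.
#' @param what `"position"` (default) or `"velocity"`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot hill_fit
#' @export
autoplot.hill_fit <- function(object, what = c("position", "velocity"), ...) {
  what <- match.arg(what)
  tt <- seq(min(object$data$time), max(object$data$time), length.out = 200)
  if (what == "position") {
    curve <- tibble::tibble(time = tt,
                            y = hill_value(object$params,
                                           pmax(tt - object$t0, 0)))
    ggplot2::ggplot(object$data, ggplot2::aes(.data$time, .data$position)) +
      ggplot2::geom_point(colour = "firebrick") +
      ggplot2::geom_line(data = curve, ggplot2::aes(.data$time, .data$y),
                         colour = "steelblue") +
      ggplot2::labs(x = "time from window start (s)", y = "position (deg)",
                    title = sprintf("Hill fit (R² = %.4f)", object$r_squared))
  } else {
    curve <- tibble::tibble(
      time = tt,
      v = abs(hill_velocity(object$params, pmax(tt - object$t0, 1e-12))))
    ggplot2::ggplot(curve, ggplot2::aes(.data$time, .data$v)) +
      ggplot2::geom_line(colour = "steelblue") +
      ggplot2::labs(x = "time from window start (s)", y = "speed (deg/s)",
                    title = "Analytic velocity profile")
  }
}

#' Plot a main-sequence fit
#'
#' The fitted amplitude/peak-velocity curve over the data points.
#'
#' @param object A `mainseq_fit`.
#' @param grid Amplitude grid for the curve (defaults to the data range).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot mainseq_fit
#' @export
autoplot.mainseq_fit <- function(object, grid = NULL, ...) {
  if (is.null(grid)) {
    lo <- min(object$data$amplitude)
    if (object$model_id == "fixed_sqrt") {
      lo <- max(lo, object$constants$A_th)
    }
    grid <- seq(lo, max(object$data$amplitude), length.out = 200)
  }
  curve <- tibble::tibble(amplitude = grid,
                          peak_velocity = evaluate_model(object, grid))
  ggplot2::ggplot(object$data,
                  ggplot2::aes(.data$amplitude, .data$peak_velocity)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_line(data = curve, colour = "steelblue", linewidth = 1) +
    ggplot2::labs(x = "amplitude (deg)", y = "peak velocity (deg/s)",
                  title = sprintf("%s (adj. R² = %.3f)", object$model_id,
                                  object$r_squared_adjusted))
}

#' Plot bootstrap repeatability against boot size
#'
#' Median and interquartile band of the pairwise curve MAPE (and adjusted
#' R-squared) across boot sizes; the dashed vertical line marks the stability
#' size where parameter estimates stop changing statistically.
#'
#' @param object A `bootstrap_report`.
#' @param statistic `"mape"` (default) or `"r_squared"`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot bootstrap_report
#' @export
autoplot.bootstrap_report <- function(object, statistic = c("mape", "r_squared"),
                                      ...) {
  statistic <- match.arg(statistic)
  td <- tidy(object)
  if (statistic == "mape") {
    p <- ggplot2::ggplot(td, ggplot2::aes(.data$boot_size, .data$mape_median)) +
      ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mape_q1,
                                        ymax = .data$mape_q3), alpha = 0.25) +
      ggplot2::labs(y = "pairwise curve MAPE (%)")
  } else {
    p <- ggplot2::ggplot(td, ggplot2::aes(.data$boot_size, .data$r2_median)) +
      ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$r2_q1,
                                        ymax = .data$r2_q3), alpha = 0.25) +
      ggplot2::labs(y = "adjusted R² (vs. full dataset)")
  }
  p <- p + ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "boot size (saccades per resample)",
                  title = object$model_id)
  if (is.finite(object$stability_size)) {
    p <- p + ggplot2::geom_vline(xintercept = object$stability_size,
                                 linetype = "dashed", colour = "grey40")
  }
  p
}

#' Plot a gaze trace
#'
#' Azimuth and elevation against time, invalid samples omitted.
#'
#' @param object A `gaze_trace`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot gaze_trace
#' @export
autoplot.gaze_trace <- function(object, ...) {
  df <- tidyr::pivot_longer(
    tibble::as_tibble(object)[object$valid, ],
    c("azimuth", "elevation"), names_to = "axis", values_to = "angle")
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$angle,
                                   colour = .data$axis)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "gaze angle (deg)")
}
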