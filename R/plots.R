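#' Plot a sensor voltage trace
#'
#' @param trace A trace tibble (`time_s`, `voltage_au`).
#' @param event Optional [detect_event()] result; spike times and the
#'   interior integration window are marked when given.
#' @return A ggplot.
#' @export
plot_trace <- function(trace, event = NULL) {
  p <- ggplot2::ggplot(trace, ggplot2::aes(.data$time_s, .data$voltage_au)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "sensor voltage (a.u.)")
  if (!is.null(event)) {
    p <- p +
      ggplot2::annotate("rect",
                        xmin = event$interior_start_s,
                        xmax = event$interior_end_s,
                        ymin = -Inf, ymax = Inf, alpha = 0.12,
                        fill = "steelblue") +
      ggplot2::geom_vline(
        xintercept = c(event$front_spike_time_s, event$back_spike_time_s),
        linetype = "dashed", colour = "firebrick"
      )
  }
  p
}

#' @method autoplot dv_calibration
#' @export
autoplot.dv_calibration <- function(object, data = NULL, ...) {
  line <- tibble(
    x = seq(object$valid_range[1], object$valid_range[2], length.out = 50)
  ) |>
    dplyr::mutate(y = object$intercept + object$slope * .data$x)
  p <- ggplot2::ggplot(line, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = object$predictor, y = object$response,
                  title = sprintf("%s vs %s", object$response,
                                  object$predictor))
  if (!is.null(data)) {
    pts <- tibble(x = data[[object$predictor]], y = data[[object$response]])
    p <- p + ggplot2::geom_point(data = pts, alpha = 0.6)
  }
  p
}

#' @method autoplot dv_growth_agg
#' @export
autoplot.dv_growth_agg <- function(object, ...) {
  long <- object |>
    dplyr::transmute(
      t_h = .data$t_h,
      `viscosity (cP)` = .data$viscosity_mean,
      visc_lo = .data$viscosity_mean - .data$viscosity_sd,
      visc_hi = .data$viscosity_mean + .data$viscosity_sd,
      `OD (a.u.)` = .data$od_mean,
      od_lo = .data$od_mean - .data$od_sd,
      od_hi = .data$od_mean + .data$od_sd
    ) |>
    tidyr::pivot_longer(
      cols = c("viscosity (cP)", "OD (a.u.)"),
      names_to = "quantity", values_to = "mean"
    ) |>
    dplyr::mutate(
      lo = ifelse(.data$quantity == "OD (a.u.)", .data$od_lo, .data$visc_lo),
      hi = ifelse(.data$quantity == "OD (a.u.)", .data$od_hi, .data$visc_hi)
    )
  ggplot2::ggplot(long, ggplot2::aes(.data$t_h, .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.25, fill = "steelblue") +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (h)", y = NULL,
                  title = "Replicate mean ± SD over the incubation")
}

#' Plot an along-droplet scan profile
#'
#' @param profile A [scan_profile()] tibble.
#' @return A ggplot; the droplet front is at `s = 0` (left).
#' @export
plot_scan_profile <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(.data$s, .data$voltage_au)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "axial position s (front = 0)",
                  y = "voltage (a.u.)")
}
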