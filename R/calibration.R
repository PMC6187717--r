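# Exact (noise-free) calibrations are a supported case; summary.lm's
# "essentially perfect fit" warning is expected there, not actionable.
quiet_lm_summary <- function(fit) {
  withCallingHandlers(
    summary(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
}

#' Fit a linear calibration
#'
#' Ordinary (or weighted) least squares of `response ~ predictor`, wrapped
#' with the diagnostics and valid range a calibration needs for inversion.
#'
#' @param data A data frame of calibration points.
#' @param predictor,response Column names (strings) of x and y.
#' @param weights Optional weight vector.
#' @param units Optional named character vector
#'   (`c(predictor = ..., response = ...)`) recorded for display.
#' @return An object of class `dv_calibration` with elements `slope`,
#'   `intercept`, `r_squared`, `residual_sd`, `n`, `valid_range` (of the
#'   predictor) and the underlying `lm` fit. [tidy()] and [glance()] methods
#'   expose the fit in broom style.
#' @examples
#' pts <- tibble::tibble(dt = c(103, 116), mu = c(1, 30))
#' cal <- fit_line(pts, "dt", "mu")
#' cal$slope # 2.2308 cP/s
#' @export
fit_line <- function(data, predictor, response, weights = NULL,
                     units = NULL) {
  x <- data[[predictor]]
  y <- data[[response]]
  if (length(unique(x)) < 2) {
    abort("Degenerate fit: need at least 2 distinct predictor values.")
  }
  df <- tibble(.x = x, .y = y)
  fit <- if (is.null(weights)) {
    lm(.y ~ .x, data = df)
  } else {
    lm(.y ~ .x, data = df, weights = weights)
  }
  sm <- quiet_lm_summary(fit)
  structure(
    list(
      predictor = predictor,
      response = response,
      units = units,
      slope = unname(coef(fit)[2]),
      intercept = unname(coef(fit)[1]),
      r_squared = if (nrow(df) > 2) sm$r.squared else 1,
      residual_sd = sm$sigma,
      n = nrow(df),
      valid_range = range(x),
      model = fit
    ),
    class = "dv_calibration"
  )
}

#' @export
print.dv_calibration <- function(x, ...) {
  cat(sprintf("<dv_calibration> %s = %.6g + %.6g * %s\n",
              x$response, x$intercept, x$slope, x$predictor))
  cat(sprintf("  n = %d, R^2 = %.6g, residual SD = %.3g, valid %s in [%.4g, %.4g]\n",
              x$n, x$r_squared, x$residual_sd,
              x$predictor, x$valid_range[1], x$valid_range[2]))
  invisible(x)
}

#' @rdname fit_line
#' @param x A `dv_calibration`.
#' @param ... Unused.
#' @method tidy dv_calibration
#' @export
tidy.dv_calibration <- function(x, ...) {
  if (is.null(x$model)) {
    return(tibble(
      term = c("(Intercept)", x$predictor),
      estimate = c(x$intercept, x$slope),
      std.error = NA_real_, statistic = NA_real_, p.value = NA_real_
    ))
  }
  cf <- summary(x$model)$coefficients
  tibble(
    term = c("(Intercept)", x$predictor),
    estimate = unname(cf[, 1]),
    std.error = unname(cf[, 2]),
    statistic = unname(cf[, 3]),
    p.value = unname(cf[, 4])
  )
}

#' @rdname fit_line
#' @method glance dv_calibration
#' @export
glance.dv_calibration <- function(x, ...) {
  tibble(
    r.squared = x$r_squared,
    sigma = x$residual_sd,
    nobs = x$n,
    predictor = x$predictor,
    response = x$response
  )
}

# An anchored (data-free) calibration line.
anchored_calibration <- function(predictor, response, slope, intercept,
                                 valid_range, units = NULL) {
  structure(
    list(
      predictor = predictor, response = response, units = units,
      slope = slope, intercept = intercept,
      r_squared = NA_real_, residual_sd = NA_real_, n = 2L,
      valid_range = valid_range, model = NULL
    ),
    class = "dv_calibration"
  )
}

#' Default viscosity calibration (passage time to viscosity)
#'
#' The inverse of the reference affine law anchored to the endpoint pairs
#' (103 s, 1 cP) and (116 s, 30 cP) at 100 mbar:
#' `mu = 2.230769 * dt - 228.769` cP. At other pressures the passage times
#' scale as `100 / p_mbar`, so the slope scales as `p_mbar / 100` while the
#' intercept is pressure-invariant.
#'
#' @param pressure_mbar Operating pressure the passage times were measured at.
#' @return A `dv_calibration` mapping `passage_time_s` to `viscosity_cp`,
#'   valid over the passage times of the 1-30 cP calibration span.
#' @export
default_viscosity_calibration <- function(pressure_mbar = 100) {
  scale <- pressure_mbar / 100
  anchored_calibration(
    predictor = "passage_time_s", response = "viscosity_cp",
    slope = scale / BETA_100,
    intercept = -ALPHA_100 / BETA_100,
    valid_range = c(ALPHA_100 + BETA_100, ALPHA_100 + 30 * BETA_100) / scale,
    units = c(predictor = "s", response = "cP")
  )
}

#' Default optical-density calibration (integrated voltage to OD)
#'
#' The line through the reference endpoints (1.8 a.u., OD 2.5) and
#' (2.3 a.u., OD 0.05): `OD = -4.9 * V + 11.32`, nominally valid on the
#' 1.8-2.3 a.u. voltage range.
#'
#' @return A `dv_calibration` mapping `integrated_signal_au` to `od_au`.
#' @export
default_od_calibration <- function() {
  anchored_calibration(
    predictor = "integrated_signal_au", response = "od_au",
    slope = -2.45 / 0.5, intercept = 2.5 + 2.45 / 0.5 * 1.8,
    valid_range = c(1.8, 2.3),
    units = c(predictor = "a.u.", response = "a.u.")
  )
}

#' Invert a viscosity calibration
#'
#' Evaluates `mu = slope * dt + intercept` with a 1-SE uncertainty propagated
#' from the fit (prediction of the mean response at `dt`); anchored default
#' calibrations carry no residual information and report `NA` SE.
#'
#' @param passage_time_s Measured passage time(s), s.
#' @param cal A `dv_calibration` whose response is `viscosity_cp`.
#' @return A tibble: `passage_time_s`, `viscosity_cp`, `se_cp`,
#'   `extrapolated` (outside the calibration's valid range; flagged, not
#'   fatal).
#' @export
viscosity_from_time <- function(passage_time_s,
                                cal = default_viscosity_calibration()) {
  if (!inherits(cal, "dv_calibration") || cal$response != "viscosity_cp") {
    abort("`cal` must be a dv_calibration with response `viscosity_cp`.")
  }
  extrap <- passage_time_s < cal$valid_range[1] |
    passage_time_s > cal$valid_range[2]
  se <- if (is.null(cal$model)) {
    rep(NA_real_, length(passage_time_s))
  } else {
    predict(cal$model, newdata = data.frame(.x = passage_time_s),
            se.fit = TRUE)$se.fit
  }
  tibble(
    passage_time_s = passage_time_s,
    viscosity_cp = cal$slope * passage_time_s + cal$intercept,
    se_cp = se,
    extrapolated = extrap
  )
}

#' Invert an optical-density calibration
#'
#' @param signal_au Time-averaged interior voltage(s), a.u.
#' @param cal A `dv_calibration` whose response is `od_au`.
#' @return A tibble: `integrated_signal_au`, `od_au`, `extrapolated`.
#'   Negative inverted ODs are floored at 0 with a warning; readings outside
#'   the nominal voltage range are flagged as extrapolated, not rejected
#'   (growth runs legitimately exceed the OD 2.5 anchor).
#' @export
od_from_signal <- function(signal_au, cal = default_od_calibration()) {
  if (!inherits(cal, "dv_calibration") || cal$response != "od_au") {
    abort("`cal` must be a dv_calibration with response `od_au`.")
  }
  od <- cal$slope * signal_au + cal$intercept
  if (any(od < 0)) {
    warn("Negative inverted OD floored at 0.")
    od <- pmax(od, 0)
  }
  tibble(
    integrated_signal_au = signal_au,
    od_au = od,
    extrapolated = signal_au < cal$valid_range[1] |
      signal_au > cal$valid_range[2]
  )
}

#' Gaussian fit to a passage-time sample
#'
#' Maximum-likelihood normal fit; for the normal family this is the sample
#' mean and sample SD.
#'
#' @param x Numeric sample, length >= 10.
#' @return A tibble: `mean`, `sd`, `n`.
#' @export
fit_gaussian <- function(x) {
  if (length(x) < 10) abort("Need at least 10 observations for a Gaussian fit.")
  tibble(mean = mean(x), sd = sd(x), n = length(x))
}

#' Viscosity resolution of the instrument
#'
#' Two-sigma single-measurement criterion: the smallest viscosity difference
#' resolvable from one transit is `2 * sigma_dt * slope`, with `sigma_dt`
#' the passage-time SD and `slope` the calibration slope in cP/s. With the
#' default timing jitter and 100 mbar slope this evaluates to 0.05 cP.
#'
#' @param sigma_dt Passage-time SD, s.
#' @param cal A viscosity `dv_calibration`.
#' @return A tibble: `sigma_dt_s`, `slope_cp_per_s`, `resolution_cp`,
#'   `criterion`.
#' @export
resolution <- function(sigma_dt, cal = default_viscosity_calibration()) {
  if (sigma_dt < 0) abort("`sigma_dt` must be non-negative.")
  tibble(
    sigma_dt_s = sigma_dt,
    slope_cp_per_s = cal$slope,
    resolution_cp = 2 * sigma_dt * cal$slope,
    criterion = "two-sigma single measurement"
  )
}

#' Fit a CFU-vs-OD calibration
#'
#' @param data A data frame with OD and CFU columns.
#' @param od,cfu Column names.
#' @param force_origin Constrain the line through the origin (zero cells at
#'   zero OD).
#' @return A `dv_calibration` (intercept 0 when constrained).
#' @export
fit_cfu_calibration <- function(data, od = "od_au", cfu = "cfu_per_ml",
                                force_origin = FALSE) {
  if (!force_origin) {
    return(fit_line(data, od, cfu))
  }
  x <- data[[od]]
  y <- data[[cfu]]
  if (length(unique(x)) < 2) abort("Degenerate fit: need >= 2 distinct OD values.")
  df <- tibble(.x = x, .y = y)
  fit <- lm(.y ~ 0 + .x, data = df)
  sm <- quiet_lm_summary(fit)
  structure(
    list(
      predictor = od, response = cfu, units = NULL,
      slope = unname(coef(fit)[1]), intercept = 0,
      r_squared = sm$r.squared, residual_sd = sm$sigma, n = nrow(df),
      valid_range = range(x), model = NULL
    ),
    class = "dv_calibration"
  )
}
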