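# Centred moving average with truncated windows at the ends.
moving_average <- function(x, window) {
  if (window <= 1) return(x)
  half <- floor(window / 2)
  n <- length(x)
  vapply(seq_len(n), function(i) {
    mean(x[max(1, i - half):min(n, i + half)])
  }, numeric(1))
}

#' Assemble calibrated growth records from event-level measurements
#'
#' Inverts every transit through the viscosity and OD calibrations, one
#' calibrated point per event. Events outside a calibration's valid range are
#' kept and flagged, not dropped.
#'
#' @param events A tibble with columns `replicate`, `t_h`, `passage_time_s`,
#'   `integrated_signal_au` (as produced by [generate_run()] or read from an
#'   events CSV).
#' @param viscosity_cal,od_cal `dv_calibration` objects.
#' @return A tibble of class `dv_growth`: `replicate`, `t_h`,
#'   `viscosity_cp`, `viscosity_se`, `od_au`, `flagged`.
#' @export
assemble <- function(events,
                     viscosity_cal = default_viscosity_calibration(),
                     od_cal = default_od_calibration()) {
  if (nrow(events) == 0) {
    warn("Empty event list: returning an empty growth record.")
    out <- tibble(replicate = integer(), t_h = numeric(),
                  viscosity_cp = numeric(), viscosity_se = numeric(),
                  od_au = numeric(), flagged = logical())
    class(out) <- c("dv_growth", class(out))
    return(out)
  }
  mu <- viscosity_from_time(events$passage_time_s, viscosity_cal)
  od <- od_from_signal(events$integrated_signal_au, od_cal)
  out <- events |>
    dplyr::mutate(
      viscosity_cp = mu$viscosity_cp,
      viscosity_se = mu$se_cp,
      od_au = od$od_au,
      flagged = mu$extrapolated | od$extrapolated
    ) |>
    dplyr::select("replicate", "t_h", "viscosity_cp", "viscosity_se",
                  "od_au", "flagged") |>
    dplyr::arrange(.data$replicate, .data$t_h)
  class(out) <- c("dv_growth", class(out))
  out
}

#' Aggregate replicates onto the common time grid
#'
#' Pointwise mean and SD across replicates at each cadence tick. Replicates
#' must share the grid; small mismatches are snapped to the nearest common
#' tick, gaps larger than one cadence are an error.
#'
#' @param record A `dv_growth` tibble with >= 2 replicates.
#' @return A tibble of class `dv_growth_agg`: `t_h`, `viscosity_mean`,
#'   `viscosity_sd`, `od_mean`, `od_sd`, `n`.
#' @export
aggregate_replicates <- function(record) {
  if (dplyr::n_distinct(record$replicate) < 2) {
    abort("Need at least 2 replicates to aggregate.")
  }
  grid <- sort(unique(record$t_h))
  cadence <- median(diff(grid))
  snapped <- grid[pmax(1, pmin(length(grid),
                               findInterval(record$t_h, grid - cadence / 2)))]
  if (any(abs(snapped - record$t_h) > cadence)) {
    abort("Replicate time grids differ by more than one cadence tick.")
  }
  out <- record |>
    dplyr::mutate(t_h = snapped) |>
    dplyr::group_by(.data$t_h) |>
    dplyr::summarise(
      viscosity_mean = mean(.data$viscosity_cp),
      viscosity_sd = sd(.data$viscosity_cp),
      od_mean = mean(.data$od_au),
      od_sd = sd(.data$od_au),
      n = dplyr::n(),
      .groups = "drop"
    )
  class(out) <- c("dv_growth_agg", class(out))
  out
}

# Pull the OD and time columns out of a per-replicate or aggregated curve.
curve_columns <- function(curve) {
  od_col <- intersect(c("od_mean", "od_au"), names(curve))[1]
  visc_col <- intersect(c("viscosity_mean", "viscosity_cp"), names(curve))[1]
  if (is.na(od_col)) abort("Curve must carry an OD column (od_au or od_mean).")
  list(t = curve$t_h, od = curve[[od_col]],
       visc = if (!is.na(visc_col)) curve[[visc_col]] else NULL)
}

#' Locate the OD inflexion
#'
#' Time of the maximum first difference of the smoothed OD curve (centred
#' moving average); ties break to the earliest tick.
#'
#' @param curve A per-replicate or aggregated growth curve (tibble with
#'   `t_h` and an OD column), >= 7 points.
#' @param window Smoothing window, ticks.
#' @param min_range Minimum smoothed OD range, a.u.; flatter curves have no
#'   inflexion and raise an error.
#' @return Inflexion time, h.
#' @export
od_inflexion <- function(curve, window = 5, min_range = 0.1) {
  cc <- curve_columns(curve)
  if (length(cc$t) < 7) abort("Need at least 7 points to locate an inflexion.")
  sm <- moving_average(cc$od, window)
  if (diff(range(sm)) < min_range) {
    abort("No inflexion: OD curve is flat within `min_range`.")
  }
  slope <- diff(sm) / diff(cc$t)
  i <- which.max(slope) # which.max returns the earliest tie
  mean(cc$t[c(i, i + 1)])
}

#' Segment the growth phases of an OD curve
#'
#' Conventions (all configurable; the canonical batch-culture phases have no
#' universal numeric boundaries): lag ends at the last tick with smoothed OD
#' below `od_min + lag_frac * range`; log ends at the first tick above
#' `od_max - top_frac * range`; stationary ends at the last tick before a
#' sustained decline (`decline_run` consecutive decreasing ticks). A curve
#' whose smoothed range is below `min_range` is all lag (no growth).
#'
#' @param curve A growth curve tibble (`t_h` plus an OD column).
#' @param lag_frac,top_frac Range fractions for the lag/log boundaries.
#' @param decline_run Consecutive decreasing ticks that mark sustained
#'   decline.
#' @param window Smoothing window, ticks.
#' @param min_range Minimum smoothed OD range for growth to be declared.
#' @return An object of class `dv_phases`: list with `lag_end`, `log_end`,
#'   `stationary_end`, `od_inflexion` (h; NA where undefined) and `labels`,
#'   a tibble (`t_h`, `phase`).
#' @export
segment_phases <- function(curve, lag_frac = 0.05, top_frac = 0.05,
                           decline_run = 3, window = 5, min_range = 0.1) {
  cc <- curve_columns(curve)
  if (length(cc$t) < 7) abort("Curve too short to segment.")
  t <- cc$t
  sm <- moving_average(cc$od, window)
  rng <- diff(range(sm))

  if (rng < min_range) {
    out <- list(lag_end = t[length(t)], log_end = NA_real_,
                stationary_end = NA_real_, od_inflexion = NA_real_,
                labels = tibble(t_h = t, phase = "lag"))
    class(out) <- "dv_phases"
    return(out)
  }

  od_min <- min(sm)
  od_max <- max(sm)
  i_peak <- which.max(sm)

  below <- which(sm < od_min + lag_frac * rng & seq_along(sm) < i_peak)
  lag_end <- if (length(below)) t[max(below)] else t[1]

  above <- which(sm > od_max - top_frac * rng)
  log_end <- t[min(above)]

  decl <- diff(sm) < 0
  run <- rle(decl)
  ends <- cumsum(run$lengths)
  starts <- ends - run$lengths + 1
  cand <- which(run$values & run$lengths >= decline_run &
                  starts >= min(above))
  stationary_end <- if (length(cand)) t[starts[cand[1]]] else t[length(t)]

  infl <- od_inflexion(curve, window = window, min_range = min_range)

  # Enforce the phase ordering: lag <= inflexion <= log <= stationary.
  lag_end <- min(lag_end, infl)
  log_end <- max(log_end, infl)
  stationary_end <- max(stationary_end, log_end)

  labels <- tibble(
    t_h = t,
    phase = dplyr::case_when(
      t <= lag_end ~ "lag",
      t <= log_end ~ "log",
      t <= stationary_end ~ "stationary",
      TRUE ~ "death"
    )
  )
  out <- list(lag_end = lag_end, log_end = log_end,
              stationary_end = stationary_end, od_inflexion = infl,
              labels = labels)
  class(out) <- "dv_phases"
  out
}

#' @export
print.dv_phases <- function(x, ...) {
  cat(sprintf(
    "<dv_phases> lag <= %.2f h | inflexion %.2f h | log <= %.2f h | stationary <= %.2f h\n",
    x$lag_end, x$od_inflexion, x$log_end, x$stationary_end
  ))
  invisible(x)
}

#' @rdname segment_phases
#' @param x A `dv_phases` object.
#' @param ... Unused.
#' @method tidy dv_phases
#' @export
tidy.dv_phases <- function(x, ...) {
  tibble(
    boundary = c("lag_end", "od_inflexion", "log_end", "stationary_end"),
    t_h = c(x$lag_end, x$od_inflexion, x$log_end, x$stationary_end)
  )
}

#' Summary statistics of a growth record
#'
#' Baseline viscosity is the mean over the detected lag phase; the viscosity
#' maximum (value and time) and OD maximum come from the (optionally
#' smoothed) series; finals are the last tick. With multiple replicates a
#' one-row summary per replicate is returned.
#'
#' @param record A `dv_growth` tibble (one or many replicates) or a
#'   `dv_growth_agg`.
#' @param smooth_window Smoothing window (ticks) for the extrema. Default 1
#'   (raw series): at the default cadence the calibrated-viscosity noise
#'   (~0.03 cP) is negligible next to replicate variation, and smoothing a
#'   kinked peak only biases it down. Raise for noisier data.
#' @param ... Passed to [segment_phases()].
#' @return A tibble with columns `replicate` (where applicable),
#'   `mu_baseline`, `mu_max`, `t_mu_max`, `od_max`, `mu_final`, `od_final`.
#' @export
summarize_growth <- function(record, smooth_window = 1, ...) {
  one <- function(df) {
    cc <- curve_columns(df)
    if (length(cc$t) == 0) abort("Empty series.")
    phases <- tryCatch(segment_phases(df, ...), error = function(e) NULL)
    sm_mu <- moving_average(cc$visc, smooth_window)
    sm_od <- moving_average(cc$od, smooth_window)
    in_lag <- if (!is.null(phases)) cc$t <= phases$lag_end else rep(TRUE, length(cc$t))
    i_max <- which.max(sm_mu)
    tibble(
      mu_baseline = mean(cc$visc[in_lag]),
      mu_max = sm_mu[i_max],
      t_mu_max = cc$t[i_max],
      od_max = max(sm_od),
      mu_final = cc$visc[length(cc$t)],
      od_final = cc$od[length(cc$t)]
    )
  }
  if ("replicate" %in% names(record) &&
      dplyr::n_distinct(record$replicate) > 1) {
    record |>
      dplyr::group_by(.data$replicate) |>
      dplyr::group_modify(~ one(.x)) |>
      dplyr::ungroup()
  } else {
    one(record)
  }
}

#' Time-invariance test (negative control)
#'
#' Least-squares slope of viscosity and OD against time with a confidence
#' interval; a series passes when its CI covers zero. The negative-control
#' droplet (nutrient only) should pass both; a growth run should fail.
#'
#' @param record A `dv_growth` tibble (single replicate or pooled),
#'   >= 10 points.
#' @param conf_level CI level.
#' @return A tibble with one row per series: `series`, `slope_per_h`,
#'   `ci_low`, `ci_high`, `p_value`, `pass`.
#' @export
invariance_test <- function(record, conf_level = 0.95) {
  if (nrow(record) < 10) abort("Need at least 10 points for the invariance test.")
  one <- function(y, name) {
    if (sd(y) == 0) {
      return(tibble(series = name, slope_per_h = 0, ci_low = 0, ci_high = 0,
                    p_value = 1, pass = TRUE))
    }
    fit <- lm(y ~ record$t_h)
    ci <- confint(fit, level = conf_level)[2, ]
    tibble(
      series = name,
      slope_per_h = unname(coef(fit)[2]),
      ci_low = ci[[1]], ci_high = ci[[2]],
      p_value = summary(fit)$coefficients[2, 4],
      pass = ci[[1]] <= 0 && ci[[2]] >= 0
    )
  }
  dplyr::bind_rows(
    one(record$viscosity_cp, "viscosity_cp"),
    one(record$od_au, "od_au")
  )
}
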