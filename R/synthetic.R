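#' Growth scenario: the ground-truth conditions of a 48-h culture run
#'
#' Collects every parameter of the synthetic bacterial-culture experiment:
#' the logistic-plus-death optical-density trajectory, the OD-slaved
#' viscosity trajectory with its shear-(pressure-)dependent peak, the
#' replicate-to-replicate variability, and the measurement cadence.
#'
#' Defaults emulate an *E. coli* DH5-alpha batch culture in LB broth measured
#' in a circulating 2.4 uL droplet: OD rises from 0.05 to a maximum of
#' 2.83 a.u. with inflexion near 6 h; viscosity starts at 1.83 cP, peaks at
#' the OD inflexion (23.31 cP at 100 mbar, ~10 cP at 200 mbar, ~5.5 cP at
#' 300 mbar, reflecting shear-dependent aggregation) and relaxes towards
#' 5.5 cP by 48 h. Replicate coefficients of variation are back-solved from
#' the reference spreads (0.38/1.83, 1.86/23.31, 0.07/2.83). Growth-rate,
#' stationary-onset and death-slope defaults are conventions chosen for a
#' realistic batch curve; they are not independently constrained.
#'
#' @param pressure_mbar Operating pressure; must have an entry in `mu_max`.
#' @param od0 Lag-phase optical density, a.u.
#' @param od_max Logistic plateau OD, a.u.
#' @param k_growth Logistic growth rate, h^-1.
#' @param t_inflex Logistic midpoint = OD inflexion time, h.
#' @param t_stationary Onset of the death-phase OD decline, h.
#' @param death_slope Linear OD decline past `t_stationary`, a.u./h.
#' @param mu_base Lag-phase (fresh-medium) viscosity, cP.
#' @param mu_max Named vector of peak viscosities by pressure, cP.
#' @param mu_inf Long-time asymptotic viscosity, cP.
#' @param decay_tau Post-peak exponential relaxation time, h.
#' @param rise_exponent Shape exponent coupling the viscosity rise to the
#'   normalized OD rise (see [viscosity_curve()]). The default 2 keeps
#'   lag-phase viscosity changes negligible relative to measurement scatter
#'   while preserving the peak value and timing.
#' @param replicate_cv Named list of replicate coefficients of variation for
#'   `mu_base`, `mu_max` and `od_max`.
#' @param cadence_min Minutes between transits.
#' @param duration_h Total run length, h.
#' @param n_replicates Number of independent droplets.
#' @param seed Integer seed for the whole run.
#' @return An object of class `dv_scenario`.
#' @export
growth_scenario <- function(pressure_mbar = 100,
                            od0 = 0.05, od_max = 2.83, k_growth = 1.0,
                            t_inflex = 6, t_stationary = 12,
                            death_slope = 0.0064,
                            mu_base = 1.83,
                            mu_max = c("100" = 23.31, "200" = 10, "300" = 5.5),
                            mu_inf = 5.5, decay_tau = 6, rise_exponent = 2,
                            replicate_cv = list(mu_base = 0.21, mu_max = 0.08,
                                                od_max = 0.025),
                            cadence_min = 10, duration_h = 48,
                            n_replicates = 10, seed = 1L) {
  if (od_max <= od0 || od0 <= 0) abort("Need od_max > od0 > 0.")
  if (mu_base <= 0 || mu_inf <= 0 || any(mu_max <= 0)) {
    abort("Viscosity parameters must be positive.")
  }
  if (cadence_min <= 0 || duration_h <= 0) {
    abort("`cadence_min` and `duration_h` must be positive.")
  }
  sc <- structure(
    list(
      pressure_mbar = pressure_mbar,
      od0 = od0, od_max = od_max, k_growth = k_growth, t_inflex = t_inflex,
      t_stationary = t_stationary, death_slope = death_slope,
      mu_base = mu_base, mu_max = mu_max, mu_inf = mu_inf,
      decay_tau = decay_tau, rise_exponent = rise_exponent,
      replicate_cv = replicate_cv,
      cadence_min = cadence_min, duration_h = duration_h,
      n_replicates = n_replicates, seed = as.integer(seed)
    ),
    class = "dv_scenario"
  )
  scenario_mu_peak(sc) # validates the pressure key
  sc
}

scenario_mu_peak <- function(scenario) {
  key <- as.character(scenario$pressure_mbar)
  if (!key %in% names(scenario$mu_max)) {
    abort(sprintf(
      "No peak viscosity configured for %s mbar (known: %s).",
      key, paste(names(scenario$mu_max), collapse = ", ")
    ))
  }
  unname(scenario$mu_max[[key]])
}

#' Ground-truth optical density trajectory
#'
#' Logistic growth with a linear death-phase decline:
#' `OD(t) = od0 + (od_max - od0) / (1 + exp(-k (t - t_inflex)))
#'  - death_slope * max(0, t - t_stationary)`, floored at `od0`. The
#' inflexion of the logistic part sits at `t_inflex`.
#'
#' @param t_h Time, h (vectorised).
#' @param scenario A [growth_scenario()] (or a list with the OD fields).
#' @return OD, a.u.
#' @export
od_curve <- function(t_h, scenario = growth_scenario()) {
  if (any(t_h < 0)) abort("`t_h` must be non-negative.")
  logist <- scenario$od0 + (scenario$od_max - scenario$od0) /
    (1 + exp(-scenario$k_growth * (t_h - scenario$t_inflex)))
  pmax(scenario$od0,
       logist - scenario$death_slope * pmax(0, t_h - scenario$t_stationary))
}

#' Ground-truth viscosity trajectory
#'
#' Up to the OD inflexion the viscosity rise is slaved to the normalized
#' logistic OD rise through a shape exponent `p`:
#' `mu(t) = mu_base + (mu_peak - mu_base) * r(t)^p` with
#' `r(t) = (OD(t) - od0) / (OD(t_inflex) - od0)`. With the default `p = 2`
#' the lag phase stays flat at `mu_base` (changes well below the replicate
#' scatter) while `mu(t_inflex) = mu_peak` exactly. Past the inflexion the
#' viscosity relaxes exponentially to `mu_inf`:
#' `mu(t) = mu_inf + (mu_peak - mu_inf) exp(-(t - t_inflex)/decay_tau)`,
#' continuous at the peak.
#'
#' @param t_h Time, h (vectorised).
#' @param scenario A [growth_scenario()].
#' @param mu_peak Peak viscosity, cP; defaults to the scenario's value for
#'   its configured pressure.
#' @param mu_base Baseline viscosity, cP (per-replicate draws override it).
#' @return Viscosity, cP.
#' @export
viscosity_curve <- function(t_h, scenario = growth_scenario(),
                            mu_peak = scenario_mu_peak(scenario),
                            mu_base = scenario$mu_base) {
  if (any(t_h < 0)) abort("`t_h` must be non-negative.")
  # Pure logistic part (death decline never applies before the inflexion).
  sig <- 1 / (1 + exp(-scenario$k_growth * (t_h - scenario$t_inflex)))
  ratio <- pmin(1, 2 * sig) # (OD(t) - od0) / (OD(t_inflex) - od0)
  rise <- mu_base + (mu_peak - mu_base) * ratio^scenario$rise_exponent
  relax <- scenario$mu_inf + (mu_peak - scenario$mu_inf) *
    exp(-(t_h - scenario$t_inflex) / scenario$decay_tau)
  ifelse(t_h <= scenario$t_inflex, rise, relax)
}

#' Aggregation regime of the axial OD profile
#'
#' Below 5 cP the droplet content is homogeneous; between 5 and 15 cP on the
#' rising branch, bacteria form scattered aggregates (patchy profile); above
#' 15 cP on the rising branch a single conglomerate sits in the trailing
#' quarter of the plug. After the viscosity peak the content is homogeneous
#' again regardless of viscosity.
#'
#' @param viscosity_cp Viscosity, cP (vectorised).
#' @param post_peak Logical, past the viscosity maximum?
#' @param thresholds Regime thresholds, cP.
#' @return Character vector: `"uniform"`, `"patchy"` or `"rear_conglomerate"`.
#' @export
profile_regime <- function(viscosity_cp, post_peak = FALSE,
                           thresholds = c(patchy = 5, conglomerate = 15)) {
  dplyr::case_when(
    post_peak ~ "uniform",
    viscosity_cp < thresholds[["patchy"]] ~ "uniform",
    viscosity_cp < thresholds[["conglomerate"]] ~ "patchy",
    TRUE ~ "rear_conglomerate"
  )
}

#' Generate an axial OD profile for one droplet
#'
#' Builds a normalized axial profile for the regime implied by the viscosity
#' and growth phase (see [profile_regime()]), then scales it so its spatial
#' mean equals `true_od` exactly. Patchy profiles carry 2-4 random Gaussian
#' aggregate bumps; the rear-conglomerate profile concentrates excess OD in
#' the trailing 25% of the plug.
#'
#' @param true_od Spatial-mean optical density, a.u.
#' @param viscosity_cp Droplet viscosity, cP.
#' @param post_peak Logical, past the viscosity maximum?
#' @param n Number of grid points on `s` in `[0, 1]` (0 = front).
#' @param seed Optional integer seed (scoped to this call).
#' @return A tibble with columns `s`, `od` and attribute `regime`.
#' @export
spatial_profile <- function(true_od, viscosity_cp, post_peak = FALSE,
                            n = 101, seed = NULL) {
  if (true_od < 0 || viscosity_cp < 0) abort("Inputs must be non-negative.")
  regime <- profile_regime(viscosity_cp, post_peak)
  s <- seq(0, 1, length.out = n)
  w <- switch(
    regime,
    uniform = rep(1, n),
    patchy = withr::with_seed(seed %||% sample.int(.Machine$integer.max, 1), {
      n_bumps <- sample(2:4, 1)
      centres <- runif(n_bumps, 0.05, 0.95)
      widths <- runif(n_bumps, 0.03, 0.08)
      amps <- runif(n_bumps, 0.5, 2)
      1 + Reduce(`+`, lapply(seq_len(n_bumps), function(i) {
        amps[i] * exp(-(s - centres[i])^2 / (2 * widths[i]^2))
      }))
    }),
    rear_conglomerate = 0.4 + 6 * exp(-(s - 0.875)^2 / (2 * 0.06^2))
  )
  od <- if (true_od == 0) rep(0, n) else true_od * w / mean(w)
  out <- tibble(s = s, od = od)
  attr(out, "regime") <- regime
  out
}

#' Colony-forming units from optical density
#'
#' Linear CFU/OD conversion. The default factor 8e8 CFU/mL per OD unit is a
#' conventional order-of-magnitude value for *E. coli* in LB, supplied only
#' so synthetic CFU calibrations can be exercised; it is configuration, not
#' a measured constant.
#'
#' @param od Optical density, a.u. (vectorised).
#' @param factor CFU/mL per OD unit.
#' @return CFU/mL.
#' @export
cfu_from_od <- function(od, factor = 8e8) {
  if (any(od < 0)) abort("`od` must be non-negative.")
  factor * od
}

# Lognormal replicate factor with mean 1 and coefficient of variation cv.
replicate_factor <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# Event-level affine calibration implied by the instrument network:
# dt = alpha' + beta' * mu_cP at the instrument's operating pressure.
event_coefficients <- function(instrument) {
  geo <- instrument$geometry
  net <- instrument$network
  dp <- instrument$operating_point$pressure_pa
  lS <- geo$sensor_separation * geo$cross_section
  list(
    alpha = lS * net$channel_resistance / dp,
    beta = lS * net$droplet_resistance_coefficient * 1e-3 / dp
  )
}

#' Generate a full synthetic growth run
#'
#' Draws per-replicate multiplicative factors (lognormal, mean 1, with the
#' scenario's CVs) for the baseline viscosity, peak viscosity and plateau OD,
#' then emits one event-level transit per cadence tick per replicate:
#' `passage_time = alpha' + beta' * mu_true + N(0, sigma_dt)` and
#' `integrated_signal = OD-to-voltage map(od_true) + N(0, sigma_sig)`,
#' with `alpha'`, `beta'` implied by the instrument network at its operating
#' pressure. The ground-truth table records the true trajectory and the
#' aggregation regime at every tick.
#'
#' @param scenario A [growth_scenario()].
#' @param instrument A [default_instrument()] at the scenario's pressure.
#' @param seed Integer seed; defaults to the scenario's.
#' @param level `"event"` (default): emit event-level records only, the fast
#'   path for long runs. `"trace"`: additionally synthesise the full sensor
#'   voltage traces of every transit (with the tick's spatial OD profile);
#'   capped at 2000 events to stay desk-scale.
#' @return A list of class `dv_run`: `events` (tibble `replicate`, `t_h`,
#'   `passage_time_s`, `integrated_signal_au`) and `truth` (tibble
#'   `replicate`, `t_h`, `true_od_au`, `true_visc_cp`, `regime`). With
#'   `level = "trace"` also `traces`, a tibble with a list-column `transit`
#'   of [simulate_transit()] results.
#' @examples
#' run <- generate_run(growth_scenario(seed = 7))
#' dplyr::count(run$truth, regime)
#' @export
generate_run <- function(scenario = growth_scenario(),
                         instrument = default_instrument(scenario$pressure_mbar),
                         seed = scenario$seed,
                         level = c("event", "trace")) {
  level <- match.arg(level)
  ticks <- seq(0, scenario$duration_h, by = scenario$cadence_min / 60)
  n_events <- length(ticks) * scenario$n_replicates
  if (n_events > 1e6) {
    abort(sprintf("Run would produce %d events (> 1e6); reduce duration, cadence or replicates.", n_events))
  }
  if (level == "trace" && n_events > 2000) {
    abort("Trace-level synthesis is capped at 2000 events; shorten the run or use level = \"event\".")
  }
  coefs <- event_coefficients(instrument)
  sens <- instrument$sensor
  cv <- scenario$replicate_cv

  withr::with_seed(seed, {
    f_base <- replicate_factor(scenario$n_replicates, cv$mu_base)
    f_peak <- replicate_factor(scenario$n_replicates, cv$mu_max)
    f_od <- replicate_factor(scenario$n_replicates, cv$od_max)

    truth <- purrr::map_dfr(seq_len(scenario$n_replicates), function(r) {
      sc_r <- scenario
      sc_r$od_max <- scenario$od_max * f_od[r]
      od <- od_curve(ticks, sc_r)
      mu <- viscosity_curve(ticks, scenario,
                            mu_peak = scenario_mu_peak(scenario) * f_peak[r],
                            mu_base = scenario$mu_base * f_base[r])
      tibble(
        replicate = r, t_h = ticks,
        true_od_au = od, true_visc_cp = mu,
        regime = profile_regime(mu, post_peak = ticks > scenario$t_inflex)
      )
    })

    events <- truth |>
      dplyr::mutate(
        passage_time_s = coefs$alpha + coefs$beta * .data$true_visc_cp +
          rnorm(dplyr::n(), 0, sens$passage_time_jitter),
        integrated_signal_au = sens$od_voltage_intercept +
          sens$od_voltage_slope * .data$true_od_au +
          rnorm(dplyr::n(), 0, sens$signal_noise_au)
      ) |>
      dplyr::select("replicate", "t_h", "passage_time_s",
                    "integrated_signal_au")

    out <- list(events = events, truth = truth)
    if (level == "trace") {
      out$traces <- truth |>
        dplyr::mutate(transit = purrr::pmap(
          list(.data$true_od_au, .data$true_visc_cp, .data$t_h),
          function(od, mu, t) {
            prof <- spatial_profile(od, mu,
                                    post_peak = t > scenario$t_inflex,
                                    seed = sample.int(2^30, 1))
            simulate_transit(
              droplet_state(mu, od_profile = prof),
              instrument, seed = sample.int(2^30, 1)
            )
          }
        )) |>
        dplyr::select("replicate", "t_h", "transit")
    }
    structure(out, class = "dv_run")
  })
}

#' Generate a synthetic viscosity-calibration set
#'
#' Event-level transits of water/glycerol-like standards of known viscosity,
#' with the instrument's timing jitter and signal noise. Standards are given
#' directly as viscosities (externally measured, e.g. by a rolling-ball
#' viscometer); no composition model is involved.
#'
#' @param standards_cp Known standard viscosities, cP, each in (0, 50]
#'   (droplet formation is unreliable above ~60 cP; such standards are
#'   refused).
#' @param n_rep Transits per standard.
#' @param instrument A [default_instrument()].
#' @param seed Integer seed (scoped to this call).
#' @param blank_od OD of the standards (0: clear liquids).
#' @return A tibble: `label`, `viscosity_cp`, `passage_time_s`,
#'   `integrated_signal_au`.
#' @export
generate_calibration_set <- function(standards_cp = c(1, 5, 10, 20, 30),
                                     n_rep = 10,
                                     instrument = default_instrument(),
                                     seed = NULL, blank_od = 0) {
  if (any(standards_cp <= 0)) abort("Standard viscosities must be positive.")
  if (any(standards_cp > 60)) {
    abort("Standards above 60 cP cannot form monodisperse droplets; refused.")
  }
  if (any(standards_cp > 50)) {
    warn("Standards above 50 cP are outside the validated range.")
  }
  coefs <- event_coefficients(instrument)
  sens <- instrument$sensor
  withr::with_seed(seed %||% sample.int(.Machine$integer.max, 1), {
    tidyr::expand_grid(viscosity_cp = standards_cp, rep = seq_len(n_rep)) |>
      dplyr::mutate(
        label = sprintf("std_%g_cP", .data$viscosity_cp),
        passage_time_s = coefs$alpha + coefs$beta * .data$viscosity_cp +
          rnorm(dplyr::n(), 0, sens$passage_time_jitter),
        integrated_signal_au = sens$od_voltage_intercept +
          sens$od_voltage_slope * blank_od +
          rnorm(dplyr::n(), 0, sens$signal_noise_au)
      ) |>
      dplyr::select("label", "viscosity_cp", "passage_time_s",
                    "integrated_signal_au")
  })
}

#' Generate a negative-control run (nutrient only)
#'
#' Constant true viscosity (`mu_base`) and OD (`od0`) with measurement noise
#' only: the null scenario behind the invariance test.
#'
#' @inheritParams generate_run
#' @param n_replicates Number of control droplets (default 1).
#' @return A `dv_run` list as in [generate_run()].
#' @export
negative_control_run <- function(scenario = growth_scenario(),
                                 instrument = default_instrument(scenario$pressure_mbar),
                                 n_replicates = 1,
                                 seed = scenario$seed) {
  sc <- scenario
  sc$n_replicates <- n_replicates
  # Freeze the trajectory at its initial state and drop replicate spread:
  # a control droplet is fresh medium throughout.
  sc$replicate_cv <- list(mu_base = 0, mu_max = 0, od_max = 0)
  ticks <- seq(0, sc$duration_h, by = sc$cadence_min / 60)
  if (length(ticks) * n_replicates > 1e6) abort("Control run too large.")
  coefs <- event_coefficients(instrument)
  sens <- instrument$sensor
  withr::with_seed(seed, {
    truth <- tidyr::expand_grid(replicate = seq_len(n_replicates),
                                t_h = ticks) |>
      dplyr::mutate(true_od_au = sc$od0, true_visc_cp = sc$mu_base,
                    regime = "uniform")
    events <- truth |>
      dplyr::mutate(
        passage_time_s = coefs$alpha + coefs$beta * .data$true_visc_cp +
          rnorm(dplyr::n(), 0, sens$passage_time_jitter),
        integrated_signal_au = sens$od_voltage_intercept +
          sens$od_voltage_slope * .data$true_od_au +
          rnorm(dplyr::n(), 0, sens$signal_noise_au)
      ) |>
      dplyr::select("replicate", "t_h", "passage_time_s",
                    "integrated_signal_au")
    structure(list(events = events, truth = truth), class = "dv_run")
  })
}
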