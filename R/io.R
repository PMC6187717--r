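#' Built-in configuration defaults
#'
#' The full layered-configuration tree with every instrument and scenario
#' default. User-facing units follow lab conventions (mm, mbar, cP, mN/m);
#' [build_instrument()] converts to SI at the boundary.
#'
#' @return A nested named list with sections `geometry`, `oil`, `sensor`,
#'   `operating_point`, `network`, `scenario`.
#' @export
default_config <- function() {
  list(
    geometry = list(
      inner_diameter_mm = 0.8,
      sensor_separation_m = 1.0,
      loop_length_m = 1.2
    ),
    oil = list(
      viscosity_cp = 0.395,
      interfacial_tension_mn_m = 19,
      label = "HFE-7200 + 5% PFO"
    ),
    sensor = list(
      baseline_voltage = 2.5,
      od_voltage_slope = -0.5 / 2.45,
      od_voltage_intercept = 2.3 + 0.05 * 0.5 / 2.45,
      spike_amplitude = 0.3,
      spike_width_s = 0.02,
      spike_polarity = 1,
      voltage_noise_rms = 5e-5,
      sampling_rate_hz = 2000,
      passage_time_jitter_s = SIGMA_DT,
      signal_noise_au = 1.8e-6
    ),
    operating_point = list(
      pressure_mbar = 100,
      temperature_c = 37
    ),
    network = list( # NULL entries back-solved from the calibration anchors
      channel_resistance = NULL,
      droplet_resistance_coefficient = NULL
    ),
    scenario = list(
      pressure_mbar = 100,
      od0 = 0.05, od_max = 2.83, k_growth = 1.0, t_inflex = 6,
      t_stationary = 12, death_slope = 0.0064,
      mu_base = 1.83,
      mu_max = list(`100` = 23.31, `200` = 10, `300` = 5.5),
      mu_inf = 5.5, decay_tau = 6, rise_exponent = 2,
      replicate_cv = list(mu_base = 0.21, mu_max = 0.08, od_max = 0.025),
      cadence_min = 10, duration_h = 48, n_replicates = 10, seed = 1
    )
  )
}

merge_config <- function(base, override, path = character()) {
  for (key in names(override)) {
    here <- c(path, key)
    if (!key %in% names(base)) {
      abort(sprintf("Unknown configuration key: %s",
                    paste(here, collapse = "$")))
    }
    if (is.list(base[[key]]) && !is.null(override[[key]]) &&
        is.list(override[[key]])) {
      base[[key]] <- merge_config(base[[key]], override[[key]], here)
    } else {
      base[[key]] <- override[[key]]
    }
  }
  base
}

validate_config <- function(config) {
  check_pos <- function(value, key) {
    if (!is.null(value) && (!is.numeric(value) || any(value <= 0))) {
      abort(sprintf("Configuration value `%s` must be positive.", key))
    }
  }
  check_pos(config$geometry$inner_diameter_mm, "geometry$inner_diameter_mm")
  check_pos(config$geometry$sensor_separation_m, "geometry$sensor_separation_m")
  check_pos(config$oil$viscosity_cp, "oil$viscosity_cp")
  check_pos(config$oil$interfacial_tension_mn_m, "oil$interfacial_tension_mn_m")
  check_pos(config$operating_point$pressure_mbar, "operating_point$pressure_mbar")
  check_pos(config$sensor$sampling_rate_hz, "sensor$sampling_rate_hz")
  check_pos(config$scenario$cadence_min, "scenario$cadence_min")
  check_pos(config$scenario$duration_h, "scenario$duration_h")
  if (config$geometry$sensor_separation_m > config$geometry$loop_length_m) {
    abort("`geometry$sensor_separation_m` cannot exceed `geometry$loop_length_m`.")
  }
  invisible(config)
}

#' Load and validate a layered configuration
#'
#' Built-in defaults, overridden by an optional YAML/JSON file, overridden by
#' an optional list of in-code overrides. Unknown keys and non-positive
#' physical values raise descriptive errors.
#'
#' @param path Optional path to a YAML (or JSON) configuration file.
#' @param overrides Optional nested list applied on top of the file.
#' @return The merged, validated configuration list.
#' @examples
#' cfg <- load_config(overrides = list(operating_point = list(pressure_mbar = 300)))
#' cfg$operating_point$pressure_mbar
#' @export
load_config <- function(path = NULL, overrides = list()) {
  config <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) abort(sprintf("Configuration file not found: %s", path))
    from_file <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
      jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
    } else {
      yaml::read_yaml(path)
    }
    if (length(from_file)) config <- merge_config(config, from_file)
  }
  if (length(overrides)) config <- merge_config(config, overrides)
  validate_config(config)
  config
}

#' Build instrument and scenario objects from a configuration
#'
#' Converts the lab-unit configuration into SI-backed [default_instrument()]
#' and [growth_scenario()] objects. Missing network entries are back-solved
#' from the calibration anchors.
#'
#' @param config A [load_config()] result.
#' @return A list with elements `instrument` and `scenario`.
#' @export
build_instrument <- function(config = load_config()) {
  geometry <- channel_geometry(
    inner_diameter = config$geometry$inner_diameter_mm * 1e-3,
    sensor_separation = config$geometry$sensor_separation_m,
    loop_length = config$geometry$loop_length_m
  )
  oil <- continuous_phase(
    viscosity_cp = config$oil$viscosity_cp,
    interfacial_tension = config$oil$interfacial_tension_mn_m * 1e-3,
    label = config$oil$label
  )
  sensor <- sensor_model(
    baseline_voltage = config$sensor$baseline_voltage,
    od_voltage_slope = config$sensor$od_voltage_slope,
    od_voltage_intercept = config$sensor$od_voltage_intercept,
    spike_amplitude = config$sensor$spike_amplitude,
    spike_width = config$sensor$spike_width_s,
    spike_polarity = config$sensor$spike_polarity,
    voltage_noise_rms = config$sensor$voltage_noise_rms,
    sampling_rate = config$sensor$sampling_rate_hz,
    passage_time_jitter = config$sensor$passage_time_jitter_s,
    signal_noise_au = config$sensor$signal_noise_au
  )
  network <- if (is.null(config$network$channel_resistance) ||
                 is.null(config$network$droplet_resistance_coefficient)) {
    default_network(geometry)
  } else {
    hydraulic_network(config$network$channel_resistance,
                      config$network$droplet_resistance_coefficient)
  }
  sc <- config$scenario
  scenario <- growth_scenario(
    pressure_mbar = sc$pressure_mbar,
    od0 = sc$od0, od_max = sc$od_max, k_growth = sc$k_growth,
    t_inflex = sc$t_inflex, t_stationary = sc$t_stationary,
    death_slope = sc$death_slope,
    mu_base = sc$mu_base, mu_max = unlist(sc$mu_max), mu_inf = sc$mu_inf,
    decay_tau = sc$decay_tau, rise_exponent = sc$rise_exponent,
    replicate_cv = sc$replicate_cv,
    cadence_min = sc$cadence_min, duration_h = sc$duration_h,
    n_replicates = sc$n_replicates, seed = sc$seed
  )
  list(
    instrument = default_instrument(
      pressure_mbar = config$operating_point$pressure_mbar,
      geometry = geometry, oil = oil, sensor = sensor, network = network
    ),
    scenario = scenario
  )
}

#' Read and write event records
#'
#' Event CSVs carry one transit per row:
#' `replicate,t_h,passage_time_s,integrated_signal_au`.
#'
#' @param events An events tibble.
#' @param path File path.
#' @return `write_events()` returns `path` invisibly; `read_events()` a
#'   tibble.
#' @export
write_events <- function(events, path) {
  readr::write_csv(events, path)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    replicate = readr::col_integer(),
    t_h = readr::col_double(),
    passage_time_s = readr::col_double(),
    integrated_signal_au = readr::col_double()
  ))
}

#' Read and write ground-truth tables
#'
#' Truth CSVs: `replicate,t_h,true_od_au,true_visc_cp,regime`.
#'
#' @param truth A truth tibble.
#' @param path File path.
#' @export
write_truth <- function(truth, path) {
  readr::write_csv(truth, path)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    replicate = readr::col_integer(),
    t_h = readr::col_double(),
    true_od_au = readr::col_double(),
    true_visc_cp = readr::col_double(),
    regime = readr::col_character()
  ))
}

#' Read and write calibration files
#'
#' Calibrations are stored as JSON with slope/intercept/range/diagnostics
#' and provenance (package version, timestamp).
#'
#' @param cal A `dv_calibration`.
#' @param path File path.
#' @export
write_calibration <- function(cal, path) {
  payload <- list(
    predictor = cal$predictor, response = cal$response,
    slope = cal$slope, intercept = cal$intercept,
    r_squared = cal$r_squared, residual_sd = cal$residual_sd,
    n = cal$n, valid_range = cal$valid_range,
    provenance = list(
      package = "dropvisc",
      version = as.character(utils::packageVersion("dropvisc")),
      written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    )
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  anchored_calibration(
    predictor = p$predictor, response = p$response,
    slope = p$slope, intercept = p$intercept,
    valid_range = p$valid_range
  ) |>
    (\(cal) {
      cal$r_squared <- p$r_squared
      cal$residual_sd <- p$residual_sd
      cal$n <- p$n
      cal
    })()
}

#' Run manifest
#'
#' Records everything needed to reproduce a run: configuration snapshot,
#' seed, package version, input/output file hashes and a timestamp. Every
#' stochastic output of a pipeline run is traceable to the seed recorded
#' here.
#'
#' @param config The configuration used.
#' @param seed The integer seed used.
#' @param files Character vector of files to hash (missing ones are skipped).
#' @param path Optional path; when given the manifest is written as JSON.
#' @return The manifest list (invisibly when written).
#' @export
run_manifest <- function(config, seed, files = character(), path = NULL) {
  existing <- files[file.exists(files)]
  manifest <- list(
    package = "dropvisc",
    version = as.character(utils::packageVersion("dropvisc")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = config,
    file_md5 = as.list(tools::md5sum(existing))
  )
  if (!is.null(path)) {
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
    return(invisible(manifest))
  }
  manifest
}
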