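#' Channel geometry of the measuring tubing
#'
#' Describes the FEP tubing that carries the droplet: inner diameter, the
#' distance between the two optical sensors, and the total loop length between
#' the circulation valves. Derived quantities (radius, circular cross-section
#' `S = pi * d^2 / 4`) are stored alongside.
#'
#' @param inner_diameter Inner diameter of the tubing, m. Default 0.8 mm.
#' @param sensor_separation Distance between the two optical sensors, m.
#'   Default 1.0 m (a configuration parameter: it is implied by the droplet
#'   speed and the capillary number at the reference operating point, not a
#'   hard instrument constant).
#' @param loop_length Length of tubing between the circulation valves, m.
#'   Default 1.2 m.
#' @return An object of class `dv_geometry`: a list with the arguments plus
#'   `radius` and `cross_section` (m^2).
#' @examples
#' geo <- channel_geometry()
#' geo$cross_section # 5.027e-7 m^2
#' @export
channel_geometry <- function(inner_diameter = 0.8e-3,
                             sensor_separation = 1.0,
                             loop_length = 1.2) {
  if (!is.numeric(inner_diameter) || inner_diameter <= 0) {
    abort("`inner_diameter` must be a positive length in metres.")
  }
  if (sensor_separation <= 0 || sensor_separation > loop_length) {
    abort("`sensor_separation` must satisfy 0 < sensor_separation <= loop_length.")
  }
  structure(
    list(
      inner_diameter = inner_diameter,
      radius = inner_diameter / 2,
      cross_section = pi * inner_diameter^2 / 4,
      sensor_separation = sensor_separation,
      loop_length = loop_length
    ),
    class = "dv_geometry"
  )
}

#' Continuous (carrier) phase
#'
#' The fluorinated oil that carries the aqueous plugs. Defaults are the 37 degC
#' values for HFE-7200 with 5% w/w perfluorooctanol: viscosity 0.395 cP and
#' oil/broth interfacial tension 19 mN/m.
#'
#' @param viscosity_cp Dynamic viscosity of the oil, cP (1 cP = 1 mPa s).
#' @param interfacial_tension Oil/sample interfacial tension, N/m.
#' @param label Free-text label for the fluid.
#' @return An object of class `dv_oil` with viscosity in both cP and Pa s.
#' @export
continuous_phase <- function(viscosity_cp = 0.395,
                             interfacial_tension = 19e-3,
                             label = "HFE-7200 + 5% PFO") {
  if (viscosity_cp <= 0) abort("Oil viscosity must be positive.")
  if (interfacial_tension <= 0) abort("Interfacial tension must be positive.")
  structure(
    list(
      viscosity_cp = viscosity_cp,
      viscosity_pa_s = viscosity_cp * 1e-3,
      interfacial_tension = interfacial_tension,
      label = label
    ),
    class = "dv_oil"
  )
}

#' Operating point of the instrument
#'
#' @param pressure_mbar Pressure difference driving the continuous phase,
#'   mbar. One of 100 / 200 / 300 in the reference experiments, but any
#'   positive value is accepted.
#' @param temperature_c Bath temperature, degC (informational; all fluid
#'   constants are the 37 degC values).
#' @return An object of class `dv_operating_point` with the pressure also in Pa.
#' @export
operating_point <- function(pressure_mbar = 100, temperature_c = 37) {
  if (pressure_mbar <= 0) abort("`pressure_mbar` must be positive.")
  structure(
    list(
      pressure_mbar = pressure_mbar,
      pressure_pa = pressure_mbar * 100,
      temperature_c = temperature_c
    ),
    class = "dv_operating_point"
  )
}

# Calibration-line anchors at the 100 mbar reference point: passage time is
# affine in droplet viscosity, dt = ALPHA_100 + BETA_100 * mu_cP, through the
# endpoint pairs (1 cP, 103 s) and (30 cP, 116 s).
ALPHA_100 <- 103 - 13 / 29 # s
BETA_100 <- 13 / 29        # s per cP

# Single-transit timing jitter back-solved so that the two-sigma resolution
# criterion gives 0.05 cP at the 100 mbar slope: 0.05 = 2 * sigma * (1/BETA).
SIGMA_DT <- 0.05 * 13 / 58 # s

#' Photodetector and timing sensor model
#'
#' Parameters of the optical sensors and of the event-level measurement noise.
#' The interior voltage of a droplet maps linearly from local optical density:
#' `V = od_voltage_intercept + od_voltage_slope * OD`, anchored so that
#' OD 0.05 reads 2.3 a.u. and OD 2.5 reads 1.8 a.u. Menisci appear as sharp
#' Gaussian voltage spikes of configurable amplitude, width and polarity.
#'
#' @param baseline_voltage Sensor voltage over pure oil, a.u.
#' @param od_voltage_slope,od_voltage_intercept Linear OD-to-voltage map
#'   (a.u. per OD and a.u.).
#' @param spike_amplitude Meniscus spike height, a.u.
#' @param spike_width Meniscus spike Gaussian sigma, s.
#' @param spike_polarity `+1` (default) for upward spikes, `-1` for downward.
#' @param voltage_noise_rms Additive white voltage noise RMS, a.u. (50 uV).
#' @param sampling_rate Trace sampling rate, Hz.
#' @param passage_time_jitter Single-transit timing jitter SD, s. The default
#'   is back-solved from the 0.05 cP two-sigma resolution at 100 mbar.
#' @param signal_noise_au Event-level noise SD on the time-averaged interior
#'   voltage, a.u.; default is the voltage noise divided by the square root of
#'   a typical interior sample count (~800 at 2 kHz).
#' @return An object of class `dv_sensor`.
#' @export
sensor_model <- function(baseline_voltage = 2.5,
                         od_voltage_slope = -0.5 / 2.45,
                         od_voltage_intercept = 2.3 + 0.05 * 0.5 / 2.45,
                         spike_amplitude = 0.3,
                         spike_width = 0.02,
                         spike_polarity = 1,
                         voltage_noise_rms = 5e-5,
                         sampling_rate = 2000,
                         passage_time_jitter = SIGMA_DT,
                         signal_noise_au = 1.8e-6) {
  if (sampling_rate <= 0) abort("`sampling_rate` must be positive.")
  if (voltage_noise_rms < 0) abort("`voltage_noise_rms` must be non-negative.")
  if (passage_time_jitter < 0) abort("`passage_time_jitter` must be non-negative.")
  if (!spike_polarity %in% c(-1, 1)) abort("`spike_polarity` must be +1 or -1.")
  structure(
    list(
      baseline_voltage = baseline_voltage,
      od_voltage_slope = od_voltage_slope,
      od_voltage_intercept = od_voltage_intercept,
      spike_amplitude = spike_amplitude,
      spike_width = spike_width,
      spike_polarity = spike_polarity,
      voltage_noise_rms = voltage_noise_rms,
      sampling_rate = sampling_rate,
      passage_time_jitter = passage_time_jitter,
      signal_noise_au = signal_noise_au
    ),
    class = "dv_sensor"
  )
}

#' Lumped hydraulic network of the viscometer
#'
#' The series-resistance picture: the oil-filled channel contributes a fixed
#' resistance `Rc`, the plug contributes `Rd = k_d * mu_d` with `mu_d` the
#' droplet viscosity in Pa s. `k_d` is a lumped, calibrated coefficient
#' (a bare Hagen-Poiseuille estimate of the plug contradicts the measured
#' slope, so calibration anchors the model).
#'
#' @param channel_resistance `Rc`, Pa s m^-3.
#' @param droplet_resistance_coefficient `k_d`, m^-3 (so that
#'   `k_d * mu[Pa s]` has resistance units).
#' @return An object of class `dv_network`.
#' @export
hydraulic_network <- function(channel_resistance,
                              droplet_resistance_coefficient) {
  if (channel_resistance <= 0 || droplet_resistance_coefficient <= 0) {
    abort("Resistances must be positive.")
  }
  structure(
    list(
      channel_resistance = channel_resistance,
      droplet_resistance_coefficient = droplet_resistance_coefficient
    ),
    class = "dv_network"
  )
}

#' Default calibrated hydraulic network
#'
#' Back-solves `Rc` and `k_d` from the affine passage-time law
#' `dt = alpha + beta * mu_cP` at 100 mbar, with `alpha = 102.5517 s` and
#' `beta = 0.448276 s/cP` (the two-point line through (1 cP, 103 s) and
#' (30 cP, 116 s)): `Rc = alpha * dp / (l * S)` and
#' `k_d = beta * dp / (l * S)` per cP, converted to SI.
#'
#' @param geometry A [channel_geometry()].
#' @return A [hydraulic_network()].
#' @export
default_network <- function(geometry = channel_geometry()) {
  lS <- geometry$sensor_separation * geometry$cross_section
  dp_ref <- 1e4 # Pa, the 100 mbar anchor
  hydraulic_network(
    channel_resistance = ALPHA_100 * dp_ref / lS,
    droplet_resistance_coefficient = BETA_100 * dp_ref / lS / 1e-3
  )
}

#' A droplet (plug) state
#'
#' @param viscosity_cp Droplet viscosity, cP. Values above 50 cP are outside
#'   the validated monodispersity range and trigger a warning.
#' @param volume Plug volume, m^3. Default 2.4 uL.
#' @param od Uniform optical density of the plug, a.u. Ignored when
#'   `od_profile` is given.
#' @param od_profile Optional axial OD profile: a function of the normalized
#'   position `s` in `[0, 1]` (0 = droplet front), or a data frame with
#'   columns `s` and `od` (interpolated linearly, constant beyond the ends).
#' @return An object of class `dv_droplet`.
#' @export
droplet_state <- function(viscosity_cp, volume = 2.4e-9, od = 0,
                          od_profile = NULL) {
  if (!is.numeric(viscosity_cp) || viscosity_cp <= 0) {
    abort("`viscosity_cp` must be positive.")
  }
  if (viscosity_cp > 50) {
    warn("Viscosity above 50 cP is outside the validated monodispersity range.")
  }
  if (volume <= 0) abort("`volume` must be positive.")
  if (is.null(od_profile)) {
    if (od < 0) abort("`od` must be non-negative.")
    od_val <- od
    od_profile <- local({
      level <- od_val
      function(s) rep(level, length(s))
    })
  } else if (is.data.frame(od_profile)) {
    if (any(od_profile$od < 0)) abort("OD profile must be non-negative.")
    od_val <- mean(od_profile$od)
    od_profile <- approxfun(od_profile$s, od_profile$od, rule = 2)
  } else if (is.function(od_profile)) {
    od_val <- mean(od_profile(seq(0, 1, length.out = 201)))
    if (od_val < 0) abort("OD profile must be non-negative on [0, 1].")
  } else {
    abort("`od_profile` must be a function or a data frame with columns s, od.")
  }
  structure(
    list(
      viscosity_cp = viscosity_cp,
      viscosity_pa_s = viscosity_cp * 1e-3,
      volume = volume,
      od = od_val,
      od_profile = od_profile
    ),
    class = "dv_droplet"
  )
}

#' Assemble the default instrument
#'
#' Bundles the default geometry, oil, sensor model and the calibrated
#' hydraulic network at the requested operating pressure. With these
#' constants the forward model reproduces the reference calibration:
#' 103 s at 1 cP and 116 s at 30 cP under 100 mbar.
#'
#' @param pressure_mbar Operating pressure, mbar.
#' @param geometry,oil,sensor,network Optional component overrides.
#' @return An object of class `dv_instrument`: a list with elements
#'   `geometry`, `oil`, `sensor`, `network`, `operating_point`.
#' @examples
#' inst <- default_instrument()
#' passage_time(1, inst)$passage_time_s # 103 s
#' @export
default_instrument <- function(pressure_mbar = 100,
                               geometry = channel_geometry(),
                               oil = continuous_phase(),
                               sensor = sensor_model(),
                               network = default_network(geometry)) {
  structure(
    list(
      geometry = geometry,
      oil = oil,
      sensor = sensor,
      network = network,
      operating_point = operating_point(pressure_mbar)
    ),
    class = "dv_instrument"
  )
}

#' @export
print.dv_instrument <- function(x, ...) {
  cat("<dv_instrument>\n")
  cat(sprintf("  tubing      : %.2f mm ID, sensors %.2f m apart (loop %.2f m)\n",
              x$geometry$inner_diameter * 1e3, x$geometry$sensor_separation,
              x$geometry$loop_length))
  cat(sprintf("  oil         : %s, %.3f cP, gamma %.1f mN/m\n",
              x$oil$label, x$oil$viscosity_cp, x$oil$interfacial_tension * 1e3))
  cat(sprintf("  pressure    : %g mbar\n", x$operating_point$pressure_mbar))
  cat(sprintf("  network     : Rc %.4g Pa s m^-3, k_d %.4g m^-3\n",
              x$network$channel_resistance,
              x$network$droplet_resistance_coefficient))
  invisible(x)
}

#' Cylindrical plug length
#'
#' Length of a plug of volume `V` treated as a cylinder filling the tube
#' cross-section, `L = V / S`. End caps are ignored: at the reference volume
#' the plug is ~6 diameters long, so the cap correction is small.
#'
#' @param volume Plug volume, m^3.
#' @param geometry A [channel_geometry()].
#' @return Length, m.
#' @examples
#' plug_length(2.4e-9, channel_geometry()) # 4.77 mm ~ 6 inner diameters
#' @export
plug_length <- function(volume, geometry = channel_geometry()) {
  if (any(volume <= 0)) abort("`volume` must be positive.")
  volume / geometry$cross_section
}

#' Hagen-Poiseuille resistance of a tube segment
#'
#' `R = 8 mu L / (pi r^4)` for laminar flow of a fluid of viscosity `mu`
#' through a circular tube of length `L` and radius `r`.
#'
#' @param viscosity_pa_s Dynamic viscosity, Pa s.
#' @param length Segment length, m.
#' @param radius Tube radius, m.
#' @return Resistance, Pa s m^-3.
#' @export
tube_resistance <- function(viscosity_pa_s, length, radius) {
  if (any(viscosity_pa_s <= 0) || any(length <= 0) || any(radius <= 0)) {
    abort("`viscosity_pa_s`, `length` and `radius` must all be positive.")
  }
  8 * viscosity_pa_s * length / (pi * radius^4)
}

#' Capillary number
#'
#' `Ca = mu_o v / gamma`: the ratio of viscous to interfacial forces at the
#' droplet interface. At the reference operating point Ca ~ 2e-4, deep in the
#' interfacial-tension-dominated (plug) regime.
#'
#' @param speed Droplet speed, m/s.
#' @param oil A [continuous_phase()].
#' @return Dimensionless capillary number.
#' @export
capillary_number <- function(speed, oil = continuous_phase()) {
  if (oil$interfacial_tension <= 0) abort("Interfacial tension must be positive.")
  oil$viscosity_pa_s * speed / oil$interfacial_tension
}

#' Interface shear rate estimate
#'
#' The shear rate vanishes on the droplet centreline and is maximal at the
#' interface. A calibrated-coefficient estimate `c_s * v / r` is used in
#' place of the exact film-flow solution; the default `c_s = 0.453`
#' reproduces ~11 s^-1 for a fresh LB plug at 100 mbar.
#'
#' @param speed Droplet speed, m/s.
#' @param geometry A [channel_geometry()].
#' @param coefficient Dimensionless shear coefficient `c_s`.
#' @return Shear rate, s^-1.
#' @export
interface_shear_rate <- function(speed, geometry = channel_geometry(),
                                 coefficient = 0.453) {
  if (coefficient <= 0) abort("`coefficient` must be positive.")
  coefficient * speed / geometry$radius
}

#' Forward transit model: passage time and flow diagnostics
#'
#' Closed-form series-resistance kinematics for a plug of viscosity `mu`:
#' `dt = l S (Rc + k_d mu) / dp`, `v = l / dt`, `Q = v S`, with the capillary
#' number and interface shear rate as diagnostics. Passage time is affine in
#' droplet viscosity and inversely proportional to the driving pressure.
#'
#' @param viscosity_cp Droplet viscosity, cP (vectorised).
#' @param instrument A [default_instrument()].
#' @param shear_coefficient Passed to [interface_shear_rate()].
#' @return A tibble with one row per viscosity: `viscosity_cp`,
#'   `passage_time_s`, `speed_m_s`, `flow_rate_m3_s`, `capillary_number`,
#'   `shear_rate_s`.
#' @examples
#' passage_time(c(1, 30), default_instrument())
#' @export
passage_time <- function(viscosity_cp, instrument = default_instrument(),
                         shear_coefficient = 0.453) {
  if (any(!is.finite(viscosity_cp)) || any(viscosity_cp <= 0)) {
    abort("`viscosity_cp` must be positive and finite.")
  }
  if (any(viscosity_cp > 50)) {
    warn("Viscosity above 50 cP is outside the validated model range; results are extrapolated.")
  }
  geo <- instrument$geometry
  net <- instrument$network
  dp <- instrument$operating_point$pressure_pa
  r_total <- net$channel_resistance +
    net$droplet_resistance_coefficient * viscosity_cp * 1e-3
  dt <- geo$sensor_separation * geo$cross_section * r_total / dp
  v <- geo$sensor_separation / dt
  tibble(
    viscosity_cp = viscosity_cp,
    passage_time_s = dt,
    speed_m_s = v,
    flow_rate_m3_s = v * geo$cross_section,
    capillary_number = capillary_number(v, instrument$oil),
    shear_rate_s = interface_shear_rate(v, geo, shear_coefficient)
  )
}

#' Time-stepping transit oracle
#'
#' Integrates the droplet position `dx/dt = dp / (S (Rc + k_d mu))` with a
#' fixed-step explicit scheme and reads the sensor-to-sensor passage time off
#' the interpolated crossing times. This is an independent numerical route to
#' the closed form in [passage_time()] and agrees with it to better than 1e-9
#' relative.
#'
#' @param viscosity_cp Droplet viscosity, cP.
#' @param instrument A [default_instrument()].
#' @param dt_step Integration step, s.
#' @return Passage time, s.
#' @export
passage_time_numeric <- function(viscosity_cp,
                                 instrument = default_instrument(),
                                 dt_step = 0.01) {
  if (viscosity_cp <= 0) abort("`viscosity_cp` must be positive.")
  geo <- instrument$geometry
  net <- instrument$network
  dp <- instrument$operating_point$pressure_pa
  cross_time <- function(target) {
    x <- 0
    t_now <- 0
    repeat {
      r_total <- net$channel_resistance +
        net$droplet_resistance_coefficient * viscosity_cp * 1e-3
      v <- dp / (geo$cross_section * r_total)
      x_next <- x + v * dt_step
      if (x_next >= target) {
        return(t_now + (target - x) / v)
      }
      x <- x_next
      t_now <- t_now + dt_step
    }
  }
  # Sensor A sits at the start of the measured section; B one separation on.
  cross_time(geo$sensor_separation)
}

#' Synthesise the two sensor voltage traces of one transit
#'
#' Produces windowed traces (default +/- 1 s around each sensor event) of the
#' droplet passing sensor A and, a passage time later, sensor B. Each trace is
#' baseline voltage over oil, Gaussian meniscus spikes at the front and back
#' caps, interior voltage mapped from the axial OD profile under the
#' constant-speed assumption, and additive white noise. Sensor B's event is
#' delayed by the true passage time plus one jitter draw.
#'
#' @param droplet A [droplet_state()].
#' @param instrument A [default_instrument()].
#' @param window_s Padding around each droplet event, s.
#' @param seed Optional integer seed; the RNG state is scoped to this call.
#' @return A list of class `dv_transit` with tibbles `trace_a`, `trace_b`
#'   (`time_s`, `voltage_au`, `sensor_id`) and a `truth` list
#'   (`passage_time_s`, `observed_delay_s`, `speed_m_s`, `droplet_od`).
#' @export
simulate_transit <- function(droplet, instrument = default_instrument(),
                             window_s = 1, seed = NULL) {
  sens <- instrument$sensor
  kin <- passage_time(droplet$viscosity_cp, instrument)
  v <- kin$speed_m_s
  dt_true <- kin$passage_time_s
  l_plug <- plug_length(droplet$volume, instrument$geometry)
  tau <- l_plug / v # time the plug spends over one sensor
  n_interior <- floor(0.8 * tau * sens$sampling_rate)
  if (n_interior < 20) {
    abort("Sampling too coarse: fewer than 20 interior samples would resolve the droplet.")
  }

  synth <- function(t_front, time_s, noise) {
    t_back <- t_front + tau
    volt <- rep(sens$baseline_voltage, length(time_s))
    inside <- time_s > t_front & time_s < t_back
    s <- (time_s[inside] - t_front) / tau
    volt[inside] <- sens$od_voltage_intercept +
      sens$od_voltage_slope * droplet$od_profile(s)
    spike <- function(centre) {
      sens$spike_polarity * sens$spike_amplitude *
        exp(-(time_s - centre)^2 / (2 * sens$spike_width^2))
    }
    volt <- volt + spike(t_front) + spike(t_back)
    volt + noise
  }

  build <- withr::with_seed(
    seed %||% sample.int(.Machine$integer.max, 1),
    {
      jitter <- rnorm(1, 0, sens$passage_time_jitter)
      tf_a <- window_s
      tf_b <- tf_a + dt_true + jitter
      mk_trace <- function(tf, id) {
        time_s <- seq(tf - window_s, tf + tau + window_s,
                      by = 1 / sens$sampling_rate)
        noise <- if (sens$voltage_noise_rms > 0) {
          rnorm(length(time_s), 0, sens$voltage_noise_rms)
        } else {
          0
        }
        tibble(time_s = time_s, voltage_au = synth(tf, time_s, noise),
               sensor_id = id)
      }
      list(a = mk_trace(tf_a, "A"), b = mk_trace(tf_b, "B"), jitter = jitter)
    }
  )

  structure(
    list(
      trace_a = build$a,
      trace_b = build$b,
      truth = list(
        passage_time_s = dt_true,
        observed_delay_s = dt_true + build$jitter,
        speed_m_s = v,
        droplet_od = droplet$od
      )
    ),
    class = "dv_transit"
  )
}
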