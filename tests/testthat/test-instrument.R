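test_that("plug length follows the cylindrical approximation", {
  geo <- channel_geometry()
  # 2.4 uL in 0.8 mm ID tubing: ~6 inner diameters long
  l <- plug_length(2.4e-9, geo)
  expect_equal(l, 4.7746e-3, tolerance = 1e-4)
  expect_equal(round(l / geo$inner_diameter), 6)
  # one diameter's worth of volume gives length exactly one diameter
  expect_equal(plug_length(geo$cross_section * geo$inner_diameter, geo),
               geo$inner_diameter)
  # halving the volume halves the length
  expect_equal(plug_length(1.2e-9, geo), plug_length(2.4e-9, geo) / 2)
  expect_equal(plug_length(1.2e-9, geo), 2.3873e-3, tolerance = 1e-4)
  expect_error(plug_length(-1, geo), "positive")
})

test_that("Hagen-Poiseuille tube resistance and its scalings", {
  expect_equal(tube_resistance(0.395e-3, 1.2, 0.4e-3), 4.715e10,
               tolerance = 1e-3)
  r0 <- tube_resistance(1e-3, 1, 1e-3)
  expect_equal(tube_resistance(1e-3, 1, 2e-3), r0 / 16)
  expect_equal(tube_resistance(1e-2, 1, 1e-3), r0 * 10)
  expect_error(tube_resistance(0, 1, 1), "positive")
})

test_that("default instrument reproduces the reference calibration endpoints", {
  inst <- default_instrument()
  expect_equal(inst$network$channel_resistance, 2.040e12, tolerance = 1e-3)
  res <- passage_time(c(1, 30), inst)
  expect_equal(res$passage_time_s, c(103, 116))
  # doubling the pressure halves the passage time
  inst2 <- default_instrument(200)
  expect_equal(passage_time(1, inst2)$passage_time_s, 51.5)
  expect_error(passage_time(-1, inst), "positive")
  expect_warning(passage_time(55, inst), "50 cP")
})

test_that("passage time is affine in viscosity and monotone", {
  inst <- default_instrument()
  mu <- c(1, 5, 12, 25, 40)
  res <- passage_time(mu, inst)
  fit <- fit_line(res, "viscosity_cp", "passage_time_s")
  expect_lt(1 - fit$r_squared, 1e-12)
  expect_true(all(diff(res$passage_time_s) > 0))
  expect_true(all(diff(res$speed_m_s) < 0))
})

test_that("passage time scales inversely with pressure", {
  for (mu in c(1.83, 10, 30)) {
    dts <- vapply(c(100, 200, 300), function(p) {
      passage_time(mu, default_instrument(p))$passage_time_s
    }, numeric(1))
    expect_equal(dts * c(100, 200, 300), rep(dts[1] * 100, 3))
  }
})

test_that("time-stepping oracle matches the closed form and the hand law", {
  inst <- default_instrument()
  for (mu in c(1, 17, 30)) {
    dt_closed <- passage_time(mu, inst)$passage_time_s
    dt_num <- passage_time_numeric(mu, inst, dt_step = 0.05)
    expect_lt(abs(dt_num - dt_closed) / dt_closed, 1e-9)
    expect_equal(dt_closed, oracle_dt(mu))
  }
})

test_that("flow diagnostics: capillary number and interface shear rate", {
  v <- 1 / passage_time(1, default_instrument())$passage_time_s # 9.71 mm/s
  expect_equal(capillary_number(v), 2.02e-4, tolerance = 1e-2)
  expect_equal(capillary_number(0), 0)
  expect_equal(capillary_number(2 * v), 2 * capillary_number(v))
  expect_equal(interface_shear_rate(v), 11.0, tolerance = 1e-2)
  expect_equal(interface_shear_rate(0), 0)
  # at 24 cP the same coefficient lands near (within ~10% of) 9 s^-1
  v24 <- passage_time(24, default_instrument())$speed_m_s
  expect_equal(interface_shear_rate(v24), 10.0, tolerance = 0.02)
})

test_that("synthesised traces carry the modelled interior voltage", {
  inst <- noise_free_instrument()
  tr <- simulate_transit(droplet_state(1, od = 0.05), inst, seed = 1)
  ev <- detect_event(tr$trace_a)
  expect_equal(ev$integrated_signal_au, 2.3, tolerance = 1e-3)
  # noise-free: spike-to-spike separation equals the closed-form passage
  # time to within one sample period
  ev_b <- detect_event(tr$trace_b)
  expect_equal(passage_time_between(ev, ev_b), tr$truth$passage_time_s,
               tolerance = (1 / inst$sensor$sampling_rate) / 100)
})

test_that("trace synthesis rejects undersampled droplets", {
  inst <- default_instrument(sensor = sensor_model(sampling_rate = 30))
  expect_error(simulate_transit(droplet_state(1, od = 0.05), inst, seed = 1),
               "interior samples")
})

test_that("uniform noise-free droplet integrates to the exact OD map value", {
  inst <- noise_free_instrument()
  tr <- simulate_transit(droplet_state(5, od = 1.0), inst, seed = 2)
  ev <- detect_event(tr$trace_a)
  sens <- inst$sensor
  expect_equal(ev$integrated_signal_au,
               sens$od_voltage_intercept + sens$od_voltage_slope * 1.0,
               tolerance = 1e-3)
})

test_that("component constructors validate their invariants", {
  expect_error(channel_geometry(inner_diameter = -1), "positive")
  expect_error(channel_geometry(sensor_separation = 2, loop_length = 1.2),
               "loop_length")
  expect_error(continuous_phase(viscosity_cp = 0), "positive")
  expect_error(operating_point(0), "positive")
  expect_error(hydraulic_network(-1, 1), "positive")
  expect_error(droplet_state(0), "positive")
  geo <- channel_geometry()
  expect_equal(geo$cross_section, pi * geo$inner_diameter^2 / 4)
})
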