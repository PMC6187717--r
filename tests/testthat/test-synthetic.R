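test_that("OD trajectory hits the lag, midpoint and endpoint anchors", {
  sc <- growth_scenario()
  expect_lte(od_curve(0, sc), 0.06)
  expect_gte(od_curve(0, sc), 0.05)
  expect_equal(od_curve(sc$t_inflex, sc), (0.05 + 2.83) / 2)
  expect_equal(od_curve(48, sc), 2.83 - 0.0064 * 36, tolerance = 1e-3)
  # non-decreasing through stationary onset, non-increasing well after
  t_up <- seq(0, 12, by = 0.25)
  expect_true(all(diff(od_curve(t_up, sc)) >= 0))
  t_dn <- seq(14, 48, by = 0.25)
  expect_true(all(diff(od_curve(t_dn, sc)) <= 0))
})

test_that("viscosity trajectory: flat lag, exact peak at the OD inflexion, 48-h asymptote", {
  sc <- growth_scenario()
  expect_equal(viscosity_curve(0, sc), 1.83, tolerance = 1e-3)
  expect_equal(viscosity_curve(sc$t_inflex, sc), 23.31)
  expect_equal(viscosity_curve(48, sc), 5.5, tolerance = 5e-3)
  # lag-phase changes are negligible: within the replicate scatter of the baseline
  expect_lt(max(viscosity_curve(seq(0, 3, by = 0.25), sc)) - 1.83, 0.38)
  # unique maximum at t_inflex; continuous across the peak
  t <- seq(0, 48, by = 1 / 60)
  mu <- viscosity_curve(t, sc)
  expect_equal(t[which.max(mu)], 6, tolerance = 0.02)
  eps <- 1e-6
  expect_equal(viscosity_curve(6 - eps, sc), viscosity_curve(6 + eps, sc),
               tolerance = 1e-4)
})

test_that("peak viscosity decreases with pressure (shear) and errors on unknown pressure", {
  peaks <- vapply(c(100, 200, 300), function(p) {
    sc <- growth_scenario(pressure_mbar = p)
    viscosity_curve(sc$t_inflex, sc)
  }, numeric(1))
  expect_equal(peaks, c(23.31, 10, 5.5))
  expect_true(all(diff(peaks) < 0))
  expect_error(growth_scenario(pressure_mbar = 150), "150 mbar")
})

test_that("spatial profiles follow the aggregation regimes and normalize exactly", {
  # low viscosity: uniform
  p1 <- spatial_profile(0.1, 1.5, seed = 1)
  expect_equal(attr(p1, "regime"), "uniform")
  expect_equal(sd(p1$od), 0)
  # high viscosity pre-peak: single rear conglomerate, OD max in trailing quarter
  p3 <- spatial_profile(2.0, 23, post_peak = FALSE, seed = 1)
  expect_equal(attr(p3, "regime"), "rear_conglomerate")
  expect_gt(p3$s[which.max(p3$od)], 0.75)
  # intermediate pre-peak: patchy; post-peak: uniform again
  expect_equal(attr(spatial_profile(1, 10, FALSE, seed = 2), "regime"),
               "patchy")
  expect_equal(attr(spatial_profile(1, 23, TRUE, seed = 2), "regime"),
               "uniform")
  # normalization: spatial mean equals the true OD to machine precision
  for (args in list(list(0.7, 1.5), list(1.3, 10), list(2.4, 23))) {
    p <- spatial_profile(args[[1]], args[[2]], seed = 3)
    expect_equal(mean(p$od), args[[1]], tolerance = 1e-12)
  }
})

test_that("CFU conversion is linear through the origin", {
  expect_equal(cfu_from_od(0), 0)
  expect_equal(cfu_from_od(1.0), 2 * cfu_from_od(0.5))
  expect_equal(cfu_from_od(0.5, factor = 8e8), 4e8)
  expect_error(cfu_from_od(-1), "non-negative")
})

test_that("a default run has the expected shape and is seed-reproducible", {
  sc <- growth_scenario(seed = 11)
  run <- generate_run(sc)
  expect_equal(nrow(run$events), 10 * 289)
  expect_equal(dplyr::n_distinct(run$events$replicate), 10)
  expect_setequal(unique(run$truth$regime),
                  c("uniform", "patchy", "rear_conglomerate"))
  run2 <- generate_run(sc)
  expect_identical(run$events, run2$events)
  expect_identical(run$truth, run2$truth)
  # a different seed gives different noise
  run3 <- generate_run(growth_scenario(seed = 12))
  expect_false(identical(run$events$passage_time_s,
                         run3$events$passage_time_s))
})

test_that("trace-level runs synthesise detectable transits consistent with their events", {
  sc <- deterministic_scenario(n_replicates = 1, duration_h = 1,
                               cadence_min = 30, seed = 19)
  run <- generate_run(sc, noise_free_instrument(), level = "trace")
  expect_equal(nrow(run$traces), 3)
  tr <- run$traces$transit[[1]]
  dt <- passage_time_between(detect_event(tr$trace_a),
                             detect_event(tr$trace_b))
  expect_equal(dt, run$truth$true_visc_cp[1] * 13 / 29 + 103 - 13 / 29,
               tolerance = 1e-5)
  expect_error(generate_run(growth_scenario(seed = 1), level = "trace"),
               "2000")
})

test_that("the run generator refuses desk-scale violations", {
  expect_error(generate_run(growth_scenario(cadence_min = 0.01,
                                            duration_h = 48,
                                            n_replicates = 10)),
               "1e6")
})

test_that("noise-free events invert to the exact ground truth", {
  sc <- deterministic_scenario(seed = 5)
  inst <- noise_free_instrument()
  run <- generate_run(sc, inst)
  rec <- assemble(run$events)
  expect_equal(rec$viscosity_cp, run$truth$true_visc_cp, tolerance = 1e-10)
  expect_equal(rec$od_au, run$truth$true_od_au, tolerance = 1e-10)
})

test_that("replicate spread reproduces the configured peak-viscosity SD", {
  sc <- growth_scenario(n_replicates = 200, seed = 21)
  run <- generate_run(sc)
  peaks <- run$truth |>
    dplyr::group_by(replicate) |>
    dplyr::summarise(peak = max(true_visc_cp), .groups = "drop")
  expect_equal(sd(peaks$peak), 1.86, tolerance = 0.15)
  expect_equal(mean(peaks$peak), 23.31, tolerance = 0.02)
})

test_that("calibration sets have the right size, noise level and guard rails", {
  set <- generate_calibration_set(c(1, 5, 10, 20, 30), n_rep = 10, seed = 31)
  expect_equal(nrow(set), 50)
  # passage-time scatter matches the configured jitter
  big <- generate_calibration_set(1.0, n_rep = 1000, seed = 32)
  expect_equal(sd(big$passage_time_s), 0.0112069, tolerance = 0.1)
  expect_error(generate_calibration_set(c(10, 65)), "60 cP")
  expect_warning(generate_calibration_set(55, n_rep = 2, seed = 1), "50 cP")
  # noise-free set recovers the generating line exactly
  set0 <- generate_calibration_set(c(1, 5, 10, 20, 30), n_rep = 3,
                                   instrument = noise_free_instrument(),
                                   seed = 33)
  fit <- suppressWarnings(fit_line(set0, "passage_time_s", "viscosity_cp"))
  expect_equal(fit$slope, 29 / 13, tolerance = 1e-10)
  expect_lt(1 - fit$r_squared, 1e-12)
})

test_that("negative control runs are flat apart from measurement noise", {
  sc <- growth_scenario(seed = 41)
  nc <- negative_control_run(sc)
  expect_true(all(nc$truth$true_visc_cp == sc$mu_base))
  expect_true(all(nc$truth$true_od_au == sc$od0))
  rec <- assemble(nc$events)
  expect_equal(mean(rec$od_au), sc$od0,
               tolerance = 3 * 4.9 * 1.8e-6 / sqrt(nrow(rec)) / sc$od0)
  # noise-free control is exactly constant
  nc0 <- negative_control_run(sc, noise_free_instrument())
  expect_equal(sd(assemble(nc0$events)$viscosity_cp), 0)
})
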