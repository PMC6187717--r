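test_that("assembly inverts events and flags out-of-range points", {
  ev <- tibble::tibble(
    replicate = 1L, t_h = c(0, 1, 2),
    passage_time_s = c(103, 113, 150),
    integrated_signal_au = c(2.3, 2.0, 1.7)
  )
  rec <- assemble(ev)
  expect_s3_class(rec, "dv_growth")
  expect_equal(rec$viscosity_cp[2], 23.31, tolerance = 2e-3)
  expect_true(rec$flagged[3]) # both calibrations exceeded, point kept
  expect_equal(nrow(rec), 3)
  expect_warning(empty <- assemble(ev[0, ]), "Empty")
  expect_equal(nrow(empty), 0)
})

test_that("replicate aggregation reduces to the exact pointwise identities", {
  base <- tibble::tibble(t_h = seq(0, 1, by = 0.5),
                         viscosity_cp = c(2, 3, 4), viscosity_se = NA,
                         od_au = c(0.1, 0.2, 0.3), flagged = FALSE)
  ten <- purrr::map_dfr(1:10, ~ dplyr::mutate(base, replicate = .x))
  agg <- aggregate_replicates(ten)
  expect_true(all(agg$viscosity_sd == 0))
  expect_equal(agg$n, rep(10L, 3))
  # two replicates offset by 2*delta have SD = delta * sqrt(2) everywhere
  delta <- 0.4
  two <- dplyr::bind_rows(
    dplyr::mutate(base, replicate = 1L),
    dplyr::mutate(base, replicate = 2L,
                  viscosity_cp = viscosity_cp + 2 * delta)
  )
  expect_equal(aggregate_replicates(two)$viscosity_sd,
               rep(delta * sqrt(2), 3))
  expect_error(aggregate_replicates(base |> dplyr::mutate(replicate = 1L)),
               "2 replicates")
})

test_that("OD inflexion is found at the logistic midpoint", {
  sc <- deterministic_scenario(seed = 1)
  run <- generate_run(sc, noise_free_instrument())
  rec <- assemble(run$events) |> dplyr::filter(replicate == 1)
  expect_equal(od_inflexion(rec), 6, tolerance = 1 / 6 + 1e-9)
  # densely sampled pure logistic: analytic midpoint
  dense <- tibble::tibble(t_h = seq(0, 12, by = 0.01),
                          od_au = 1 / (1 + exp(-(t_h - 6))))
  expect_equal(od_inflexion(dense, window = 1), 6, tolerance = 0.011)
  flat <- tibble::tibble(t_h = 1:20, od_au = rep(0.05, 20))
  expect_error(od_inflexion(flat), "No inflexion")
})

test_that("phase segmentation matches the designed trajectory", {
  sc <- growth_scenario(seed = 2)
  run <- generate_run(sc)
  agg <- aggregate_replicates(assemble(run$events))
  ph <- segment_phases(agg)
  expect_gte(ph$lag_end, 2)
  expect_lte(ph$lag_end, 3.2)
  expect_gte(ph$log_end, 8.5)
  expect_lte(ph$log_end, 11)
  expect_equal(ph$od_inflexion, 6, tolerance = 0.35)
  expect_true(ph$lag_end <= ph$od_inflexion)
  expect_true(ph$od_inflexion <= ph$log_end)
  expect_true(ph$log_end <= ph$stationary_end)
  expect_setequal(unique(ph$labels$phase),
                  c("lag", "log", "stationary", "death"))
  td <- tidy(ph)
  expect_equal(td$t_h[1], ph$lag_end)
})

test_that("degenerate OD curves segment sensibly", {
  # step function: lag ends where the step is
  step <- tibble::tibble(t_h = seq(0, 10, by = 0.5),
                         od_au = ifelse(t_h < 5, 0.05, 2.5))
  ph <- segment_phases(step, window = 1)
  expect_equal(ph$lag_end, 4.5)
  expect_equal(ph$log_end, 5)
  # a flat negative control is all lag with no log phase
  nc <- negative_control_run(growth_scenario(seed = 3))
  ph_nc <- segment_phases(assemble(nc$events))
  expect_true(all(ph_nc$labels$phase == "lag"))
  expect_true(is.na(ph_nc$log_end))
})

test_that("growth summaries recover the scenario parameters", {
  # noise-free single replicate: summary equals the generator's parameters
  sc0 <- deterministic_scenario(n_replicates = 1, seed = 4)
  run0 <- generate_run(sc0, noise_free_instrument())
  s0 <- summarize_growth(assemble(run0$events))
  expect_equal(s0$mu_max, 23.31, tolerance = 1e-9)
  expect_equal(s0$t_mu_max, 6)
  expect_equal(s0$od_max, max(run0$truth$true_od_au), tolerance = 1e-9)
  expect_equal(s0$mu_final, 5.5, tolerance = 5e-3)
  expect_lt(abs(s0$mu_baseline - 1.83), 0.1)
  # viscosity peak coincides with the OD inflexion within one cadence tick
  rec0 <- assemble(run0$events)
  expect_lte(abs(s0$t_mu_max - od_inflexion(rec0)), 1 / 6 + 1e-9)
  # default noisy 10-replicate run: replicate means within 2 SE of the design
  run <- generate_run(growth_scenario(seed = 5))
  summ <- summarize_growth(assemble(run$events))
  expect_equal(nrow(summ), 10)
  expect_lt(abs(mean(summ$mu_max) - 23.31), 2 * 1.86 / sqrt(10))
  expect_lt(abs(mean(summ$od_max) - 2.83), 2 * 0.07 / sqrt(10))
  # 300 mbar: low shear-limited peak
  run300 <- generate_run(growth_scenario(pressure_mbar = 300, seed = 6))
  summ300 <- summarize_growth(
    assemble(run300$events, default_viscosity_calibration(300))
  )
  expect_equal(mean(summ300$mu_max), 5.5, tolerance = 0.1)
})

test_that("the invariance test separates controls from growth", {
  nc <- negative_control_run(growth_scenario(seed = 7))
  inv <- invariance_test(assemble(nc$events))
  expect_true(all(inv$pass))
  run <- generate_run(growth_scenario(seed = 8))
  rec1 <- assemble(run$events) |> dplyr::filter(replicate == 1)
  expect_false(any(invariance_test(rec1)$pass))
  # noise-free constant series: slope exactly zero
  nc0 <- negative_control_run(growth_scenario(seed = 9),
                              noise_free_instrument())
  inv0 <- invariance_test(assemble(nc0$events))
  expect_equal(inv0$slope_per_h, c(0, 0))
  expect_error(invariance_test(assemble(nc$events)[1:5, ]), "10 points")
})
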