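# Shared fixtures: noise-free instrument variants and tiny oracles.

noise_free_sensor <- function(...) {
  sensor_model(voltage_noise_rms = 0, passage_time_jitter = 0,
               signal_noise_au = 0, ...)
}

noise_free_instrument <- function(pressure_mbar = 100, ...) {
  default_instrument(pressure_mbar, sensor = noise_free_sensor(), ...)
}

# Independent closed-form evaluation of the affine transit law, written
# directly from the resistance picture (not via passage_time()).
oracle_dt <- function(mu_cp, pressure_mbar = 100) {
  l <- 1.0
  S <- pi * (0.8e-3)^2 / 4
  dp <- pressure_mbar * 100
  alpha <- 103 - 13 / 29
  beta <- 13 / 29
  rc <- alpha * 1e4 / (l * S)
  kd <- beta * 1e4 / (l * S) / 1e-3
  l * S * (rc + kd * mu_cp * 1e-3) / dp
}

# Noise-free scenario: no replicate spread, no measurement noise.
deterministic_scenario <- function(...) {
  growth_scenario(replicate_cv = list(mu_base = 0, mu_max = 0, od_max = 0),
                  ...)
}
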