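# dropvisc

Simulation and analysis of a **two-sensor droplet-microfluidic viscometer**:
an instrument that measures the viscosity *and* optical density (OD) of a
microlitre sample plug — for example a live bacterial culture — from a single
transit between two photodetectors, in real time, over days.

The package is for experimenters and method developers who want to

* model the instrument forward (plug hydrodynamics → passage times →
  photodetector voltage traces),
* process sensor traces into droplet events (meniscus spike detection,
  passage times, interior optical averages, along-droplet scans),
* fit and invert the linear calibrations (viscosity ↔ passage time,
  OD ↔ integrated voltage, CFU ↔ OD) with diagnostics and uncertainty, and
* analyse 48-hour growth runs: phase segmentation, OD inflexion, replicate
  aggregation, summaries, and a negative-control invariance test —

all against a seeded synthetic-data generator that stands in for the
instrument.

## The model

A plug of viscosity $\mu_d$ travels in tubing of cross-section $S$ under a
pressure difference $\Delta p$. The fluidic circuit obeys a series-resistance
(Kirchhoff) law with a fixed channel resistance $R_c$ and a droplet
resistance $R_d = k_d \mu_d$ (Hagen–Poiseuille scaling, lumped calibrated
coefficient), so the passage time over the sensor separation $l$ is **affine
in viscosity** and inversely proportional to pressure:

$$\Delta t = \frac{l\,S\,(R_c + k_d\,\mu_d)}{\Delta p}.$$

$R_c$ and $k_d$ are back-solved from the reference calibration anchors
(1 cP → 103 s, 30 cP → 116 s at 100 mbar). The interior sensor voltage maps
linearly to OD ($\mathrm{OD} = -4.9\,V + 11.32$ over 1.8–2.3 a.u.), and the
two-sigma timing jitter converts to a viscosity resolution of 0.05 cP.
Everything — geometry, oil, sensor noise, network, growth scenario — is
configuration with physically anchored defaults.

## Worked example

Forward model at the reference operating point:

```r
library(dropvisc)
library(dplyr)

inst <- default_instrument()     # 0.8 mm ID tubing, 100 mbar, calibrated network
passage_time(c(1, 17, 30), inst)
#> # A tibble: 3 × 6
#>   viscosity_cp passage_time_s speed_m_s flow_rate_m3_s capillary_number
#>          <dbl>          <dbl>     <dbl>          <dbl>            <dbl>
#> 1            1           103    0.00971  0.00000000488         0.000202
#> 2           17           110.   0.00908  0.00000000456         0.000189
#> 3           30           116    0.00862  0.00000000433         0.000179
```

A 1 cP plug crosses in 103 s at ~9.7 mm/s; capillary number ~2×10⁻⁴ confirms
plug flow. A full synthetic growth run — 10 replicate droplets, 48 h at
10-min cadence — processed through the inversion chain:

```r
run  <- generate_run(growth_scenario(seed = 42))   # events + ground truth
rec  <- assemble(run$events)                       # invert both calibrations
summarize_growth(rec) |> summarise(across(-replicate, ~ round(mean(.x), 3)))
#>   mu_baseline mu_max t_mu_max od_max mu_final od_final
#> 1        2.07   23.1        6   2.81     5.52     2.59

tidy(segment_phases(aggregate_replicates(rec)))
#>   boundary         t_h
#> 1 lag_end         3
#> 2 od_inflexion    6.08
#> 3 log_end         9
#> 4 stationary_end 12.3
```

The recovered culture numbers read directly: lag-phase viscosity ≈ 2 cP,
peak 23.1 cP at t = 6 h (coinciding with the OD inflexion), relaxing to
5.5 cP by 48 h while OD plateaus near 2.8 — the coupled viscosity/OD
signature of a growing, aggregating, then declining culture. The instrument
resolution under the two-sigma criterion:

```r
resolution(0.05 * 13/58)
#>   sigma_dt_s slope_cp_per_s resolution_cp criterion
#> 1     0.0112           2.23          0.05 two-sigma single measurement
```

`autoplot()` methods cover calibrations and aggregated growth curves;
`plot_trace()` and `plot_scan_profile()` show raw sensor signals and
along-droplet structure. See `vignette source in vignettes/` for the full
account of the model, conventions and limitations.

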