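---
title: "Droplet viscometry: model, calibration and growth-curve analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Droplet viscometry: model, calibration and growth-curve analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dropvisc)
library(dplyr)
```

## The measurement principle

A microlitre plug of sample (the dispersed phase) travels through thin FEP
tubing, carried by a fluorinated oil under a constant pressure difference
$\Delta p$. Treating the fluidic circuit like an electrical one, the channel
filled with oil contributes a fixed hydrodynamic resistance $R_c$ and the
plug contributes $R_d$, so that

$$R_c + R_d \;=\; \frac{\Delta p}{Q} \;=\; \frac{\Delta p}{S\,v}
\;\simeq\; \frac{\Delta t\, \Delta p}{S\,l},$$

with $Q$ the volumetric flow rate, $S$ the tube cross-section, $v$ the plug
speed, $l$ the distance between the two optical sensors, and $\Delta t$ the
passage time between them. For a long plug the Hagen–Poiseuille picture gives
$R_d \propto \mu_d$, the plug viscosity, so the passage time is *affine in
viscosity*:

$$\Delta t \;=\; \frac{l\,S\,(R_c + k_d\,\mu_d)}{\Delta p}.$$

Measuring $\Delta t$ and inverting a linear calibration therefore measures
viscosity. The same optical sensors read the light transmitted through the
plug interior, whose time-averaged voltage maps linearly to optical density
(OD) — so one transit yields a simultaneous viscosity and OD reading of a
live bacterial culture enclosed in the droplet.

```{r forward}
inst <- default_instrument() # 0.8 mm ID tubing, 100 mbar, calibrated network
passage_time(c(1, 30), inst)[, 1:3]
```

### Why the droplet resistance is a lumped coefficient

`k_d` is *calibrated*, not derived ab initio: a bare Hagen–Poiseuille
estimate of the plug's own resistance disagrees with the measured
viscosity-vs-time slope, because the lubricating oil film, the end caps and
internal circulation all modify the effective resistance. The package
back-solves $R_c$ and $k_d$ from the two anchor points of the reference
calibration (1 cP at 103 s, 30 cP at 116 s, under 100 mbar), which pins the
model to what the instrument actually does. A consequence worth recording:
with these constants the droplet-to-channel resistance ratio at 1.7 cP is
roughly 1:135, not the ~1:500 sometimes quoted for a full microfluidic
system — lead tubing and junction resistances outside the measured section
plausibly account for the difference, so the package never asserts the
larger ratio.

The interface shear-rate diagnostic uses a calibrated coefficient as well:
`interface_shear_rate()` returns $c_s v / r$ with $c_s = 0.453$ chosen to
reproduce ~11 s⁻¹ for a fresh-medium plug at 100 mbar. The exact film-flow
solution is out of scope; at 24 cP the coefficient estimate gives
~10 s⁻¹ where ~9 s⁻¹ is expected — users should treat the shear numbers as
order-of-magnitude diagnostics, not measurements.

### Validity limits

Droplet generation is monodisperse up to ~50 cP; `passage_time()` warns
above that and `generate_calibration_set()` refuses standards above 60 cP.
The capillary number at the reference point is
$\mathrm{Ca} = \mu_o v/\gamma \approx 2\times10^{-4}$, deep in the
plug-flow regime, which is what licenses the constant-speed, rigid-plug
kinematics throughout.

## Trace synthesis and event detection

`simulate_transit()` renders what the photodetectors record: baseline
voltage over oil (2.5 a.u.), a sharp Gaussian spike as each meniscus passes
(amplitude 0.3 a.u., width 0.02 s, polarity configurable — only "sharp
spike" is constrained, not its shape), the interior voltage
$V = 2.3102 - 0.20408\,\mathrm{OD}(s)$ mapped from the axial OD profile
under constant speed, and white noise of 50 µV RMS. Sensor B's event lags
sensor A's by the true passage time plus one draw of timing jitter
($\sigma_{\Delta t} = 0.0112$ s, see below). Traces are windowed (±1 s
around each event) at 2 kHz; full-loop traces would be wastefully long.

`detect_event()` inverts this: spikes are local maxima of the residual
against a rolling-median baseline (window 0.1 s), qualifying when they
exceed 4 robust noise SDs with an absolute floor of 0.02 a.u. (the floor
keeps noise-free traces well-posed). The first and last qualifying spikes
delimit the droplet; more than two produce a multiplet warning and the
outermost pair is used — interior OD structure can legitimately produce
extra candidates. The interior window shrinks the spike-to-spike interval
by a 10% guard fraction per side before averaging, which keeps meniscus
lensing (and most of the spike tails) out of the OD reading; a residual
leak of order $10^{-3}$ a.u. at the guard edges remains visible in
`scan_profile()` edge bins and is the reason OD round-trips through traces
are exact to ~0.003 a.u. rather than machine precision. Event-level
simulation (the default for long runs) bypasses trace synthesis and is
exact by construction.

Timing uses the leading-edge convention (front spike to front spike):
insensitive to droplet-length changes, and consistent with the definition
of passage time between sensors.

```{r trace}
tr <- simulate_transit(droplet_state(10, od = 1.2), inst, seed = 1)
ev <- detect_event(tr$trace_a)
ev[, c("front_spike_time_s", "back_spike_time_s", "integrated_signal_au")]
```

## Calibrations, uncertainty and resolution

Three linear maps, all `dv_calibration` objects with `tidy()`/`glance()`
methods and explicit validity ranges:

* **viscosity vs passage time** — slope $29/13 \approx 2.2308$ cP/s,
  intercept $-228.77$ cP at 100 mbar; at pressure $p$ the slope scales as
  $p/100$ (passage times scale as $100/p$) while the intercept is
  pressure-invariant.
* **OD vs integrated voltage** — the line through (1.8 a.u., OD 2.5) and
  (2.3 a.u., OD 0.05): $\mathrm{OD} = -4.9 V + 11.32$. The "integrated
  signal" is the *time-averaged* interior voltage, not a raw time
  integral — a raw integral would scale with droplet speed and could not
  share the 1.8–2.3 a.u. axis of the calibration. Growth runs exceed the
  OD 2.5 anchor (plateau 2.83), so out-of-range inversions are flagged as
  extrapolated rather than rejected.
* **CFU vs OD** — linear, optionally through the origin. The default
  conversion 8×10⁸ CFU/mL per OD unit in `cfu_from_od()` is a conventional
  order of magnitude for *E. coli* in LB supplied for exercising the fit;
  it is configuration, not a measured constant.

Inverted viscosities carry a 1-SE uncertainty propagated from the fit;
anchored (data-free) default calibrations report `NA` there. No
multiple-testing machinery is needed anywhere in the pipeline.

**Resolution.** The instrument's resolution is defined here as twice the
single-measurement SD expressed in viscosity units:
$2\,\sigma_{\Delta t}\,(\mathrm{d}\mu/\mathrm{d}\Delta t)$. No resolution
criterion is universal; the two-sigma convention is adopted because it
matches the visual separation of passage-time histograms taken 0.1 cP
apart. The default timing jitter is *back-solved* from this criterion:
$\sigma_{\Delta t} = 0.05 \cdot 13/58 = 0.0112$ s makes the resolution
exactly 0.05 cP at the 100 mbar slope. Jitter is treated as a property of
the timing chain and kept pressure-independent.

```{r resolution}
resolution(0.05 * 13 / 58)$resolution_cp
```

## The synthetic growth scenario

No deposited data exist for this kind of instrument — every study quantity
is an instrument reading — so the generator *is* the data source, and its
defaults are the study conditions:

| parameter | default | status |
|---|---|---|
| OD: lag level / plateau | 0.05 / 2.83 a.u. | anchored |
| OD inflexion time | 6 h | anchored |
| viscosity: baseline / peak (100 mbar) | 1.83 / 23.31 cP | anchored |
| peak at 200 / 300 mbar | 10 / 5.5 cP | anchored |
| 48-h viscosity asymptote | 5.5 cP | anchored |
| replicate CVs (base, peak, OD max) | 0.21, 0.08, 0.025 | back-solved from spreads 0.38, 1.86, 0.07 |
| growth rate `k_growth` | 1.0 h⁻¹ | convention |
| stationary onset / death slope | 12 h / 0.0064 a.u. h⁻¹ | convention |
| cadence / duration / replicates | 10 min / 48 h / 10 | anchored |

The OD curve is logistic plus a linear death-phase decline. The viscosity
curve is slaved to the OD rise up to the inflexion and relaxes
exponentially afterwards (time constant 6 h), continuous at the peak:

$$\mu(t) = \mu_\mathrm{base} + (\mu_\mathrm{peak} - \mu_\mathrm{base})
\left[\frac{\mathrm{OD}(t)-\mathrm{OD}_0}
{\mathrm{OD}(t_\mathrm{inflex})-\mathrm{OD}_0}\right]^{p}, \quad t \le t_\mathrm{inflex}.$$

The shape exponent defaults to $p = 2$. This is a deliberate design choice:
with $p = 1$ the logistic's early tail drags the lag-phase viscosity from
1.83 up to ~4 cP before the lag even ends — but lag-phase viscosity changes
in this system are negligible relative to the replicate scatter
(±0.38 cP). The quadratic coupling keeps the whole lag phase within that
scatter (mean ≈ 1.87 cP over the detected lag) while preserving
$\mu(t_\mathrm{inflex}) = \mu_\mathrm{peak}$ exactly, monotonicity in OD,
and continuity at the peak. `rise_exponent` is configuration like
everything else.

Spatial structure follows viscosity: below 5 cP the plug content is
homogeneous; between 5 and 15 cP on the rising branch it is patchy (2–4
random aggregate bumps); above 15 cP a single conglomerate occupies the
trailing quarter of the plug; after the peak the content is homogeneous
again. Every generated profile is rescaled so its spatial mean equals the
true OD exactly — the event-level signal never depends on the regime. The
5/15 cP thresholds are qualitative conventions.

Replicate factors are lognormal with mean 1 (so recovery is unbiased) and
the CVs above. A single seeded generator is threaded through every
stochastic operation (`withr::with_seed` scoping), and identical seeds give
bit-identical event records; `run_manifest()` records the seed with the
configuration snapshot and output hashes.

**What the generator does not emulate:** mechanistic aggregation or
motility, oxygen transport, temperature drift, pressure-regulator drift,
droplet-volume error, biofilm fouling, or any coupling between the OD and
viscosity *noise*. Passing the round-trip tests therefore shows the
analysis chain is correct and well-calibrated against this idealisation,
not that a real instrument meets the same numbers.

## Growth analysis conventions

Phases have no universal numeric boundaries; the segmentation conventions
are explicit and configurable: the lag ends at the last tick with smoothed
OD below 5% of the observed range above its minimum; the log phase ends at
the first tick within 5% of the observed maximum; stationary ends at the
first sustained decline (3 consecutive decreasing ticks); the OD inflexion
is the maximum first difference of the smoothed curve, ties to the
earliest tick. Smoothing is a centred moving average, window 5 ticks
(50 min), truncated at the ends — the simplest estimator adequate at the
configured noise level. A curve whose smoothed range is below `min_range`
(0.1 a.u.) is all lag: that is what a negative control looks like.

`summarize_growth()` computes extrema on the *raw* calibrated series by
default (`smooth_window = 1`): the calibrated-viscosity noise at the
default cadence is ~0.03 cP, far below replicate variation, while
averaging across a kinked peak would bias the maximum down by ~1 cP.
The window is a parameter for noisier data. One side effect worth knowing:
on long flat stretches (e.g. the 300 mbar run, whose post-peak curve is
constant at 5.5 cP) the raw maximum rides the upper envelope of the noise
and of the one-sided replicate factor, giving a small (+0.3–0.4 cP) upward
bias that sits well within the 10% reproduction band for that quantity.

`invariance_test()` regresses viscosity and OD on time and passes when the
95% CI of the slope covers zero. Under the null this passes with
probability equal to the nominal coverage, so repeated-seed studies should
compare the observed pass fraction against binomial bounds around 0.95,
not against 0.95 itself.

```{r pipeline}
run <- generate_run(growth_scenario(seed = 7))
rec <- assemble(run$events)
summarize_growth(rec) |> summarise(across(-replicate, mean))
tidy(segment_phases(aggregate_replicates(rec)))
```

## Numerical and degenerate-input choices

* Constants are stored as exact expressions (`13/29`, `0.05*13/58`,
  `-0.5/2.45`), not rounded decimals, so inversion identities hold to
  machine precision.
* `passage_time_numeric()` is an independent fixed-step integration of the
  plug kinematics kept in the package as a cross-check of the closed form
  (agreement better than 1e-9 relative).
* Spike detection tie-breaks to the earliest qualifying sample; fewer than
  two spikes is a hard no-droplet error; fewer than 20 interior samples is
  an undersampling error (both in synthesis and detection).
* Degenerate fits (all-identical predictor) error; constant series give an
  exact zero slope with a trivially passing invariance test; empty event
  lists assemble to an empty record with a warning.
* `generate_run()` refuses runs beyond 10⁶ events, and trace-level
  synthesis is capped at 2000 events; both are desk-scale guards.

The test suite exercises the stochastic properties at deliberately modest
sizes — 500-transit detection round trips, 1000-transit resolution
estimates, 100-seed calibration-quality studies, 400-seed invariance
studies, 10-replicate growth round trips — sizes chosen so the whole suite
runs in under a minute while leaving the binomial/sampling error of each
check comfortably below its tolerance.

## Known limitations

* The hydraulic model is lumped and linear; it cannot represent
  non-Newtonian plugs, film-thickness dependence on Ca, or inertial
  effects — all negligible at Ca ~ 2×10⁻⁴ but real elsewhere.
* The shear-rate and CFU numbers are calibrated conveniences, not
  first-principles outputs.
* Calibration inversion assumes the instrument state (oil, temperature,
  pressure) matches the calibration's; the package tracks validity ranges
  but cannot detect drift.
* The growth model is descriptive. Its functional forms are the minimal
  ones consistent with the anchored values; they carry no mechanistic
  claim about aggregation or oxygen limitation.
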