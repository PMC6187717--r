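Package: dropvisc
Title: Droplet Microfluidic Viscometry and Bacterial Growth-Curve Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward simulation and analysis pipeline for a two-sensor
    droplet-microfluidic viscometer. Models the hydrodynamic resistance of a
    plug travelling in pressure-driven tubing flow, synthesises photodetector
    voltage traces with meniscus spikes and optical-density attenuation,
    extracts droplet events from traces, fits and inverts the linear
    viscosity/passage-time and optical-density/voltage calibrations with
    uncertainty, and analyses 48-hour bacterial growth runs (phase
    segmentation, OD inflexion, replicate aggregation, negative-control
    invariance test). A seeded synthetic-data generator emulates coupled
    optical-density and viscosity trajectories of a growing culture,
    shear-dependent viscosity maxima, spatial aggregate profiles and
    replicate variability, standing in for the instrument.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
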