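Package: robovent
Title: Coupled Human-Robot Two-Compartment Respiratory Mechanics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of robot-assisted ventilation with a
    lumped-parameter two-compartment chest-wall model. Simulates rib-cage,
    abdominal and lung volume dynamics under muscle and extracorporeal
    robotic driving pressures, derives pleural pressure and diaphragm
    displacement, generates synthetic ultrasound (M-mode) and spirometer
    recordings for cohorts of virtual participants, traces diaphragm curves
    from M-mode images, computes breath-by-breath excursion and tidal
    volume metrics with paired spontaneous-vs-assisted comparisons, fits
    free model parameters to recordings by bounded least squares, and
    simulates the on-off pneumatic valve controller of the soft actuator
    with its step-response and tracking metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    minpack.lm,
    jsonlite,
    yaml,
    png,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
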