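# robovent

Simulation and analysis of **robot-assisted ventilation** with a
lumped-parameter two-compartment respiratory mechanics model.

Wearable soft robots can assist breathing from outside the body by
pressing on the abdominal wall during expiration, pushing the diaphragm
cranially and augmenting ventilation. Evaluating such devices hinges on two
measurements: diaphragm **excursion** (peak-to-trough displacement per
breath, read from M-mode ultrasound, cm) and **tidal volume** (the
integral of spirometer flow per breath, L). `robovent` provides the full
computational stack for this problem — for researchers in respiratory
biomechanics and soft-robotic assistance who need a tested, reproducible
pipeline from mechanics model to cohort-level statistics, without access
to raw clinical recordings.

## The model

Respiration is modeled as two first-order chest-wall compartments (rib
cage, abdomen) coupled to the lung through the pleural cavity:

```
R_rc dV_rc/dt + V_rc/C_rc = P_rcmus
R_ab dV_ab/dt + V_ab/C_ab = P_dimus + P_rex
P_pl = (V_ab + V_rc)/C_pl
R_l  dV_l/dt  + V_l/C_l  = P_pl
x_di [cm] = 100 · (V_ab · 1e-3) / A_di
```

`P_rcmus`/`P_dimus` are muscle driving pressures, `P_rex` the effective
robotic pressure on the abdominal wall (signed negative during expiratory
assistance), and `x_di` the diaphragm displacement through body
cross-section `A_di`. The package adds everything around the model:
waveform generators (half-sine muscle drives; square/triangle/sine robotic
programs at 30–50 kPa with an explicit actuator-to-abdomen transmission
gain), a synthetic cohort generator with ultrasound/spirometer measurement
surrogates, M-mode image rendering and curve tracing, breath segmentation
and metrics (excursion, tidal volume, amplitude error, NRMSE, paired
Wilcoxon comparison), bounded least-squares parameter fitting, and a
simulator of the actuator's on-off pneumatic valve controller. The
Yoshimura-origami closure condition `tan γ · cos(θ/2) = tan(π/M)` of the
actuator geometry is included as a design helper.

## Worked example

Calibrate a virtual participant to the reference spontaneous measurements
(excursion 1.14 cm, tidal volume 0.83 L), then add calibrated robotic
assistance:

```r
library(robovent)

p6 <- calibrate_amplitudes(
  participant_profile(noise_disp = 0, noise_flow = 0, id = "P6"))

measure_session(generate_session(p6, "spontaneous", seed = 1))
#> # A tibble: 1 × 4
#>   mean_excursion mean_vt n_breaths_disp n_breaths_flow
#>            <dbl>   <dbl>          <int>          <int>
#> 1           1.14   0.830              6              4

assist <- calibrate_assistance(p6)   # effect-ratio knobs 1.95x / 2.14x
measure_session(generate_session(p6, "assisted", program = assist$program,
                                 pattern = assist$pattern, seed = 1))
#> # A tibble: 1 × 4
#>   mean_excursion mean_vt n_breaths_disp n_breaths_flow
#>            <dbl>   <dbl>          <int>          <int>
#> 1           2.22    1.78              6              4
```

The calibrated session reproduces the targets: 1.14 cm and 0.830 L
spontaneously, 2.22 cm (= 1.95 × 1.14) and 1.78 L (= 2.14 × 0.83) with
assistance. A full cohort — sampling mechanics variability, generating
paired sessions, measuring, testing, and fitting — is one call:

```r
res <- analyze_cohort(run_config(seed = 1))
res$comparison$excursion
#> <comparison_result> n=8  ratio of means 1.943  mean ratio 1.943  p=0.007812
```

The pipeline recovers the calibrated effect ratios from the noisy
recordings (1.94× measured vs the 1.95× knob) with an exact Wilcoxon
signed-rank p = 0.0078 for n = 8. Every fitted object supports
`tidy()`, `glance()`, and `autoplot()`.

The pneumatic controller and actuator geometry:

```r
step_metrics(simulate_pneumatics(plant_params(), 50, duration = 10))
#> # A tibble: 1 × 3
#>   rise_time_s settling_time_s overshoot_kpa
#>         <dbl>           <dbl>         <dbl>
#> 1        0.15            0.15             0

yoshimura_prefold_angle(60, 4)
#> [1] 109.4712
```

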