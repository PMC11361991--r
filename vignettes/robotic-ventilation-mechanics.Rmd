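---
title: "Coupled human-robot respiratory mechanics: model, synthetic data, and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coupled human-robot respiratory mechanics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(robovent)
```

# The model

`robovent` models respiration as a lumped-parameter two-compartment chest
wall — rib cage and abdomen, separated by the diaphragm — coupled to the
lung through the pleural cavity. Each compartment is a first-order
resistance–compliance element; all volumes are deviations from the
end-expiratory baseline (functional residual capacity):

$$R_{rc}\,\dot V_{rc} + V_{rc}/C_{rc} = P_{rcmus}$$
$$R_{ab}\,\dot V_{ab} + V_{ab}/C_{ab} = P_{dimus} + P_{rex}$$
$$P_{pl} = (V_{ab} + V_{rc})/C_{pl}, \qquad
  R_l\,\dot V_l + V_l/C_l = P_{pl}$$

$P_{rcmus}$ and $P_{dimus}$ are the rib-cage and diaphragm muscle driving
pressures; $P_{rex}$ is the effective pressure a wearable extracorporeal
robot applies to the abdominal wall. The displaced abdominal volume moves
the diaphragm through the body cross-section $A_{di}$:

$$x_{di}\,[\mathrm{cm}] = 100\,\frac{V_{ab}\cdot 10^{-3}}{A_{di}}$$

with explicit L→m³ and m→cm conversions at that boundary. Internal units
are cmH₂O, L, s throughout; $A_{di}$ is in m².

Reference parameter values (`mech_params()` defaults):

| parameter | value | units |
|---|---|---|
| $R_{rc}, R_{ab}$ | 1 | cmH₂O/(L·s) |
| $R_l$ | 2 | cmH₂O/(L·s) |
| $C_{rc}, C_l$ | 0.2 | L/cmH₂O |
| $C_{ab}$ | 0.4 | L/cmH₂O |
| $C_{pl}$ | 0.25 | L/cmH₂O |
| $A_{di}$ | 0.08 | m² |

The time constants are 0.2–0.4 s, far shorter than a 3–6 s breath, so each
compartment tracks its drive quasi-statically with a modest lag.

## Sign conventions

Positive $V_{ab}$ means caudal diaphragm displacement (abdominal wall
outward). The robot pushes the abdominal wall inward — diaphragm cranially —
during expiration, so the robotic channel is encoded as a *negative-signed*
trace ($P_{rex} \le 0$) while the abdominal driving pressure remains the
plain sum $P_{ab} = P_{dimus} + P_{rex}$. Direction lives in the waveform
sign; the algebra is untouched. This is our resolution of an ambiguity in
the source description, which adds the robotic pressure with the same sign
as the muscle pressure while describing cranial diaphragm motion.

A second textual ambiguity — the lung equation's constants described with a
garbled compartment list — is read as lung-only constants $R_l$, $C_l$.

## Integration

`simulate_mechanics()` integrates the system with classical fixed-step
4th-order Runge–Kutta (default `dt` = 1 ms), linearly interpolating the
drive traces between grid points and sampling the output on the drive grid.
Because the system is linear and time-invariant, the per-step RK4 update is
an affine map $x_{n+1} = \Phi x_n + G_0 u_n + G_1 u_{n+1}$ with constant
matrices, which the package evaluates as three C-level recursive filters.
This is algebraically identical to the literal stage-by-stage loop (the
test suite verifies agreement with a closed-form first-order oracle to
below $10^{-6}$ L and step-halving stability below $10^{-8}$ L) while
remaining bit-stable and fast. An adaptive-step solver was deliberately
avoided: the system is stiff-free at the reference time constants and
fixed-step integration gives reproducible results to the last bit.

Initial volumes default to zero (rest at functional residual capacity); the
source never states initial conditions.

# Driving waveforms

Muscle drives are half-rectified sines per channel: a half-sine of the
channel amplitude over the inspiratory window $[0, f_{insp}T)$, zero during
expiration. The source only calls the muscle drive "trigonometric"; the
rectified half-sine, amplitudes, and phase are this package's choices,
exposed via `breath_pattern()`. Defaults are $T = 6$ s and $f_{insp} = 0.5$,
which make the expiratory window exactly fit the 3 s robotic inflation of
the study protocol.

The robotic program (`robot_program()`) is a square, triangle, or half-sine
pulse over the first `t_inflate` seconds of each expiration, at an actuator
set pressure of 30–50 kPa. The model needs that pressure in cmH₂O on the
abdominal wall, and the two printed scales are reconciled by an explicit
free constant `k_transmission` (default 0.1 cmH₂O/kPa, so a 30 kPa square
program produces the 3 cmH₂O effective plateau of the reference parameter
table). It is a documented calibration constant, not derived physics.

The actuator geometry helper `yoshimura_prefold_angle()` solves the closure
condition $\tan\gamma \cos(\theta/2) = \tan(\pi/M)$ of the cylindrical
origami fold pattern; for the built design ($\gamma = 60°$, $M = 4$) it
returns $\theta = 2\arccos(1/\sqrt3) \approx 109.47°$.

```{r waveforms, eval = FALSE}
pat <- breath_pattern(t_total = 6, f_insp = 0.5, a_rc = 5, a_dim = 2.5)
drives <- build_drives(pat, robot_program("square", 30), n_breaths = 6)
traj <- simulate_mechanics(mech_params(), drives)
autoplot(traj)
```

# Synthetic cohorts and sessions

No raw recordings from the study are available, so every downstream stage
is exercised on synthetic data that emulates the measurement structure:
per-breath diaphragm displacement (the M-mode ultrasound surrogate) and
airflow (the spirometer surrogate).

* **Variability.** `sample_cohort()` multiplies every resistance and
  compliance by independent unit-mean lognormal factors (default cv = 0.2 —
  wide enough to reproduce the "varied widely across participants"
  character of the study while keeping parameters positive) and draws
  breath periods uniformly from the typical 3–6 s range.
* **Noise.** Additive Gaussian, defaults 0.05 cm (displacement) and
  0.02 L/s (flow). The source reports no noise characteristics; these
  levels are roughly 4–5% of the spontaneous signal ranges, a realistic
  scale for M-mode reading and flow sensing.
* **Sampling.** One shared session grid (default 100 Hz) for both channels.
  The two instruments in the study ran at different rates, but a shared
  grid keeps every recording self-consistent; the 50 Hz ultrasound
  surrogate appears instead as the default M-mode image time axis.
* **Determinism.** Every generator is a pure function of its inputs and an
  integer seed.

## Calibration: targets, not predictions

Muscle amplitudes are never printed in the source, so they are *calibrated*:
`calibrate_amplitudes()` solves for $(A_{dim}, A_{rc})$ such that the
noiseless spontaneous session reproduces a target mean excursion and tidal
volume — by default the printed reference spontaneous values 1.14 cm and
0.83 L. Excursion depends only on $A_{dim}$ (the abdominal compartment sees
only the diaphragm channel) and is exactly linear in it; $A_{rc}$ then
follows from a one-dimensional root search on the volume target.

The assisted condition is likewise calibrated, with two explicit knobs:
`calibrate_assistance()` scales `k_transmission` until the assisted mean
excursion is `r_disp` (default 1.95) times the spontaneous one, then
re-solves the assisted-condition rib-cage amplitude until the tidal-volume
ratio equals `r_vol` (default 2.14). Letting the assisted breathing pattern
differ from the spontaneous one is deliberate: the study itself observed
breathing slow down under assistance, and participants were trained to
synchronize with the 3 s robot cycle. For the same reason the assisted
period is stretched to `t_inflate / (1 - f_insp)` (6 s at defaults) so the
programmed inflation always fits the expiration, whatever the participant's
spontaneous rate. These ratios are calibration constructs that stand in for
the unavailable raw cohort data — the pipeline's job is to *recover* them
from the generated recordings, not to predict them.

In cohort generation each subject's two targets are scaled by a single
lognormal body-size factor (cv = 0.15), keeping the excursion/volume pair
physically consistent. If a subject's sampled mechanics make the volume
target unattainable even with no rib-cage drive (the diaphragm alone
already displaces more), the generator accepts a diaphragm-dominant
breather with $A_{rc} = 0$ rather than failing; direct calls to
`calibrate_amplitudes()` keep the strict error by default.

# Measurement and metrics

`measure_session()` implements the study's measurement procedure:

* a 0.25 s centered moving average conditions both channels before
  segmentation — the stand-in for the smoothing any M-mode reader or
  spirometry software applies. Excursions are read from the smoothed
  displacement; a raw per-cycle max − min would be biased upward by
  noise extremes. Tidal volumes integrate the *raw* flow, where zero-mean
  noise averages out.
* `segment_breaths()` finds cycle starts: negative-to-positive zero
  crossings with a ±2%-of-peak hysteresis band (flow), or local minima
  separated by at least half the nominal period (displacement).
* `tidal_volumes()` is the trapezoidal integral of the inspiratory
  (positive) flow per cycle, with the expiratory integral reported
  alongside as a mass-balance check. `excursions()` is the per-cycle
  peak-to-trough displacement.
* `normalize_cycles()` resamples each cycle to 20 points of normalized
  phase and averages the first 3 cycles — the protocol used for waveform
  comparisons across conditions.
* `amplitude_error()` is $100\,|sim-obs|/obs$; `nrmse()` is RMSE normalized
  by the observed peak-to-peak range (the source never defines its
  normalization; range normalization is the common choice for periodic
  signals and is scale-invariant).
* `paired_ratio_test()` reports both the ratio of condition means (default
  headline number) and the mean of per-subject ratios — the source does not
  say which it printed — plus a two-sided *exact* Wilcoxon signed-rank
  p-value, chosen over a paired t-test because n = 8 warrants no normality
  assumption.

# M-mode rendering and tracing

`render_mmode()` draws one image column per time sample: a Gaussian bright
band (FWHM = `band_width`, default 0.3 cm) centered at the displacement
depth over a uniform background, quantized to 8-bit, depth increasing
downward. It emulates the geometry of an M-mode display only — no speckle,
attenuation, probe geometry, or cardiac artifacts.

`trace_mmode()` recovers the curve by per-column argmax after 3-pixel
vertical smoothing, followed by a 5-column running median for continuity;
flat (signal-free) columns fall back to neighbor interpolation and lower
the reported `quality` fraction. The study cites an external segmentation
method without details, so the simplest robust tracer with a stated
contract was chosen; round-trip accuracy (within one depth pixel for
band-limited signals, verified by property tests) is its contract, not
equivalence with the study's tool.

# Pneumatic control

The supply/exhaust solenoid pair follows a dead-band (bang-bang) law around
the target pressure; `simulate_pneumatics()` closes the loop against a
first-order plant — one chamber filled from a 100 kPa source
(`tau_fill` = 0.25 s) and vented to atmosphere (`tau_vent` = 0.35 s) at a
100 Hz loop rate with a 10%-of-target dead band. The source gives no plant
model or loop rate; these defaults are a plausibility construct whose
simulated 0→50 kPa step lands inside the reported hardware envelope
(settling < 0.75 s, overshoot < 5 kPa), asserted as a property of the
simulation, not a hardware reproduction. The ambiguous printed rise-time
definition is read as "first time within 10% of the target", consistent
with the settling definition.

# Model fitting

`fit_mechanics()` estimates free parameters (muscle amplitudes, effective
robotic pressure, compliances) by bounded Levenberg–Marquardt least squares
on two residual channels: the displacement trace and the flow-integrated
volume trace, each normalized by its observed peak-to-peak range so units
cannot dominate (default 1:1 weights). The simulated volume is pushed
through the *same* discrete pipeline as the observation (forward-difference
flow, cumulative trapezoid) so the noiseless residual is exactly zero at
the truth. Five deterministic multi-starts spread over the bounds (with a
small seeded jitter) guard against local minima; cycle alignment is a
cross-correlation lag on the displacement channel, estimated from the
fitted simulation and refined iteratively, applied to both channels.
Protocol timing (breath period, inspiratory fraction, program shape/level)
is treated as known experimenter-set metadata; only physiology is free.

`recovery_experiment()` wraps the generate→fit loop: true amplitudes drawn
uniformly per replicate, sessions generated at relative noise levels
(noise SD as a fraction of the noiseless channel range), and per-parameter
bias/RMSE/median-absolute-relative-error summaries. At the package's
reference conditions (20 replicates, 10 breaths, 50 Hz) zero-noise recovery
is exact to numerical precision and 5% measurement noise leaves the
diaphragm-amplitude error well under 1%.

# Problem sizes and runtime choices

Default problem sizes were chosen as the smallest that exercise every
stage at the study's own scale: 8-subject cohorts, 6 breaths per session at
100 Hz (10 breaths at 50 Hz for recovery experiments), 20 recovery
replicates, 100 random drive pairs for the superposition property. The
linear-filter integrator makes a full cohort run (calibration, paired
sessions, metrics, 16 model fits) complete in well under a minute.

# What passing tests do and do not show

All evaluation is on synthetic data generated by the package's own model.
Passing the acceptance properties shows the pipeline is *self-consistent*:
the integrator matches analytic solutions, the measurement stack recovers
what the simulator produced, calibration targets are reproduced, and
calibrated effect ratios survive the full generate→measure→compare loop.
It does **not** validate the model against real physiology: the printed
in-vivo cohort numbers (1.95×/2.14× augmentation, <7% amplitude error,
NRMSE bounds) derive from eight human participants whose raw recordings
are not deposited, and the synthetic cohort emulates their *structure*,
not their data. Known limitations: linear mechanics (no posture, gravity,
or gas compressibility), no airflow-triggered synchronization, no
ultrasound physics, and no identifiability analysis beyond the recovery
tables.
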