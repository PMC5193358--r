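---
title: "Joint-space modelling of walking energetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint-space modelling of walking energetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitmee)
```

## The model

gaitmee models the instantaneous metabolic energy expenditure (MEE) rate of
walking in joint space. The body is an articulated chain with up to $n = 42$
rotational degrees of freedom (3 per ankle, knee, hip, wrist, elbow and
shoulder on each side, plus 3 each for neck and waist). Given joint angular
velocities $\dot q_i(t)$ (rad/s) and actuator torques $\tau_i(t)$ (N·m), the
model decomposes whole-body metabolic power into net joint work, two
generalized muscle-heat terms, an optional torque-independent cocontraction
term and the basal rate:

$$
\dot E_{met}(t) \;=\; \sum_i \tau_i\dot q_i
\;+\; \sum_i h_i^{am}\,|\tau_i|
\;+\; \sum_i h_i^{sl}\,|\tau_i\dot q_i|
\;+\; \sum_i \dot Q_i^{cc}
\;+\; \dot E_{bmr}.
$$

The two heat terms are joint-space images of the activation–maintenance and
shortening–lengthening heat of skeletal muscle. By the second law of
thermodynamics every heat component is non-negative, which is why the torque
and power enter through absolute values: concentric and eccentric phases
with equal $|\tau\dot q|$ dissipate equally. $h^{am}$ carries units of 1/s
(it converts a torque into watts); $h^{sl}$ is dimensionless.
$\dot Q^{cc}$ defaults to zero — relaxed, natural walking makes the
torque-independent cocontraction negligible — but is accepted as an input
trace. The basal rate $\dot E_{bmr}$ is a measured subject parameter
(sitting BMR); its internal decomposition is out of scope.

Economy measures derive pointwise and by interval:

$$
\mathrm{ICOT}(t) = \frac{\dot E_{met}(t)}{M\,g\,v(t)}, \qquad
\mathrm{COT}_T = \frac{\tfrac1T\int_T \dot E_{met}\,dt}
                      {M\,g\,\tfrac1T\int_T v\,dt},
$$

with $M$ body mass, $g = 9.81$ m/s² (configurable; the value is a
convention, not measured), and $v(t)$ the centre-of-mass speed. $T$ may be a
whole stride, a union of gait-phase intervals (single support SS, double
support DS), or a single instant.

### Subject-specific heat coefficients

Subjects differ energetically even under identical kinematics. The
coefficients are separable products of a subject factor and a DOF factor:

$$
h_i^{am} = \big(w_0^{am} + w_1^{am} m_n + w_2^{am} a_n + w_3^{am} h_n\big)
\Big(1 + w_4^{am}\,\tfrac{\tau^{max}_{knee}}{\tilde\tau^{max}_{knee}}
\tilde\tau_{n,i}\Big),
$$

and analogously for $h^{sl}$. Here $m_n = M/100$, $a_n = A/100$,
$h_n = H/10$ and $\tilde\tau_{n,i} = \tilde\tau_i^{max}/100$ are the
subject mass, age, height and per-DOF reference torques divided by their
maximum orders of magnitude, so all regressors are dimensionless and of
comparable scale. Age substitutes for aerobic capacity
($\dot VO_2max$), which is impractical to measure routinely. The strength
ratio $\tau^{max}_{knee}/\tilde\tau^{max}_{knee}$ — measured maximum
isometric knee extension over the population reference — linearly scales a
catalog of per-DOF reference torques, giving each subject a full-body
strength profile from one dynamometer number. The knee ratio is already
dimensionless and is used raw; only $\tilde\tau_i^{max}$ is divided by 100.

The package ships the published estimates of the ten weights
(`published_weights()`) and a 42-DOF reference-torque catalog per sex
(`default_dof_catalog()`). Only the male sagittal hip (240.1 N·m) and ankle
(151.5 N·m) entries are published values; all other entries are catalog
defaults assembled from typical adult strength magnitudes and flagged
`"catalog-default"` in the CSV, which users can edit. The reference knee
torque defaults to the estimation-group means (212.4 N·m male, 107.6 N·m
female); the female catalog scales the male entries by their ratio.

### A numerical note on published precision

The published weights are printed to three significant digits. At that
precision the subject factor of $h^{am}$ evaluates to about $-3\times10^{-7}$
for one light, short validation subject — a sign flip produced entirely by
rounding (a half-digit change in $w_3^{am}$ moves the factor by
$\pm7\times10^{-7}$). `heat_coefficients()` therefore clamps first factors
in $(-\text{tol}, 0)$ to zero, with `tol = 1e-6` — far below any
physiological heat-rate scale — and errors for genuine violations
(`tol = 0` restores strict behaviour).

## Estimation

Only time-averaged MEE is observable (indirect calorimetry), so the weights
are estimated by matching the model's stride-averaged rate to the measured
per-condition rate:

$$
\mathrm{error}(\mathbf w) = \frac{1}{2N}\sum_{k=1}^{N}
\Big(\bar E_{met,k} - \tfrac{1}{T_k}\int_{T_k}\dot E_{met}(t)\,dt\Big)^2 .
$$

As printed elsewhere this residual subtracts an energy from a rate; we
divide the integral by the stride duration so both terms are watts.

Constraints implement thermodynamic irreversibility:

* both factors of each coefficient non-negative (per subject, per DOF);
* net MEE per DOF non-negative at every sample,
  $\tau_i\dot q_i + h_i^{am}|\tau_i| + h_i^{sl}|\tau_i\dot q_i|\ge 0$
  (expended metabolic energy cannot be recharged by negative joint work);
* stride-average MEE within $[0, \dot VO_2max]$ when aerobic capacity is
  known (skipped with a warning otherwise).

`fit_mee()` solves this constrained nonlinear least-squares problem with a
seeded multistart augmented-Lagrangian method written for this package: the
inequality margins enter a smooth quadratic penalty with multiplier
updates, inner problems are solved by BFGS with analytic gradients, and the
ten weights are scaled internally by their orders of magnitude
($10^{-4},10^{-4},10^{-4},10^{-3},10^{3}$ for am;
$1,1,1,1,10^{-2}$ for sl) so the optimizer sees O(1) coordinates. The
net-MEE constraint is enforced per sample inside the penalty — on reduced
grids this is vectorised and cheap, and it keeps the penalty smooth,
which we prefer over aggregating to a per-DOF minimum during the solve;
the constraint report aggregates per subject and DOF for readability
(`mee_constraints(..., aggregate = FALSE)` gives the per-sample margins).
Because an active constraint can end a hair outside the feasible set after
a finite penalty loop, a monotone restoration step follows: the net-MEE and
first-factor margins are strictly increasing in the am/sl intercepts, so
the solution is pushed strictly inside along those directions with an
objective perturbation of the order of the violation itself
(typically $10^{-6}$ W). Defaults: 8 starts (zero, the published values,
and seeded perturbations of both), objective tolerance $10^{-10}$,
constraint tolerance $10^{-8}$, seed 20161228.

The ten weights are not always individually identifiable — within one
subject the am and sl regressors can be nearly collinear across speeds —
so recovery claims are made on predicted stride-average MEE, never on the
weight vector itself. In our synthetic studies eight estimation subjects
spanning both sexes make held-out predictions reproduce the ground truth
essentially exactly at zero noise; with fewer than about six subjects the
subject-factor map is underdetermined and held-out predictions drift even
when the training fit is exact.

## Calorimetry and gait processing

`vo2_to_watts()` converts per-minute gas exchange to watts either by the
gas-exchange formula $(16.58\,\dot VO_2 + 4.51\,\dot VCO_2)$ kJ/min (the
urinary-nitrogen term is dropped; urine is not collected in a treadmill
protocol) or by a fixed energy equivalent of oxygen (default 20.1 kJ/L).
The two agree within 3% for respiratory exchange ratios up to about 0.9
and within 5% at RER = 1; above 1 the aerobic assumption fails and a
warning is attached. The BMR is the mean of minutes 4–6 of a six-minute
quiet-sitting record; each five-minute walking condition is summarized by
the mean of its last three minutes.

Gait events come from a vertical-GRF threshold detector (20 N with 5 N
hysteresis, linear interpolation at crossings) or, without force channels,
a coarse ankle-velocity sign-change proxy. A stride runs from right heel
strike to the next right heel strike; double support spans heel strike of
one side to toe off of the other, and phase durations partition the stride
exactly. `synchronize_bilateral()` rebuilds a whole-body stride from
separately captured right and left strides by splitting the left stride at
the right heel strike it contains and resampling periodically onto the
right time base. Dimensionless speed uses
$Fr = \bar v/\sqrt{g\,l}$ with leg length $l = 0.53\,H$; the square-root
form is the standard convention and the only dimensionless reading.
COT–speed curves are fitted by least squares on the Laurent basis
$\{\bar v^{-1}, 1, \bar v\}$ — the minimal basis able to produce the
convex, interior-minimum shape of walking COT; the degree set is
configurable.

## The synthetic-data generator

`generate_dataset()` emulates the study conditions end to end: subjects
drawn from sex-specific truncated normals (males 1.83 ± 0.06 m,
87.9 ± 10.9 kg, 31 ± 6 yr, 212.4 ± 66.2 N·m; females 1.62 ± 0.07 m,
57.1 ± 10.0 kg, 32 ± 9 yr, 107.6 ± 35.7 N·m; ±3 SD truncation plus
physiological floors), five conditions at 70/85/100/115/130% of a
preferred speed (1.29 ± 0.11 m/s; stride length 1.48 ± 0.11 m at preferred
speed, scaling as $v^{0.5}$), a double-support fraction falling linearly
with speed from 34.9% to 22.1%, 120 Hz sampling, and measured stride
averages computed from the model under ground-truth weights with 3%
multiplicative Gaussian noise by default. The estimation/validation split
mirrors the study: half the validation subjects are unseen, half are
estimation subjects re-measured.

Trajectories are analytic: angles are 2–4 harmonic Fourier series of the
stride frequency (left channels are the right channels delayed by half a
period; one phase set is drawn per subject and reused across speeds, as a
person's gait pattern is), velocities are exact derivatives, and torques
are harmonic series scaled per DOF group by fractions of the subject's
scaled maximum torque (lower-limb sagittal 0.12, other lower-limb 0.06,
trunk 0.05, upper limb 0.04 of $\tau_i^{max}$; peak capped at
$0.8\,\tau_i^{max}$). Two deliberately mechanistic features shape the
energetics: harmonic torque amplitudes grow as $(v/v_{pref})^{1.4}$, giving
the classic $a + b\,v^2$-like rise of metabolic rate and hence a convex COT
curve with an interior minimum near the preferred speed; and Gaussian
torque-and-velocity bursts centred in the double-support windows (torque
0.45, angle 0.18 rad, scaling as $(v/v_{pref})^{0.6}$) emulate push-off, so
double support carries a larger share of metabolic energy than of time,
most strongly at slow speeds. These amplitude choices were fixed once,
targeting gross walking costs of roughly 3–4.5 W/kg at preferred speed for
an average subject.

Two feasibility screens keep the generated population inside the validity
region of the generating model: subjects are redrawn until (i) their heat
coefficients under the ground-truth weights are non-negative — with the
published three-digit weights about one in seven female draws would
otherwise land marginally outside — and (ii) $h^{sl} \ge 1$ at every DOF,
the sufficient condition for non-negative per-DOF net MEE under arbitrary
kinematics. Without (ii) the ground truth itself can violate the net-MEE
constraint on its own synthetic trials, which would make parameter
recovery ill-posed.

What the generator does **not** emulate: measured joint-angle waveforms
(harmonics are not physiological shapes), ground-reaction-force profiles
(square waves, used only to exercise event detection), kinematic
measurement noise (available as an option but off by default), within-
condition stride-to-stride variability, and any musculoskeletal redundancy
— torques are free curves, not the output of a dynamics model. Passing
tests therefore demonstrate internal consistency of the estimator and the
energetics pipeline under the model's own assumptions, not validity on
real motion-capture data.

## Numerical choices

* Integration: composite trapezoid on the native grid with linear
  interpolation at interval endpoints; time averages of periodic signals
  over whole periods are then exact for the harmonic components.
* The generator's speed ripple is a whole-period cosine, so the trapezoid
  mean of $v(t)$ equals the condition speed to machine precision.
* Reduced problem sizes used in the test-suite studies: 50 samples per
  stride for estimation studies (the closed-form sufficient statistics of
  the objective make the stride grid the only cost driver), 10–20 noise
  seeds for Monte-Carlo checks. These sizes were chosen to make the whole
  study reproducible on a laptop in minutes.
* Derivative checks of generated trajectories are made by central
  differences on a refined analytic grid, since finite differences on the
  native 120 Hz grid are limited by their own $O(h^2)$ truncation error,
  not by the generator.
* `fit_mee()` is deterministic given its seed; the generator restores the
  caller's RNG state.

## Worked example

```{r example, eval = FALSE}
cfg <- generator_config(seed = 42, n_subjects = 2, n_validation = 1,
                        samples_per_stride = 50, noise_sd = 0)
sim <- generate_dataset(cfg)
fit <- fit_mee(sim$estimation, mee_control(seed = 42, multistart = 2))
summary(fit)
validate_mee(fit$weights, sim$validation)
```

## Limitations

The heat coefficients are constants per DOF and subject — the separable
published form — although the underlying theory allows angle- and
velocity-dependence; the interface leaves a hook for state-dependent
coefficients. Muscle-level phenomena (tendon elasticity, eccentric-specific
heat laws, fatigue, sweating) are outside the model. The reference-torque
catalog beyond the two published entries is a documented default, not
measured data, and estimation quality on real data will depend on it only
through the strength-scaling term.
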