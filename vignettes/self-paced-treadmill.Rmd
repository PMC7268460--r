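---
title: "Methods: force-plate self-paced treadmill control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: force-plate self-paced treadmill control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models, parameters, and design choices behind
`selfpace`. The package has three parts: a state estimator and a speed
controller, which together form a self-pacing controller for
force-instrumented treadmills, and a virtual walker/treadmill simulator
that stands in for a human subject and a motion-capture reference so the
whole loop can be exercised and verified on a desk.

## Coordinate conventions

All positions are in the lab frame with `+y` the walker's forward
direction and the origin at the treadmill centre. The belt speed `v_tm` is
a magnitude; the belt surface moves in `-y`. Under this convention a foot
resting on the belt translates by `-∫ v_tm dt`, so the previous footstep's
position is reconstructed as its COP at contact *minus* the integral of
belt speed over the step. This sign is fixed by two self-consistency
requirements: a walker with zero lab drift must measure a step length
equal to the belt travel, and the control law's plus signs must act as
negative feedback (belt and walker speeds are oppositely signed in the lab
frame). Descriptions of the method that place the axis the other way word
this as "plus the integral"; the mechanics are identical.

## State estimator

The estimator state is `x = (p, v)`, the walker's fore-aft COM position
and velocity in the lab frame. Raw per-belt signals are conditioned by a
causal third-order Butterworth low-pass at 25 Hz. The COP is *not*
filtered directly: the ratio moment/force is ill-behaved when a belt is
unloaded, so the package filters the vertical force and the fore-aft
moment (`cop × f_z`, zero where the COP is invalid) separately and
re-forms the ratio, masking samples below a validity floor of 5% of body
weight. Contact detection runs on the filtered vertical force: a rising
edge through 20% of body weight declares a contact, and the belt re-arms
only after falling below 10% of body weight (hysteresis against chatter;
only the 20% rising threshold is prescribed by the method, the re-arm
level and the 0.2-s minimum step duration are package choices). If both
belts cross in the same sample the larger force wins and the other belt
stays suppressed until it re-arms.

Per tick (Δt = 0.001 s) the filter predicts with the measured
acceleration `a_mes = f_y/m`; per detected contact it forms the step
measurements

* `v̄_mes = (y_f1 − y_f0)/(t1 − t0) − v̄_tm`, with `v̄_tm` defined as the
  time average `∫v_tm dt / (t1 − t0)` so the identity between step length,
  belt travel, and lab drift is exact by construction, and
* `p̄_mes = (y_f1 + y_f0)/2`,

and corrects the state with gain `K = P(P + R)^{-1}` (identity observation
matrix). The innovation compares the measurements with the *per-step
means* of the estimated state, accumulated at every tick since the last
contact, while the correction is applied to the instantaneous state — the
method's defining once-per-footstep structure. The additive process term
is `σa²·B·Bᵀ` with `σa² = 2.9 (m/s²)²`; written with a scalar input noise
this is the only dimensionally consistent reading of the published
constants, and it equals the printed 2×2 process matrix exactly.

Numerical choices: the covariance is re-symmetrized (`(P+Pᵀ)/2`) after
every correction; the 2×2 gain is formed by a cofactor inverse in the
tick loop (algebraically identical to `solve()`, which the exported
single-step functions use); accumulators are reset at *every* detected
contact, accepted or rejected, and the most recent detection always
becomes the next step's reference. Steps longer than 1.2 s (belt
crossovers merge two contacts into one interval) or shorter than 0.2 s
skip the correction entirely, leaving the state continuous. No correction
happens before the second detected contact; the filter initializes at
`p = v = 0` with the published `P0`, which causes a documented transient
over the first few steps (see "Evaluation windows").

## Speed controller

Once per *accepted* footstep the controller issues

```
v_tm,tgt = v̄_tm + G_v·v̄_KF + G_p·(p̄_KF − p0),   G_v = 0.25, G_p = 0.1 s⁻¹
a_tm,tgt = (v_tm,tgt − v̄_tm)/Δt_tgt,             Δt_tgt = 0.5 s
```

using the step-mean estimates and the measured mean belt speed of the
completed step (not the previously commanded target — the belt may still
be ramping). Gains of 1 would fully match speed and recenter in one
second; the published lower gains trade responsiveness for comfort.
Rejected steps issue no command (their step means are unreliable), and the
belt continues executing its previous ramp. Two clamps protect the
hardware and are package choices the method leaves open: speed in
[0, 2.5] m/s (the belt never reverses) and |acceleration| ≤ 2 m/s².
The baseline `p0` defaults to 0 and is normally calibrated with
`calibrate_p0()` as the mean estimated position over a fixed-speed
familiarization window. Self-paced trials start at `v_start = 0.8` m/s.

## Virtual walker and treadmill

The simulator is deliberately minimal: its purpose is physical
consistency, not biomechanical realism.

* **COM kinematics.** Within each step the walker holds a constant
  belt-relative speed plus a zero-mean sinusoidal oscillation
  (`osc_amp = 0.15` m/s, one cycle per step) emulating the natural
  within-step speed fluctuation of gait. The lab velocity is belt-relative
  speed minus belt speed; the total fore-aft force is *exactly* mass times
  the discrete COM acceleration, so force integration reproduces the COM
  trajectory to machine precision (the load-bearing invariant of the test
  suite).
* **Steps.** Step duration follows `T = c0 − c1·v` (`c0 = 0.8` s,
  `c1 = 0.2` s²/m, floored at 0.3 s) — a plausible linear cadence law; the
  coefficients are package choices, not fitted claims. Step length is
  `v·T`; feet land alternately on the two belts, placed symmetrically
  about the COM, and ride the belt after placement.
* **Vertical load.** Raised-cosine transfer between consecutive feet over
  a double-support window of 0.2·T; belt forces sum to body weight
  outside the first loading ramp. Vertical COM dynamics are omitted —
  `f_z` carries no information the estimator uses beyond contact timing.
* **Behaviour.** The walker steers toward a command speed plus a weak
  station-keeping correction `k_station·(station − p)` with
  `k_station = 0.1 s⁻¹`, standing in for human position control on the
  deck and giving the closed loop a unique equilibrium. In scripted
  (manually controlled belt) trials the command is the belt speed itself,
  as a human matches an imposed speed; in closed-loop trials it is the
  walker's preferred speed.
* **Noise** enters at the sensor level so the estimator's `R` keeps its
  meaning: white noise on the fore-aft force channels (default
  0.1 m/s² expressed as acceleration), on each belt's COP (default
  0.024 m), and jitter on step timing (default 0.01 s). Because the
  estimator reads the COP through the 25-Hz filter, white per-sample COP
  noise reaches the step measurements attenuated by the filter's
  white-noise gain; `calibrate_cop_noise()` computes, in closed form, the
  per-sample sigma for which the per-step position scatter equals a
  target (e.g. the square root of the published `R` diagonal). Crossovers
  can be injected deterministically (`crossover_steps`,
  `inject_crossover()`) or stochastically (`crossover_prob`).

What the simulator does *not* emulate — and what passing tests therefore
do not establish about real data: heel-to-toe COP progression within
stance, vertical dynamics and impact transients, asymmetric or impaired
gait, mediolateral motion, and human responses to visual context. The
simulator's step measurements are exact at steady speed by construction;
real force plates add structured (non-white) noise.

## Evaluation windows and known biases

Two systematic effects matter when comparing estimates with ground truth:

* **COP-at-detection offset.** Contacts are detected ~40–50 ms after
  touchdown (loading ramp plus filter delay), by which time the foot has
  ridden the belt backwards by roughly `v_tm × 50 ms`. The position
  measurement therefore sits a few centimetres behind the COM — a
  constant offset at steady speed. This is inherent to the method (its
  position estimate is explicitly *relative*), is removed by the
  offset-corrected RMS metric and absorbed by `p0` calibration, but makes
  the *true* COM settle slightly ahead of `p0` in closed loop; the
  controller regulates the estimated position. During belt accelerations
  the offset varies with speed, which dominates the position RMS of
  staircase trials.
* **Warm-up transient.** The filter initializes at zero state, so the
  first correction absorbs the full position offset (and, through the
  gain's cross terms, perturbs the speed estimate) over the first few
  steps. Tracking-accuracy evaluations therefore use recording windows
  that begin with the estimator already running (the package uses a 6-s
  warm-up), mirroring treadmill practice where measurement starts after
  the subject is walking. The initialize-at-zero behaviour itself is
  retained as published.

## Evaluation metrics

`rms_step_errors()` computes per-step RMS speed error and offset-corrected
RMS position error. `convergence_time()` builds a band from the mean ± 1
SD of the walking speed over the last 20% of the trial and reports first
entry; `convergence_distance()` does the same over the final 30 m of
cumulative distance. A degenerate band (zero tail SD) is widened by
ε = 10⁻³ m/s so entry is well-defined. The walking-speed series is the
per-step belt speed plus estimated lab speed, held between contacts —
per-step rather than instantaneous, matching the controller's own
once-per-footstep philosophy. `section_speeds()` measures distance/time
over 10-m sections; `linear_fit_corr()` and `intra_subject_sd()` (sample
SD, n−1) support cross-test comparisons of self-selected speeds.

## Verification strategy

The test suite checks the estimator against independent oracles rather
than against itself: a batch joint-Gaussian conditional-mean solver over
the stacked latent variables (on instances with one prediction per
correction, where the once-per-footstep recursion coincides with the
exact sequential solution — with multi-tick windows the step-mean
innovation is a heuristic, and no exact batch equivalent exists), a
closed-form matrix-power sum for covariance propagation, a cofactor-
formula 2×2 inverse for the gain, and an independently coded online loop
replayed against the offline estimator. Closed-loop properties (start at
0.8 m/s, convergence to the walker's preferred speed, equilibrium of the
control law, crossover rejection) are asserted on deterministic
(noise-free) trials of 30–60 s at 1000 Hz; stochastic properties use
fixed-seed batches of 20–100 runs. These problem sizes keep the whole
suite around a minute of CPU while leaving every property statistically
unambiguous.

## Limitations

The controller requires clean per-belt loading; it rejects but does not
recover crossover steps (a combined-COP estimator is the natural
extension). Gains are fixed (no scheduling), the belt model is a pure
rate-limited ramp, and running, incline, and split-belt asymmetric
control are out of scope.
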