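---
title: "Models and methods behind hitd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hitd}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hitd)
```

# The functional head-impulse paradigm

During a passive, high-acceleration head thrust the angular
vestibulo-ocular reflex (aVOR) is the only mechanism fast enough to
stabilize gaze; pursuit and prediction are too slow, and with passive
impulses efference copy is unavailable. The functional test flashes a
Landolt C on screen the instant the thrust is recognized and asks whether
the subject can report the gap orientation. The chain that turns raw
sensor traces into that judgment — and back, in simulation — is what this
package implements. This vignette records the models, the parameter
choices, and the numerical decisions, in the spirit of a methods section.

# Coordinate and sign conventions

* Time is in seconds from recording start; sample index 0-based in the
  time arithmetic (`t[k] = t0 + k/fs`); windows are half-open
  `[t1, t2)` except the VOR gain window, which includes both landmark
  samples.
* Yaw is viewed from above: counterclockwise (CCW) head rotation is
  positive (right-hand rule about earth-up); CW is negative. A trial's
  `direction` field carries the label, signed series carry the sign.
* The accelerometer measures specific force; at rest it points along
  earth-up. `estimate_gravity()` averages it over the first quiescent
  ≥ 0.2 s (gyro magnitude < 5 °/s, ≥ 10 samples) and normalizes; the
  projection of the gyro onto that axis is the earth-vertical yaw
  velocity. Because impulses contaminate the accelerometer with inertial
  components, gravity is calibrated once from the pre-test baseline, not
  tracked. The projection is exactly invariant to the sensor mounting
  (a ~30° nose-down pitch is typical, aligning the horizontal canals with
  the rotation plane), which the simulator exercises by emitting its
  traces in a pitched sensor frame.
* Eye position is eye-in-head, in degrees; blinks are `NA` and each
  operation states its `NA` policy (gain windows containing `NA` exclude
  the impulse; the eye-velocity filter dilates `NA` spans by its support).

# Trigger, timing, and the photodiode audit

The online trigger is the conjunction, at a single sample, of
`|yaw velocity| > 10 °/s` and `|yaw acceleration| > 300 °/s²`, with the
acceleration defined as the causal backward difference
`a[k] = (v[k] − v[k−1])·fs` (no filtering — this series emulates the
real-time path). After a trigger, re-arming requires the velocity to fall
back below threshold plus a 0.5 s refractory, preventing double triggers
within one thrust. Raising either threshold can only delay or remove a
thrust's trigger, never create one; note that the trigger *time* moves
with the thresholds, so this monotonicity is a per-thrust property, not a
subset relation on times.

Stimulus timing is only expressible in frames: the nominal onset is the
first vsync boundary at or after `trigger + delay_frames·frame_duration`,
the offset `duration_frames` later (e.g., six frames at 75 Hz = 80 ms).
What actually happened is audited from the photodiode channel, binarized
at mid-range with ±10% hysteresis; edge times are interpolated to the
mid-range crossing between the two straddling samples, giving sub-sample
accuracy (sensor rise time is microseconds and is neglected). A stimulus
still on screen after the head has stopped (`valid_during_motion = FALSE`)
is flagged, because a momentarily stable retina can rescue an otherwise
unreadable trial.

# Impulse landmarks and VOR gain

Within 0.4 s after a trigger, the velocity peak is the largest `|v|`
sample; onset is the last upward crossing of the velocity threshold
before it; the end is the first return below threshold after it. The
impulse acceleration is the magnitude of the least-squares line through
the **five velocity samples centered on the peak-acceleration sample**.
Two numerical refinements matter at 220 Hz:

* the backward difference estimates the derivative at `k − 1/2`, so the
  raw argmax of `|a|` is offset by about half a sample; the peak is
  relocated by parabolic interpolation and the five-sample window is then
  centered where the fitted slope magnitude is maximal (the slope of a
  smooth velocity profile is maximal when the window is centered on the
  inflection);
* landmark detection runs on a zero-phase 30 Hz low-passed copy of the
  yaw velocity (mirror-padded Butterworth, order 2 each way) so that peak
  picking is stable under gyro noise; the same filtered series feeds the
  five-sample fit, keeping one definition end-to-end.

Even so, a line through five samples of a curved profile underestimates
the true peak slope by ≈ `0.57·(2π/(T·fs))²` — about 2% for a 160 ms
impulse at 220 Hz. This bias is inherent to the five-sample definition
and is why recovery tolerances below ~2.5% per impulse are not meaningful
at this sampling rate.

VOR gain is `mean(−eye velocity)/mean(head velocity)` over the interval
from peak head acceleration to peak head velocity (≈ T/4 ≈ 35–55 ms for
the simulated profiles, consistent with the 40 ± 8 ms such intervals span
in practice). The negation makes compensatory responses positive;
anti-compensatory responses come out negative and are reported, never
clipped. Windows with `|mean head velocity| < 1 °/s` are refused as
degenerate. Covert saccades are *not* excised from the gain window — the
window usually ends before the ~100 ms saccade latency — but each
impulse's saccade inventory lets a sensitivity analysis drop contaminated
impulses.

# Binning, the 5/8 rule, planning, classification

Bins are half-open on the left, `(b − 1000, b]`, so a boundary
acceleration falls in the lower bin (the convention had to be fixed one
way; it is surfaced in `assign_bin()`). Per (direction, bin) cell the
report counts thrusts, correct answers (no-response trials are excluded
from the percent-correct denominator and counted separately), and gain
statistics; the required thrust count escalates from 5 to 8 as soon as
the cell contains a reading error. The planner's from-scratch minimum is
`bins × directions × 5`: 60 for the full 2000–7000 layout, 40 restricted
to 3000–6000.

`classify_performance()` is an explicitly labeled stand-in: a one-sided
exact binomial test of each cell's correct count against a configurable
control correct-rate (default 0.9, α = 0.05). It is not a validated
control-population procedure; its parameters are arguments, not hidden
constants, and its verdicts should be read as screening flags.

# Gaze, retinal slip, saccades

Gaze is head displacement (trapezoidal integral of yaw velocity from
impulse onset) plus eye-in-head displacement, zeroed at onset. Retinal
slip is defined as the *forward difference* of gaze,
`slip[k] = (gaze[k+1] − gaze[k])·fs`: with this definition the
rectangle-rule integral of slip telescopes exactly to the gaze change
over any sub-window, so slip and gaze are mutually consistent to machine
precision — a property worth more, for a quantity that gets integrated
over stimulus windows, than the cosmetic smoothness of a filtered
derivative (an optional low-pass is available in `mean_abs_slip()` for
noisy recordings).

Saccades are detected on the residual `eye velocity + g·head velocity`,
which removes the slow phase so that a low-gain response is not itself
"saccadic". For `g` the detector uses the *median* gain of the impulse's
direction rather than the impulse's own gain: a covert saccade inside an
impulse's gain window inflates that impulse's measured gain, and the
inflated gain would offset the residual and mask the very saccade to be
detected. Candidate spans exceed 60 °/s for ≥ 3 samples, are merged when
closer than 20 ms, and are extended outward to a 5 °/s floor so the
reported onset approaches the true start of the movement (all three
values configurable; they are conventional video-HIT-scale choices).
Labels: **covert** if the saccade onset is at or before the head-movement
end (velocity back below threshold), **overt** after it; saccades
straddling the boundary are labeled by onset and flagged. The boundary
sample itself is labeled covert, matching the detection's half-sample
late bias; either convention is defensible at 4.5 ms resolution.

# Optotype, QUEST, psychometric fit

The Landolt gap subtends `10^logMAR` arcminutes:
`gap = distance·tan(10^logMAR/60°)`, diameter `= 5·gap`. The printed
form of this relation in the source material is typographically garbled;
the implementation uses the standard Landolt relation, which is the only
reading consistent with the 1/5-gap geometry. The gap-based (rather than
full-optotype-based) angle is the standard convention and the one
adopted.

The static-acuity staircase starts at 1.0 logMAR and terminates after
exactly 20 trials. The posterior over a 0–2 logMAR grid (0.01 steps)
starts from a Gaussian prior (mean 1.0, SD 1.0) and is multiplied by a
Weibull psychometric likelihood (slope β = 3.5, guess 0.125, lapse 0.01)
after each trial; the next level is the posterior *mode*, the final
estimate the posterior *mean* — mode placement is the classic adaptive
choice, the mean is the minimum-variance summary once testing stops.
These hyperparameters are the conventional defaults of the Bayesian
adaptive method; only the start value and trial count are dictated by
the protocol.

`fit_psychometric()` fits, by binomial maximum likelihood (Nelder–Mead on
midpoint, log-slope, and a bounded lapse ∈ [0, 0.05]), a logistic with
the lower asymptote fixed at chance. All-correct or all-at-chance data
leave the threshold unidentified: the fit returns `converged = FALSE`
with an explanatory flag instead of a spurious estimate.

# What the simulator emulates — and what it does not

`simulate_session()` generates the full recording: head impulses as
raised-cosine velocity bumps `v(t) = (V/2)(1 − cos 2πt/T)` on `[0, T]`
with `T = πV/A`, so the peak acceleration is exactly `A` (at `t = T/4`)
and the peak velocity exactly `V` (at `T/2`) — closed forms that make
every landmark analytically checkable. Durations are drawn uniformly in
140–220 ms (acceleration-to-velocity-peak intervals of 35–55 ms, the
physiological band for manually imposed thrusts), giving
`V = AT/π` clamped to 80–400 °/s. Each impulse is preceded by ≥ 1 s of
rest and followed by a slow raised-cosine return to center whose peak
acceleration stays far below the 300 °/s² trigger threshold, so sessions
stay bounded without spurious triggers.

The eye model composes a slow phase (−gain × head velocity, gain per
direction), probabilistic covert saccades (latency truncated-normal,
floor 50 ms, default mean 100 ms) correcting a fraction (default 0.8) of
the instantaneous gaze error, overt saccades after head end correcting
the full residual, and a refixation between trials. Saccades follow a
minimum-jerk position profile of duration 25 ms + 2.5 ms/deg. A dead
zone (default 2°) suppresses corrective saccades for tiny gaze errors.
Reading follows a logistic in mean absolute retinal slip over the
stimulus window: `p = 0.125 + (1 − 0.125 − lapse)·logistic(−(s −
s50)/σ)` with defaults `s50 = 20 °/s`, `σ = 5 °/s` — a stand-in for the
unknown true slip-to-legibility relation (the scientific question the
instrument exists to study), with every parameter exposed.

Sensor noise is white: gyro 0.5 °/s per axis by default, eye noise
specified as white *velocity* noise (default 2 °/s) integrated into the
position channel, accelerometer 0.05 m/s², photodiode 0.02 V. Display
latency is truncated-normal (default 25 ± 8 ms) then vsync-quantized.

Not modeled, deliberately: impulse asymmetry and head overshoot;
pursuit/predictive eye movements; torsion and vergence; blinks (insert
`NA` spans manually to exercise those paths); video-oculography pixel
artifacts; and any fitting of the simulator to real patient traces.
Consequently, passing tests show the *analysis chain is correct on its
own generative model* — internal consistency, estimator accuracy,
labeling fidelity — not that the pipeline is robust to every artifact of
real recordings.

# Test problem sizes and determinism

The suite exercises: acceleration recovery over 3 impulses per
(bin, direction) noise-free and 5 at gyro noise 2 °/s; covert/overt
labeling on ~200 impulses with 3–12° saccades at 80–250 ms latencies
(noise-free, the structural regime for which ground-truth agreement ≥98%
is meaningful — under sensor noise the boundary cases are genuinely
ambiguous at one-sample resolution); gain recovery on 60 impulses at
noise SD 2 °/s; 200 seeded QUEST runs; and byte-identical session
round-trips. All randomness flows through R's RNG under fixed seeds, so
every result in the suite and in `scripts/acceptance.R` is exactly
reproducible.

# Known limitations

* The classifier is a stand-in (see above), not a normative instrument.
* The five-sample acceleration slope inherits a ~2% discretization bias
  at 220 Hz; comparisons across devices with different sampling rates
  should account for it.
* Covert saccades inside the gain window bias that impulse's gain upward;
  the package flags but does not correct this, by design.
* The no-immediate-repeat constraint on optotype orientations slightly
  anti-correlates consecutive trials; it can be disabled
  (`next_orientation(..., no_repeat = FALSE)`).
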