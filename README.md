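# hitd — functional head impulse testing, simulated and analyzed

Functional testing of the angular vestibulo-ocular reflex (VOR) asks a
simple question: while the head is being thrust sideways at high angular
acceleration, can the subject still read? A healthy VOR counter-rotates the
eyes with gain

    g = eye velocity / head velocity ≈ 1,

keeping the image of the world still on the retina. A deficient VOR (e.g.,
after vestibular neuritis) lets the image slip; even a few degrees per
second of retinal slip degrade acuity, so a briefly flashed optotype goes
unread. The head impulse testing device (HITD) paradigm exploits this: a
Landolt C (a ring whose gap is 1/5 of its diameter, shown at one of eight
45° orientations, chance level 1/8) is flashed on screen the moment head
angular velocity exceeds 10 °/s while angular acceleration exceeds
300 °/s², and the subject reports the gap orientation. Thrusts are
classified into 1000 °/s²-wide acceleration bins (upper bounds
2000–7000 °/s²) per rotation direction, with at least five thrusts per bin
(eight once a reading error occurs there) — 60 impulses minimum for the
full layout, 40 for the clinically relevant 3000–6000 °/s² range.

This package is a research toolkit for that paradigm, aimed at vestibular
and oculomotor researchers. It provides:

- **a ground-truth-annotated simulator** (`simulate_session()`): raised-cosine
  head impulses with exact closed-form peak acceleration, direction-specific
  slow-phase gains, covert (during head movement) and overt (after it)
  corrective saccades, a vsync-quantized display with photodiode feedback,
  and a logistic slip-to-legibility reading model;
- **the full analysis chain** (`analyze_session()`): gravity-referenced yaw
  velocity from a head-mounted IMU, online-style thrust detection, impulse
  segmentation with the five-sample acceleration slope, VOR gain over the
  peak-acceleration→peak-velocity interval, acceleration binning with
  per-bin reading performance and an impairment classifier, photodiode
  timing audit, gaze/retinal-slip reconstruction, saccade detection and
  covert/overt labeling, longitudinal follow-up comparison
  (`followup_compare()`);
- **psychophysics**: Landolt C sizing from logMAR and viewing distance
  (`optotype_size()`), a 20-trial QUEST staircase for static visual acuity
  (`quest_run()`), and maximum-likelihood psychometric fitting with the
  chance floor fixed at 0.125 (`fit_psychometric()`);
- **a plain-text session format** (`write_session()` / `read_session()`) and
  report generation (`run_report()`), plus a thin CLI at `inst/cli/hitd`.

## Worked example

Simulate a left-deficit patient (ipsilesional gain 0.15, contralesional
0.75) and run the standard end-of-examination report:

```r
library(hitd)
patient <- subject_model(gain_cw = 0.15, gain_ccw = 0.75,
                         covert_prob = 0.4, overt_prob = 0.8)
sim <- simulate_session(subject = patient, seed = 42)
run_report(sim$session)
```

```
=== Functional head-impulse test report ===
Impulses: 60 (0 excluded)

Per-bin reading performance:
 direction bin_upper_bound n_thrusts n_correct n_no_response percent_correct
        CW            2000         5         0             0               0
       CCW            2000         4         3             0              75
        CW            3000         5         0             0               0
       CCW            3000         5         0             0               0
        CW            4000         5         1             0              20
       CCW            4000         6         0             0               0
        CW            5000         6         3             0              50
       CCW            5000         4         0             0               0
        CW            6000         4         1             0              25
       CCW            6000         5         0             0               0
        CW            7000         5         0             0               0
       CCW            7000         5         0             0               0
 gain_mean gain_sd required_thrusts  p_value      verdict
     0.186   0.073                8 0.000010     impaired
     0.751   0.015                8 0.344000 not impaired
     ...

Stimulus timing: delay 31.8 +/- 8.0 ms, duration 80.1 +/- 2.2 ms (60 measured, 0 missing)
  ** 2 stimulus/stimuli persisted past the end of head motion

Saccades: 17 covert, 36 overt
```

Reading the output: every CW (ipsilesional) bin shows a gain near 0.15 and
reading at or near the 12.5% chance floor, so the binomial classifier flags
those cells as impaired. Toward the healthy side the gain sits at 0.75 —
enough to read at the lowest accelerations (75% correct in the 2000 °/s²
bin) but failing at higher ones, where residual retinal slip grows: the
contralesional degradation with increasing acceleration that unilateral
patients show. The timing audit measures the true optotype delay/duration
from the photodiode channel and flags two stimuli that were still on screen
after the head had stopped — trials a cautious analyst should discount,
since a momentarily stable retina can allow a correct answer. `plot()` on
the report draws the standard four panels (overlaid head/eye velocities per
direction, gain vs. peak acceleration with wrong-reading markers, per-bin
percent correct).

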