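# tapsync

Analysis of pacing–continuation finger-tapping experiments in R.

Sensorimotor-synchronization studies ask participants to tap along with a
metronome (the *pacing* phase) and then keep tapping at the same tempo after
the tone stops (the *continuation* phase), either on the beat (*synchronized*)
or midway between beats (*syncopated*). A further, easily overlooked choice is
the study design: all trials of one tapping mode in a row (*blocked*) or
switching mode every trial (*alternating*). `tapsync` provides the full
analysis chain for such experiments — and, because raw tapping datasets are
rarely public, a calibrated simulator so every stage is testable end to end.

The package is aimed at researchers analysing tap-event data (one row per
tap: participant, design, mode, phase, trial, cycle, tap time, target time)
and at methodologists studying how design context affects rhythmic
entrainment.

## What it computes

**Timing statistics.** Signed asynchrony `a_i = tap_i − target_i` (negative =
anticipation; targets are beats for synchronized tapping, inter-beat midpoints
for syncopated tapping, extrapolated past metronome offset so a *virtual*
asynchrony exists in continuation) and the inter-response interval
`IRI_i = tap_{i+1} − tap_i` over consecutive cycles. A constant device
registration delay (25 ms by default) is removed first.

**Preprocessing.** Tukey-fence outlier rejection (`[Q1 − 1.5·IQR,
Q3 + 1.5·IQR]` within condition cells) and bootstrap balancing of every
trial-phase block to a constant size (m = 5), yielding one observation per
trial-phase.

**Inference.** OLS multiple regression of the trial-phase means on mode,
phase and design (all two-way interactions), Type-III F tests with partial
η², Tukey HSD pairwise contrasts, and post-hoc power of the overall F test
from the noncentral-F distribution (`ncp = f²·n` for Cohen's f).

**Trend turning points.** Cycle-averaged trends (participants-then-grand
mean) are fit with a cubic smoothing spline (GCV-chosen smoothing); the local
maxima of its second derivative are the *turning points* — the times at which
the behavioral trend accelerates, e.g. when the metronome stops.

**Causal effect of study design.** A two-group, two-period
difference-in-differences regression
`Y = β₀ + β₁·time + β₂·group + β₃·time×group + ε`
with the block design as control and pacing as the pre period; under parallel
trends β₃ is the causal effect of the alternating design on entrainment.

## Worked example

The scripts under `analysis/` run the whole workflow on a simulated cohort
matching the paradigm's structure (23 participants: 10 blocked, 13
alternating; 20 trials of 27 cycles at 1 Hz):

```sh
Rscript analysis/01_simulate.R           # writes results/sessions.csv
Rscript analysis/02_descriptives.R
Rscript analysis/03_regression.R
Rscript analysis/04_trend_turning_points.R
Rscript analysis/05_causal_did.R
```

`02_descriptives.R` prints the per-condition table; the simulated blocked
group shows the classic negative mean asynchrony in pacing and inflated,
positive-drifting asynchrony in continuation:

```
       design         mode        phase    n mean_ms  sd_ms
5     blocked synchronized continuation 1190  31.363 104.28
6     blocked synchronized       pacing 1490 -34.348  81.94
```

`03_regression.R` fits the multiple regression of mean asynchrony
(R² = 0.30, overall F(6, 913) = 65.96) and finds the dominant phase effect
alongside a clear design effect:

```
   term df sum_sq       f        p partial_eta_sq
  phase  1 913948 313.349 1.66e-60       0.255514
 design  1 175968  60.331 2.15e-14       0.061984
```

`04_trend_turning_points.R` locates the trend turning points: the blocked
group's asynchrony trend turns exactly at continuation onset, the alternating
group's before it —

```
asynchrony / alternating design: primary turning point at 11 s
asynchrony / blocked design:     primary turning point at 15 s
```

`05_causal_did.R` estimates the causal effect of the alternating design on
mean asynchrony (β₃ = 13.89 ms, SE 7.19) and reports the standard DID table
with residual kurtosis/skewness diagnostics.

Equivalently, `run_pipeline(run_config(...))` produces the complete artifact
bundle (CSV tables, turning-point JSON, config snapshot and manifest) in one
call.

## Package layout

- `R/` — task design, simulator, metrics, preprocessing, inference, growth
  curve, DID, I/O and pipeline.
- `analysis/` — the numbered workflow drivers shown above.
- `tests/testthat/` — unit, property and end-to-end suites.
- `vignettes/tapping-timing-analysis.Rmd` — the methods vignette (model,
  calibration, numerical choices, limitations).
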