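---
title: "Methods: timing analysis of pacing–continuation tapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: timing analysis of pacing–continuation tapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tapsync)
```

## The paradigm and its encoding

`tapsync` analyses synchronization/syncopation–continuation finger-tapping
sessions. Each trial has a metronome phase (*pacing*: 15 cycles at 1 Hz by
default) followed by an unpaced phase (*continuation*: 12 cycles); tapping is
either on the beat (*synchronized*) or at the inter-beat midpoint
(*syncopated*); and a participant's 20 trials (10 per mode) are ordered
either *blocked* by mode or *alternating* every trial. Cycle indices are
0-based with the first beat at 0 ms, so cycle $i$ has its nominal target at
$i\,T$ (synchronized) or $(i + \tfrac12)\,T$ (syncopated), and with $T = 1$ s
the continuation phase begins at the 15 s cycle position. All times are
handled internally in milliseconds; trend outputs convert cycle positions to
seconds, because the timing statistics are conventionally reported in ms and
turning points in s.

Two conventions deserve explicit statement:

- **Sign of asynchrony.** Asynchrony is uniformly $tap - target$, so negative
  always means anticipation. The syncopated ("virtual") asynchrony uses the
  midpoint target in the same orientation — some write-ups orient the
  syncopated difference the other way round, which would flip the sign and
  break the anticipation-is-negative reading.
- **Continuation targets.** Virtual targets after metronome offset continue
  the *nominal* grid ($i\,T$ from trial onset), not a grid re-anchored to the
  participant's last tap. Re-anchoring would absorb exactly the drift the
  continuation analysis is supposed to measure.

The alternation granularity (every trial, rather than small sets of trials)
and the absence of any warm-up-cycle exclusion are deliberate defaults; both
are exposed (`trial_schedule()` is driven entirely by the design object, and
any cycle-range filter can be applied to the tidy tap table before analysis).

## The synthetic-data generator

No public tap-level dataset accompanies this paradigm, so the package ships
a generator whose output has the statistical structure the analysis assumes.
It is deliberately minimal — two mechanisms, a few degradations:

- **Pacing** taps are anchored to their targets:
  $tap_i = target_i + \mu + \varepsilon_i$, $\varepsilon_i \sim N(0,
  \sigma_p^2)$. Default $\mu = -35$ ms emulates the negative mean asynchrony
  of paced tapping; $\sigma_p = 50$ ms is a realistic per-tap jitter at 1 Hz.
- **Continuation** taps accumulate intervals from the last paced tap:
  $I_k = T + d_k + \eta_k$, $\eta_k \sim N(0, \sigma_{tk}^2)$, so asynchrony
  performs a random walk (variance grows linearly in cycles) with linear
  drift. Default $\sigma_{tk} = 25$ ms is a conventional internal-timekeeper
  scale. The first unpaced interval is drift-free ($d_1 = 0$,
  $d_{k \ge 2} = 8.9$ ms): the tap immediately after offset still reproduces
  the just-heard period, which places the trend's slope change exactly at the
  continuation-onset cycle and gives a mean continuation-minus-pacing
  asynchrony increase of $5.5 \times 8.9 \approx 49$ ms over 12 cycles.
- **Alternating-design degradation** (preset `params_alternating()`): a
  +23 ms bias on trials following a mode switch, plus a linear pacing-bias
  ramp (5 ms/cycle) starting 10 s into the trial — an *anticipatory*
  breakdown of entrainment that moves the trend's turning point before
  metronome offset, as alternating designs show empirically.
- **Corruption**: taps dropped with probability 0.01 and gross errors
  (deviation × 8) with probability 0.02, so the outlier filter and
  missing-data accounting have realistic work to do (a few events per
  condition and participant).

Reproducibility is structural: each participant's sub-seed is a fixed
arithmetic function of the master seed and their global index, so cohorts are
bit-reproducible and adding participants never reshuffles earlier ones.
Parameter sets whose systematic pacing deviation could reach half a period
are rejected outright, since cycle attribution would become meaningless.

**What the generator does not emulate:** learning or fatigue across trials,
participant-level heterogeneity beyond an optional Gaussian bias offset
(`participant_bias_sd`, default off — the real between-subject structure is
unknown), autocorrelated pacing errors (real asynchronies show lag-1
negative correlation from phase correction), and any dependence of misses on
condition. Passing tests therefore demonstrate that the *estimators* behave
as specified under a plausible data-generating process — not that real
tapping data satisfy that process.

## Preprocessing

Outliers are removed by Tukey fences $[Q_1 - k\,\mathrm{IQR},\;
Q_3 + k\,\mathrm{IQR}]$ with $k = 1.5$; quartiles use linear interpolation
between order statistics (type-7), which is what the hand-oracle tests
reproduce. The phrase "1.5 times the IQR" is occasionally read as comparing
observations to $1.5\,\mathrm{IQR}$ itself; that reading is scale-broken for
signed asynchronies (a −40 ms anticipation is not an outlier because the IQR
is 30), so the standard fences are used. Fences are computed within
participant × design × mode × phase cells for the inference path; groups
with fewer than four values pass through with a warning rather than being
filtered on meaningless quartiles.

Balancing then resamples every participant × trial × phase block **with
replacement** (it is a bootstrap) to exactly $m = 5$ values. The "constant
sample size" could also be read as trials per condition; the trial-phase
block is used because the downstream observation unit is the trial-phase
mean, and balancing below that level equalizes each mean's pedigree. The
resampling seed is part of the run configuration and recorded in the config
snapshot.

The observation unit for all regressions is the **trial-phase mean** after
this preprocessing: "mean asynchrony" as an outcome refers to a trial's
phase average, and using per-tap observations would only multiply
pseudo-replication.

## Regression, contrasts and power

The multiple regression of a timing outcome on mode, phase and design uses
dummy coding with reference levels synchronized / pacing / blocked and, by
default, all two-way interactions (which interactions enter a "full model"
is otherwise underdetermined; the choice is exposed via
`regression_input(interactions = FALSE)`). Factors with a single observed
level — e.g. design in a one-group cohort — are dropped from the formula
rather than left to produce a rank-deficient fit. Effect tests are Type-III
(marginal) F tests computed under sum-to-zero contrasts via `car::Anova`,
with partial $\eta^2 = SS_{effect}/(SS_{effect} + SS_{error})$. Degrees of
freedom are always computed from the actual design matrix; published tapping
studies sometimes print a fixed df pair regardless of the observation unit,
and no attempt is made to reproduce such values.

Tukey HSD contrasts use the studentized-range distribution (`stats::aov` +
`TukeyHSD`); the test suite pins this to two independent oracles — the
$q = t\sqrt{2}$ two-group identity and direct numerical integration of the
studentized-range CDF.

Post-hoc power of the overall F test is
$P\{F'_{k,\,n-k-1}(\lambda) > F^{crit}_{k,\,n-k-1,\,\alpha}\}$ with
$\lambda = f^2 n$ for Cohen's $f$. The conventional benchmark values
$f = 0.14 / 0.39 / 0.59$ at $n = 23$, $k = 3$, $\alpha = .05$ give powers of
0.073 / 0.263 / 0.557. Published power numbers for this design computed with
GUI tools can differ (exact $\lambda$ and df conventions vary across
software); the noncentral-F contract above, verified against Monte-Carlo
simulation of actual regression F tests, is the package's specification.

## Growth-curve model and turning points

Cycle-averaged trends are built participants-then-grand-mean: the statistic
is averaged across trials within participant at each cycle position, then
across participants (so each participant contributes equally regardless of
surviving tap counts). Before averaging, gross errors are rejected with the
same Tukey rule but within participant × design × mode × phase × **cycle**
cells: including the cycle position keeps the systematic within-phase drift
— the very signal the growth model fits — out of the outlier criterion.

The trend is fit with a cubic smoothing spline. Pure interpolation of a
noisy 27-point series makes the second derivative oscillate uselessly, so
GCV-chosen smoothing is the default, with two handles: `smoothing = 0`
requests exact natural-cubic interpolation, any positive value is passed
through as `spar`. One numerical guard matters: unconstrained GCV on short
series occasionally selects a *negative* `spar` (a rougher-than-unpenalized
fit, i.e. interpolation of the noise), which makes the curvature estimate
garbage; the GCV search is restricted to `spar >= 0`.

Turning points are the local maxima of the **signed** second derivative on a
dense grid (0.1 s default): upward curvature marks trend acceleration, which
is the event of interest at metronome offset, and taking $|f''|$ would
conflate accelerations with decelerations. All local maxima above 50% of the
global maximum are reported (trends can turn more than once); the global
maximum is the primary turning point. A near-constant second derivative over
the central 80% of the span — a linear or purely quadratic trend — yields an
explicit "no turning point" state rather than an arbitrary location; the
boundary 10% is excluded from that judgement because natural spline boundary
conditions force the second derivative toward zero at the ends even when the
true curvature is constant. On simulated block-design cohorts, whose only
planted change is at metronome offset, the estimator's median primary
turning point lands on the continuation-onset second (15 s) within one
cycle; the alternating preset reproduces the qualitative early turning
point, whose exact location depends on the anticipatory-ramp parameters and
is not asserted numerically.

## Difference-in-differences

The causal question — does the alternating design degrade entrainment? — is
answered by the canonical two-group (block = control, alternating =
manipulated), two-period (pacing = pre, continuation = post) DID regression

$$Y = \beta_0 + \beta_1\,\mathrm{time} + \beta_2\,\mathrm{group} +
\beta_3\,\mathrm{time}\times\mathrm{group} + \varepsilon .$$

Report rows are labelled Constant / Block / Alternating / Block ×
Alternating, the labels conventional in this literature; the mapping
(time dummy ↔ the control group's temporal change, group dummy ↔ the
alternating group's offset, interaction ↔ the causal effect) is carried in
the fitted object. On a balanced noiseless 2×2 table $\hat\beta_3$ equals
the difference-of-differences of the cell means exactly, which the tests
assert at machine precision. Tapping mode is excluded as a covariate: it is
balanced over time within every participant and cannot confound the design
contrast. Parallel trends — both groups would show the same
pacing-to-continuation change absent the manipulation — is an identifying
assumption, documented but untestable within a single two-period study.
Standard errors are conventional OLS; trial-level observations within a
participant are correlated, so these SEs are anti-conservative, and
clustered or bootstrap SEs are a noted extension rather than a current
feature. Residual kurtosis and skewness are reported as distributional
diagnostics.

## Problem sizes and determinism

The test suite runs the full estimator-recovery checks at deliberately
modest sizes — cohorts of 4–12 participants, 60–100 replicate cohorts for
changepoint recovery, $10^4$ Monte-Carlo replicates for the power oracle —
chosen so the whole suite completes in under a minute while keeping
Monte-Carlo error well below the asserted tolerances (recovery assertions
use 3-standard-error bands; the power comparison uses 2 Monte-Carlo SEs).
Every stochastic step (generator, bootstrap balancing, Monte-Carlo oracles)
is seeded, and the pipeline writes a config snapshot whose hash is recorded
against every artifact, so any bundle can be regenerated byte-for-byte.

## Known limitations

- The generator's independence assumptions (white pacing jitter, independent
  timekeeper intervals) are idealizations; estimator behavior under
  autocorrelated errors is untested.
- Turning-point estimates carry no confidence intervals; formal changepoint
  inference is out of scope.
- The IRI trend's planted step (≈9 ms) is small relative to interval noise
  at realistic cohort sizes, and its turning point is often degenerate in
  simulation — a fair reflection of how weak that signal is.
- DID standard errors ignore within-participant clustering (above).
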