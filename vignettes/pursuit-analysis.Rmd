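---
title: "Smooth-pursuit gain and timing-error analysis for rolling-wheel prediction-motion experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Smooth-pursuit gain and timing-error analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pursuitpm)
```

## The problem

In a prediction-motion task (PMT) an observer tracks a moving target that
disappears behind an occluder and must indicate, by button press, (a) the
moment the target enters the occluder and (b) the moment it would reach the
occluder's far edge. The two presses yield a **constant error** (CE, the
signed mean of `estimated - actual`, positive = late) and a **variable
error** (VE, the standard deviation of those signed errors) per condition.
Simultaneously recorded eye movements quantify how well smooth pursuit
tracks the target: the **velocity gain**, the ratio of average desaccaded
horizontal eye velocity to target velocity, computed in 24 consecutive
250 ms intervals over the 6000 ms tracking period (3000 ms visible,
3000 ms occluded).

The stimulus of interest here is a "rolling wheel": a small target on the
rim of an invisible wheel (radius 1.91°, rotation 298.8°/s) whose centre
translates rightward, optionally surrounded by eight background elements
riding the same ring — so target plus elements occupy nine equally spaced
ring positions rotating rigidly together. Three background conditions
(blank, globally *inconsistent* element shapes, globally *consistent*
shapes) probe whether global–local consistency improves tracking and
time-to-contact estimation.

`pursuitpm` implements the full analysis chain and a synthetic observer
that generates gaze and response data with known ground truth, so every
stage of the chain is testable without human data.

## Stimulus kinematics

The target follows a cycloid: with wheel phase
$\theta(t) = \theta_0 - \omega t$ (clockwise for rightward rolling,
0° = rightward, 90° = up),

$$x(t) = x_0 + v t + r\cos\theta(t), \qquad y(t) = y_0 + r\sin\theta(t).$$

Two choices were genuinely open:

* **Translation speed.** The printed display width (25.99°) cannot
  accommodate 6 s of 10°/s translation, while the rim tangential speed
  $\omega r = 298.8 \cdot \pi/180 \cdot 1.91 \approx 9.96$°/s matches the
  quoted "linear velocity of the uniform circular motion" to 0.4%. We
  therefore treat 10°/s as the *rim* speed and derive the translation
  speed from the timeline: the wheel centre covers the 12° from its start
  to the occluder's left edge in exactly 3000 ms (v = 4°/s) and reaches
  the far edge at 6000 ms, making the ground-truth events land exactly on
  the published timeline. A rolling-without-slipping mode
  (`stimulus_geometry(rolling = TRUE)`) is available for sensitivity
  analysis.
* **Occlusion ground truth.** Entry/arrival are judged on the *wheel
  centre* crossing the occluder edges — a single unambiguous event —
  while each background element becomes invisible when its own x first
  crosses the edge ("one by one").

Start orientations default to the four quarter phases {0°, 90°, 180°,
270°}, counterbalanced exactly within every condition cell of every block;
the trial order is shuffled independently per block from one seeded stream.

## The synthetic observer

The observer is a forward model of the measurement process, not a
cognitive model. Its defaults are the study conditions; they are
configuration, not constants.

**Pursuit gain profile.** Piecewise-smooth and continuous per background:
linear open-loop ramp 0 → `onset_gain` over 100 ms, hold to 250 ms, linear
rise to `steady_gain` by 500 ms, plateau to occlusion onset, exponential
decay (τ = 300 ms) toward `occlusion_residual_gain`, then a linear decline
from 5000 ms reaching `terminal_gain` at 5750 ms. The three published
window means anchor the levels — onset 0.78/0.77/0.69, steady
0.86/0.79/0.79, terminal 0.41/0.34/0.34 for consistent/inconsistent/blank.
No occlusion-phase gains between those windows are reported anywhere, so
the residual defaults to `steady_gain − 0.2` and the decay constant to
300 ms — values chosen once as typical of occlusion pursuit, and the
recovery tests compare against whatever profile is configured, not against
these numbers.

**Eye velocity and saccades.** Horizontal eye velocity is
`gain × v` plus white Gaussian noise (SD 2°/s — the simplest model
satisfying the detector's baseline-noise premise); position is its
integral. Catch-up saccades are raised-cosine velocity pulses (duration
32 ms, displacement = current pursuit lag, peak ≈ 2·amplitude/duration)
injected whenever the *deterministic* pursuit lag — the integrated gain
deficit, noise excluded — exceeds a 1° trigger jittered ±20% per event.
Driving the schedule from the deterministic lag is deliberate: if saccade
timing depended on the noise, excising saccades would select against
particular noise excursions and bias desaccaded averages; with a
noise-independent schedule the desaccaded mean is an unbiased estimator of
the smooth velocity, which is the property the analysis chain assumes and
the tests verify. Blinks arrive at 2/min as 150 ms invalid gaps.

**Responses.** `press1 = t_entry + N(ce, ve)` with the visible-phase
parameters, `press2 = t_arrival + N(ce, ve)` with the occluded-phase
parameters; draws outside the trial window are resampled and counted.
Defaults are the published circle-target condition means. An
`"extrapolation"` response mode couples the occluded bias to the terminal
pursuit gain, mimicking a motion-extrapolation strategy; the default
`"clocking"` mode draws independently. Between-subject structure comes
from Gaussian offsets on the gain levels (SD 0.03) and on the per-phase CE
means (SD 8 ms visible / 30 ms occluded), giving the repeated-measures
ANOVA a realistic error structure.

## Gaze preprocessing

Velocity is derived by a **central difference over a ±10 ms interval**:
at 250 Hz that nominal window spans 2.5 samples, so the half-window is
rounded up to k = 3 samples (12 ms) — the nearest symmetric choice that
covers the nominal span; acceleration applies the same operator to the
velocity. The first/last k (velocity) and 2k (acceleration) samples are
masked `edge`. Invalid (blink) samples are masked with a ±40 ms guard
band.

Saccade detection is two-stage:

1. **Acceleration rule.** Runs where |acceleration| exceeds 2.5 × the
   baseline acceleration SD, the threshold clamped into ≈750–1500°/s².
   The baseline SD is estimated per trial from 300–1300 ms of steady
   pursuit, iteratively trimmed at 2.5 SD until stable. (For white
   velocity noise of SD σ the cascaded operator yields an acceleration SD
   of σ/(2k^{3/2}Δt) ≈ 48°/s² at the defaults, so the clamp floor of 750
   governs and noise alone essentially never fires the rule.) Runs are
   expanded to the flanking zero-crossings of the acceleration (at most
   100 ms per side — a slow monotone deceleration carries no sign change)
   and event bounds are then refined to the 20%-of-peak crossings of the
   velocity deviation from local pursuit, undoing the differentiation
   smear; this keeps the median onset error at a sample or two.
2. **Velocity/amplitude fallback.** Remaining runs where velocity deviates
   from the local pursuit velocity (median in ±100 ms, candidates
   excluded) by >40°/s are kept only when the displacement amplitude —
   net of the local pursuit drift — lies in 0.3–5°. Note that a 24 ms
   averaging window means a >40°/s measured deviation already implies
   ≈1° of displacement, so at the default grid this rule acts as a safety
   net for events the acceleration rule missed, and the amplitude floor
   is only exercisable with a finer analysis window or a raised
   acceleration threshold (both are configuration knobs).

Excision masks each event plus a 16 ms guard band (one sample beyond the
differentiation half-window, covering the velocity leakage even when the
refined bounds sit a sample inside the true pulse). Masked samples are
excluded from all averages — no interpolation — and a trial with more than
half its samples masked is flagged unusable.

## Metrics and statistics

**Gain.** 24 half-open 250 ms bins partition [0, 6000) ms; the per-bin
gain is the mean `ok`-masked velocity divided by the constant translation
speed (the instantaneous cycloidal denominator, which oscillates at the
rotation rate, is available for sensitivity analysis — published gains
near 0.8 are only interpretable against the carrier speed). A bin needs
at least 10 usable samples. The published "100–250 ms" window is treated
as the post-open-loop part of bin 1 and is directly computable via
`velocity_gain(trace, bounds = c(100, 250))`.

**CE/VE.** Per subject × phase × background (× shape), errors are trimmed
once (non-iteratively) at mean ± 3 SD computed on the untrimmed set, then
CE = mean and VE = sample SD (n−1). The sign convention is
estimated − actual: the source wording ("difference between the actual
arrival time and the time estimated") would give the opposite sign, but
uniformly positive published CE means are only interpretable as lateness,
so the late-positive convention is the default and the flipped one is a
documented option.

**ANOVA.** `rm_anova()` computes the full within-subject factorial
decomposition from first principles: effect estimates by
inclusion–exclusion over marginal means, SS as replication-weighted sums
of squares, error stratum = effect × subject,
F = MS_effect / MS_(effect×subject), partial η² =
SS_effect/(SS_effect+SS_error). No sphericity correction is applied by
default (the published dfs are uncorrected integers); Greenhouse–Geisser
is available via `gg_correction = TRUE`. The test suite checks exact
agreement (1e-10) with an independent `aov()` Error-strata oracle and
type-I calibration on null simulations. Bonferroni pairwise comparisons
multiply paired-t p-values by the number of comparisons and widen the CIs
to the adjusted level 1 − α/m so interval and p agree.

**Per-interval tests.** The published per-interval analysis reports
df = (2, 63) with 22 subjects × 3 conditions — consistent only with a
one-way layout treating the 66 subject × condition means as observations,
not with a within-subject F (df₂ would be 42). `interval_univariate()`
therefore uses the subjects-as-replicates layout. Because subject offsets
are shared across conditions, this test is conservative at null intervals,
which is also why localized effects produce cleanly localized flags. No
correction across the 24 intervals is applied by default (an option
exists).

## Reproducible runs and problem sizes

`run_pipeline(run_config(...))` executes simulate → preprocess → metrics →
stats end to end, deterministically in the master seed (per-stage seeds
are derived by an integer mix kept within 32-bit range), and can persist
every intermediate as TSV/CSV so any stage can be rerun standalone.

Default run sizes are scaled-down sessions chosen to make simulation
studies cheap while keeping every estimate comfortably inside its Monte
Carlo error: 22 subjects (the eye-tracking sample size), 20 response
trials and 2 gaze trials per condition per subject. The validation suites
use 200 trials/condition for parameter recovery, 500 trials with injected
saccades (amplitudes 0.5–3°) for detector performance, 2000 null
experiments for ANOVA calibration, and 200 simulated groups for the
effect-direction study. The full 480/300-trial session designs are
available through `design_config()`/`enumerate_trials()`.

## What the synthetic data do and do not establish

The generator emulates the *statistical structure* the analysis assumes:
condition-dependent gain profiles, catch-up saccades detectable by the
published thresholds, blink gaps, Gaussian timing errors with
condition-dependent bias and spread, and between-subject heterogeneity.
Passing tests therefore show that the pipeline recovers known parameters
unbiasedly and that the statistics are exact and calibrated. They do not
validate the oculomotor realism of the waveforms (no main-sequence
nonlinearity, no pursuit latency jitter, no drift or measurement
low-frequency noise unless enabled), and real observers' CE/VE and gain
values are empirical facts no simulation can confirm — group-level
human means enter only as generator defaults.

Other known limitations: vertical gaze is a fixed-gain copy of the
target's y (the analysis is horizontal-only by design); saccade amplitude
during occlusion assumes perfect extrapolation of the wheel centre;
`estimate_baseline_noise()` assumes the 300–1300 ms window is
saccade-free after iterative trimming, which very dense saccade trains
could defeat.

## A worked example

```{r example, eval = FALSE}
library(pursuitpm)
report <- run_pipeline(run_config("exp2", seed = 1))
report
report$interval_table[c(1, 12, 24), ]
```

The printed report shows the per-condition CE table (consistent <
inconsistent ≈ blank in the occluded phase), the 2 × 3 within-subject
ANOVA with a significant consistency main effect, and the intervals
flagged by the per-interval tests. `scripts/acceptance.R` recomputes all
headline quantities from scratch; see the README for how to run it.
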