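---
title: "Methods: pupil dynamics in the interleaved pro-/anti-saccade task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pupil dynamics in the interleaved pro-/anti-saccade task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ipastpupil)
```

## The measurement model

In the IPAST, a luminant fixation point appears on a dark background for
1,000 ms, disappears for a 200 ms gap, and is followed by a peripheral
stimulus at ±10°. The fixation point evokes a pupillary light reflex — a
constriction beginning after an onset latency of roughly 200–400 ms and
bottoming out late in the fixation epoch — after which the pupil dilates
until the stimulus appears. That dilation carries a cognitive signal:
preparing a voluntary anti-saccade produces more dilation than preparing a
reflexive pro-saccade, and the size of that ANTI − PRO gap changes with age.

The pipeline reduces each viable trial to eight numbers:

| measure | definition | units |
|---|---|---|
| baseline size | mean pupil, 150–200 ms after fixation onset | mm |
| onset latency | first sustained departure of velocity from its baseline distribution | ms |
| constriction size | baseline − pupil at peak constriction | mm |
| peak constriction time | time of the pupil minimum | ms |
| peak constriction velocity | most negative velocity before the peak | mm/s |
| dilation size | mean pupil in [−50, 0] ms before the stimulus − pupil at the peak | mm |
| dilation velocity | mean velocity in the same 50 ms window | mm/s |
| peak dilation velocity | largest velocity between the peak and the stimulus | mm/s |

Six of these are kept separately for PRO and ANTI (their medians across a
participant's viable trials); baseline size and onset latency show no task
modulation and are pooled, giving the 14-variable row per participant that
feeds the factor analysis.

### Assumptions

* Monocular recording at a constant sampling rate (500 Hz by default); the
  tracker reports pupil *area* in arbitrary units and a per-sample validity
  flag.
* One rig-level calibration: the false pupils were recorded at the same
  position as participants' eyes, so a single conversion curve serves the
  whole data set (a per-participant curve would be a drop-in replacement).
* The pupil response of interest lies entirely in the 1,200 ms fixation
  epoch; post-stimulus dynamics are out of scope.
* Gaussian response for the lifespan GAMs; factor scores are approximately
  interval-scaled.

## Parameters that matter

All constants live in `run_config()` — nothing is hard-coded — so
sensitivity analyses are one-argument changes.

* **Despike threshold, 0.1 mm/ms.** Physiological pupil change is an order
  of magnitude slower; anything faster is tracker noise or an eyelid
  artifact. Applied once on the calibrated trace (internally everything is
  mm and mm/s).
* **Smoothing, ±25 samples.** A 51-sample (102 ms at 500 Hz) boxcar. The
  window shrinks at edges and across invalid runs rather than zero-padding.
* **Gap interpolation, ≤ 200 ms.** Longer losses stay invalid: we do not
  invent data across long blinks, and a long loss inside fixation trips the
  viability screen instead.
* **Blink padding, 50 ms** per side: eyelid occlusion corrupts the area
  signal before and after the tracker reports loss.
* **Saccade detector: 30 °/s for ≥ 6 ms** on 5-sample-smoothed gaze with
  central-difference velocity. These are field-standard values; the upstream
  standardized pipeline this stage replaces is deliberately minimal here.
* **SRT windows.** Latency classes partition [−110, 800] ms as half-open
  intervals `[−110, 90)`, `[90, 140)`, `[140, 800]`. The half-open
  convention resolves the boundary overlaps at 90 and 140 ms
  deterministically (an SRT of exactly 140 ms is regular, exactly 90 ms is
  express). The pupil-viability screen, however, follows the explicit
  "greater than 90 ms" inclusion rule, so express and regular trials are
  both retained for pupil analysis while anticipatory ones are not.
* **Amplitude convention, 2°.** The same threshold defines "a saccade away
  from fixation" for SRT and the fixation-period exclusion; using one value
  avoids a class of asymmetric edge cases.
* **Onset-latency test.** The measure needs an operational definition of
  "velocity significantly differs from baseline". We use a one-sample
  t-test of each 20 ms (10-sample) window against the mean baseline-epoch
  velocity, α = 0.05, with a 40 ms sustain requirement; window length,
  sustain and α are exposed. On noise-free data the t-statistic degenerates
  (zero spread), so a window with zero spread counts as significant only if
  its mean genuinely differs — this keeps the definition exact on synthetic
  traces.
* **Retention rules.** MoCA ≥ 20 where administered (adults only; `NA`
  means not administered) and ≥ 10 viable correct trials per condition.

## The synthetic cohort generator

The generator is first-class, tested code: its defaults define the study
conditions under which the package's statistical claims are verified.

Each trial's pupil trace is baseline − amplitude·g(t) + ramp + noise, where
g is a half-cosine pulse from the constriction latency to the peak time
(hitting baseline − amplitude *exactly* at the peak) and the dilation is a
linear ramp from the peak. The ramp continues ~260 ms past stimulus onset
before flattening — preparatory dilation does not stop instantly — which
also means the boxcar sees ramp on both sides of the dilation measurement
window, keeping the window's mean velocity unbiased. Gaze holds fixation and
then steps ±10° with a cosine velocity profile whose peak follows the
saccadic main sequence `v = 500·(1 − exp(−amplitude/15))` °/s. Blinks are
invalid runs flanked by ±0.5 mm spikes, exercising both the validity and
despike paths.

The age schedule encodes the trends this literature reports, chosen once as
plausible magnitudes: baseline 7.0 mm at age 5 falling steeply to age 20
then gradually (senile miosis); PRO dilation rate 0.40 mm/s falling with
age; an ANTI − PRO dilation gap of 0.12 mm/s at age 5 shrinking linearly to
zero by 70; a weaker, earlier ANTI constriction in the young; U-shaped SRT
with ANTI ≈ PRO + 60 ms; anti-saccade direction errors elevated in children
and the elderly. Between-participant baseline diameter varies with SD
0.35 mm at fixed age and sex (individuals differ in resting pupil size);
the stand-alone sex-difference power simulations use a 0.5 mm residual SD,
an a-priori typical between-subject spread for baseline pupil within an age
band. Ages are uniform over 5–93 unless an explicit age list is supplied —
the real cohort's age histogram is not published at usable resolution, so we
do not pretend to match it.

What the generator does **not** emulate — and hence what green tests do not
establish about real data: pupil foreshortening with gaze angle, non-white
measurement noise, trial-to-trial carry-over of slow arousal states,
response overlap between consecutive 3.2 s trials, and realistic rates of
unusable participants. At default settings nearly every simulated
participant survives the retention rules, so the generator's data-quality
model is optimistic; the flow-accounting stage is therefore verified
separately on explicit enrolment counts.

Sampled trial parameters are stored alongside each trial, and every trial
carries its own derived seed, so any trace can be re-rendered independently
and the whole pipeline is byte-reproducible from one seed.

## Numerical choices

* **Calibration** averages replicate recordings per size in area space
  (unbiased under additive area noise), then interpolates mm over
  sqrt(area). Outside the node range it extrapolates linearly from the
  terminal segments — a child's pupil can exceed the largest false pupil —
  and warns when more than 5% of samples extrapolate.
* **Noise-free recovery convention.** The eight measures recover the
  generating parameters exactly when extracted from the raw noiseless trace
  (baseline to < 1e−6 mm, constriction size to < 1e−3 mm, peak time to one
  sample, dilation velocity to < 0.02 mm/s). The boxcar is a device for
  suppressing measurement noise; on noise-free input it only biases the
  sharp minimum (by design it trades a ~1–3% flattening of the peak for
  variance reduction), so exactness is asserted pre-smoothing and the
  smoothed pipeline is held to 5% on noisy cohorts instead.
* **PAF iteration.** Communalities start at squared multiple correlations;
  the reduced matrix is re-eigendecomposed until the largest communality
  change falls below 1e−3 (the SPSS convention). A doublet factor — two
  indicators, as with baseline + onset latency — makes the weaker
  variable's communality drift geometrically toward a Heywood case, and a
  much tighter tolerance is never reached; Heywood values are clamped at
  0.999 with a warning. The iteration cap is 1000 (the drift can take a few
  hundred iterations to settle) and non-convergence is an error carrying
  the recent iteration trace.
* **Oblimin** is minimised by gradient projection with column-normalised
  oblique updates, γ = 0 (direct quartimin, the SPSS default); with one
  factor the rotation is the identity. Communalities are rotation-invariant
  and asserted so.
* **Factoring input.** Extraction runs on Pearson correlations — the
  conventional PAF input — while Spearman matrices serve display and
  sensitivity (`cor_method = "spearman"`); with monotone measure scales the
  two are close, and the choice is config-switchable because the original
  tooling's input is ambiguous.
* **Kaiser retention** counts eigenvalues of the *unreduced* correlation
  matrix strictly above 1, so an exact identity matrix retains zero
  factors.
* **Factor matching for recovery tests** is greedy maximal |Tucker
  congruence| with sign alignment.
* **GAM machinery.** Cubic regression splines, k = 10, REML; grid of 200
  ages; derivative by central differences with ε = 0.1 yr on the
  linear-predictor matrix; bands from 10,000 coefficient-posterior draws,
  seeded. The **simultaneous** band (max-statistic critical value) is the
  default because a window search across 200 grid points is a family of
  tests; pointwise bands remain available (`simultaneous = FALSE`) for
  comparison with tools that report them. Simulations in the test suite
  quantify the trade: under the study conditions the simultaneous band
  holds the null any-window rate near 3% but detects a 1-SD childhood
  decline in roughly four runs of five, whereas the pointwise band detects
  it almost always at the price of an ~8% null rate. We keep the
  conservative default and report both rates rather than tuning either.
* **Sex difference** is estimated as the female-minus-male prediction
  difference of a GAM with a shared age smooth plus an ordered-factor
  difference smooth (and a parametric sex offset), with the same
  simultaneous-band machinery on the difference curve.
* **Degenerate inputs** are flagged, not silently patched: a trace whose
  minimum sits at the search-window start (pure dilation), a peak within
  50 ms of the stimulus (no dilation window), all-zero ANTI-effects
  (p = 1, degenerate), a singular correlation matrix (error suggesting
  variable removal).

## Open choices, resolved

* *Median vs mean aggregation*: the methods wording is median, the results
  wording mentions subject averages; we use the **median** everywhere for
  subject-level aggregation and read "averages" as that median.
* *Age-group display bins*: the original 11 group boundaries are in
  unavailable supplementary material; `bin_age_groups()` defaults to 5–8,
  9–12, 13–16, 17–20, 21–29, 30–39, 40–49, 50–59, 60–69, 70–83, 84–93 with
  closed-upper assignment, and accepts arbitrary breaks.
* *Exclusion ordering*: whether direction errors were screened before or
  after the blink/saccade screen does not change the retained set; every
  violated rule is recorded per trial regardless.
* *One calibration curve*: rig-level, per the fixed false-pupil position.

## Problem sizes used in the checks

The test suite and acceptance script use cohorts scaled to the claims they
verify: 500 rows for factor recovery, 200 participants (24 noise-free
trials each) for the planted ANTI-effect, 2,000 replicates for signed-rank
null calibration, 400/100 replicates for Bonferroni error and power,
567-observation GAM simulations with 25–60 replicates per scenario, and a
50-participant two-block cohort for the end-to-end determinism run.

## Known limitations

* The onset-latency estimator's t-test treats within-window velocity
  samples as independent, which they are not after smoothing; the sustain
  criterion compensates in practice, but the latency is the least sharply
  recoverable of the eight measures.
* Regression factor scores for a doublet factor have limited determinacy
  (score-to-latent correlation ~0.75 in simulation) regardless of
  implementation.
* The exclusion model of the generator is optimistic (see above); realistic
  exclusion rates must come from real recordings.
* Smoothing-spline trajectory fits are descriptive only; all inference
  about age trends goes through the GAM derivative machinery.
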