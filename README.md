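# ipastpupil

Analysis pipeline for pupil dynamics recorded during the **interleaved
pro-/anti-saccade task (IPAST)**, aimed at researchers studying how the
pupil's task-evoked response changes across the healthy lifespan and how it
relates to saccadic behaviour.

In the IPAST each trial shows a central fixation point for 1,000 ms on a dark
background (its colour instructs a look-toward, PRO, or look-away, ANTI,
response), a 200 ms dark gap, and then a peripheral stimulus 10 degrees left
or right. The fixation point evokes a pupil constriction that is followed by
preparatory dilation until the stimulus appears; saccade preparation — ANTI
more than PRO — modulates this dilation. The package implements the full
chain from raw tracker samples to population-level inference:

- **Calibration** — false pupils of known diameter (2–12 mm) map tracker
  area units to millimetres by linear interpolation over the square root of
  the recorded area.
- **Cleaning & events** — despiking (|Δpupil| > 0.1 mm/ms), interpolation of
  short invalid gaps, ±25-sample boxcar smoothing; blink detection from
  validity runs; velocity-threshold saccade detection (30 °/s, ≥ 6 ms).
- **Trial classification** — saccadic reaction time (SRT) from stimulus
  onset to the first ≥ 2° saccade; anticipatory `[−110, 90)`, express
  `[90, 140)` and regular `[140, 800]` ms latency classes; direction errors;
  pupil-viability screening (no blink or > 2° saccade during fixation,
  SRT > 90 ms, correct direction) and participant retention (MoCA ≥ 20 where
  administered, ≥ 10 viable trials per condition).
- **Eight pupil measures per trial** — baseline size (150–200 ms after
  fixation onset), response onset latency (20 ms sliding-window velocity
  test), constriction size / peak time / peak velocity, dilation size /
  velocity / peak velocity (the dilation window is the closed 50 ms before
  stimulus onset).
- **Task modulation** — the ANTI-effect, the participant's ANTI median minus
  PRO median per measure, tested with two-sided Wilcoxon signed-rank tests.
- **Factor analysis** — the 14-variable pupil table (6 measures × 2
  conditions + pooled baseline and onset latency) and a 12-variable saccade
  table are factored by iterated principal-axis extraction with direct
  oblimin (γ = 0) rotation, preceded by KMO and Bartlett adequacy checks and
  Kaiser (eigenvalue > 1) retention; pupil and saccade regression scores are
  correlated (Spearman) under Bonferroni correction.
- **Lifespan trajectories** — penalized cubic spline GAMs (`mgcv`, k = 10,
  REML) of factor scores on age; *significant periods of change* are the
  ages where the simultaneous 95% confidence band of the fit's first
  derivative excludes zero; a difference-smooth GAM localises sex
  differences in baseline pupil size.
- **Synthetic cohorts** — because raw recordings of this kind are rarely
  shareable, a seeded generator emulates the task timeline, trace shapes,
  age trends, blinks, direction errors and the latent factor structure, so
  every stage is testable end to end.

## Worked example

```r
library(ipastpupil)

cfg <- run_config(n_participants = 40, seed = 42,
                  trials_per_block = 40, n_blocks = 1)
res <- run_pipeline(cfg)

res$report
#> Enrolled: 40 (21 F + 19 M)
#> Retained: 40; excluded: 0 (0.0%)

dplyr::select(res$anti_effect_table, measure, n, median_effect,
              p_value, significant)
#> # A tibble: 6 × 5
#>   measure                        n median_effect   p_value significant
#>   <chr>                      <int>         <dbl>     <dbl> <lgl>
#> 1 constriction_size             40      -0.0125  0.000440  TRUE
#> 2 dilation_size                 40       0.00786 0.0000186 TRUE
#> 3 dilation_velocity             40       0.0302  0.00117   TRUE
#> 4 peak_constriction_time        40      -9.5     0.00181   TRUE
#> 5 peak_constriction_velocity    40       0.0201  0.152     FALSE
#> 6 peak_dilation_velocity        40       0.0359  0.000139  TRUE
```

The generator plants larger, faster preparatory dilation (and weaker
constriction) on ANTI trials, fading with age: at 40 participants the
pipeline already resolves the positive dilation-velocity ANTI-effect
(+0.030 mm/s, p ≈ 0.001) and the negative constriction-size effect
(−0.013 mm). Factor structure needs a larger cohort:

```r
sim <- simulate_measure_rows(500, seed = 7)   # 3-factor generative model
fit_factor_model(sim)
#> Factor model: 14 variables, 3 factors (pearson correlations, n = 500)
#> KMO = 0.920; Bartlett chi2(91) = 4193.9, p = 0
#> Variance explained before rotation: 72.16%
#> (pattern matrix: constriction block on F1, dilation/peak-time block on F2,
#>  baseline + onset latency on F3)
```

`autoplot()` methods exist for every result type (`factor_model`,
`anti_effect_table`, `factor_cor`, `gam_fit`, `sex_diff`), and
`tidy()`/`glance()` return tibbles for downstream use. A thin CLI wrapper
lives in `inst/scripts/ipast-pipeline.R`
(`ipast-pipeline.R all --n 50 --seed 1 --out dir`).

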