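---
title: "Methods: free-living glucose and posture analysis for sitting-substitution trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: free-living glucose and posture analysis for sitting-substitution trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sitless)
```

## The problem

Randomised crossover trials of sedentary-behaviour substitution ask whether
replacing several hours of daily sitting with standing and walking changes
free-living glycaemia. Two wearable streams are collected per participant:
a flash glucose monitor (FGM) that stores one epoch-averaged interstitial
glucose value per 15 minutes (mmol/L), and a thigh-worn inclinometer
(activPAL-style) that emits a contiguous stream of posture events
(sitting/lying, standing, stepping) with step counts. Each participant
completes two 4-day regimens in counterbalanced order — SIT (restrict
standing and walking to at most 1 h/day each) and SITless (substitute at
least 5 h/day of sitting with at least 3 h standing and 2 h walking) —
separated by a 3-day washout.

`sitless` implements the full analysis chain: stream ingestion, valid-day
filtering, waking-window detection, daily and postprandial glycaemic
metrics, posture and sedentary-bout outcomes, and mixed-model regimen
contrasts, together with a calibrated synthetic-data generator that makes
every stage verifiable without access to participant data.

## Valid-day filtering

A participant-day enters the analysis only if both streams are valid on it:

* FGM: strictly more than 70% of the 96 15-minute epochs of the calendar
  day are present;
* activPAL: wear time at least 10 h, at least 500 steps, and strictly less
  than 95% of wear time in any single activity class.

The single-activity denominator is wear time, not the 24-h day, following
the standard processing convention for these monitors. A participant is
excluded entirely unless each regimen has at least one doubly valid day.
Washout days are never analysed, valid or not. All thresholds live in one
`pipeline_config()` block so every filter is auditable and adjustable.

## Waking windows

Waking metrics require a per-participant-day waking window. The monitor
literature delegates this to proprietary heuristics, identifying waking
hours individually per participant from the posture stream without a
published algorithm, so the package encodes a transparent heuristic: a candidate sleep block is a maximal run
of sedentary and/or nonwear events carrying zero steps and lasting at
least `min_sleep_h` (default 3 h); for each date, the candidate with the
largest overlap with the night anchor (22:00–10:00) on either side defines
wake and sleep onset, and the window is their complement. Degenerate
streams fall back to a configurable default window (07:00–23:00) with a
warning. The defaults are deliberate, conservative choices; both are
configuration keys.

Extensive waking metrics (net iAUC, time-in-range minutes) are normalised
to a nominal 16-h day by multiplying with `16 / duration`; intensive
metrics (mean, %CV, percent-of-epochs in range) pass through unchanged.

## Glycaemic metrics

Per day the package reports mean glucose, %CV (SD/mean, reported as a
fraction), percent of present epochs in 3.9–10.0 mmol/L (TIR), above 10.0
(TAR), below 3.0 (TBR), total trapezoidal AUC, and net incremental AUC
(net iAUC): total AUC minus the day's waking glucose concentration times
the covered duration. The waking glucose concentration is, by default, the
first present epoch at or after wake time; a fasting-average alternative is
exposed as a configuration choice because the field uses both.

Numerical choices:

* The trapezoid runs over present epochs; gaps longer than `max_gap_min`
  (default 60 min) are not bridged — they contribute no area and shrink the
  covered duration used in the baseline product, which keeps net iAUC
  consistent under missingness.
* Epoch-count metrics use epochs in `[t0, t1)`; the trapezoid also uses a
  sample falling exactly at `t1`, so a complete calendar day integrates
  over the full 24 h.
* TIR/TAR/TBR are epoch-count percentages, not interpolated time: the data
  are already epoch averages.
* Postprandial iAUC for each meal is the trapezoidal AUC over the 2 h
  after the logged meal time minus the last pre-meal concentration times
  the covered duration; the baseline sample must lie within 60 min before
  the meal. Values may be negative. Meal times come from the meal log;
  the pipeline never infers meals from excursions.

Regimen-level values are unweighted means over a participant's valid days,
then contrasted across regimens.

## Posture and bout outcomes

Daily totals (sitting, standing, stepping hours; steps) are computed within
the waking window, splitting boundary-straddling events pro-rata in both
duration and steps. Sedentary bouts are maximal runs of sitting/lying
within the window; nonwear terminates a bout. The duration classes 0–30,
30–60 and >=60 min partition sitting time exactly (boundary values go up);
the reported >=30 and >60 rows are derived overlapping views. A
sit-upright transition is a sedentary-to-upright boundary. Stepping events
are classed moderate-to-vigorous at a cadence of at least 100 steps/min
(configurable): the trial's own guidance that 6000 steps approximate one
hour of moderate walking implies that threshold.

## Statistical model

The analysis unit is the participant-by-regimen mean. Each outcome is
modelled as `value ~ regimen + covariate + (1 | participant)` with
maximum likelihood via lme4; with exactly two conditions per participant
the random intercept is identical to the compound-symmetry repeated-
measures structure, which is why the package implements the former.
Posture outcomes adjust for activPAL waking wear time; glucose outcomes
adjust for BMI. Inference uses Satterthwaite degrees of freedom
(lmerTest), two-tailed p-values and Wald 95% CIs. When the variance
estimate is singular (common for baseline-subtracted outcomes such as net
iAUC, whose participant-level differences are removed by construction),
the fit falls back to a paired contrast on covariate-adjusted residuals;
the result row records which route was taken. Cohen's d defaults to the
paired mean difference over the pooled SD of the two regimen
distributions, with the paired-difference SD available as an option, since
the field uses both conventions.

## The synthetic-data generator

`sim_config()` encodes the study conditions: 14 participants, 4 + 3 + 4
days, 15-min epochs, and regimen levels equal to the trial's reported
means — sitting 10.6 vs 7.0 h/day (split into bout classes 3.3/2.2/5.1 vs
2.7/1.6/2.7 h), standing 3.8 vs 5.7, light/MVPA stepping 0.6/0.6 vs
1.0/1.8 h, and cadences chosen so expected step totals are 4960 vs 13658
per day.

### Behaviour

Each waking day is assembled from exact time budgets: sedentary bout
durations are drawn per class (short bouts from a truncated exponential;
30–60 and >=60 classes from shifted exponentials matched to the reported
mean bout lengths) and rescaled within class bounds so class times are hit
exactly; bouts alternate with standing segments and cadence-jittered
stepping events, and every day starts and ends upright, with a stepless
sedentary sleep block closing the night.

Heterogeneity is deliberately *compositional*: participant, participant-
by-regimen and day-level deviations reallocate time between sitting and
upright behaviour within a day length drawn independently, with standing
as the buffer category. Two consequences were design goals. First,
sitting and stepping deviations are orthogonal to waking wear, so the
wear-adjusted model estimand equals the configured contrast for sitting,
stepping, steps and prolonged-sitting time. Second, the between-
participant spread matches the scale of the trial's reported confidence
intervals rather than collapsing once wear is adjusted for. One
inconsistency is structural and worth stating plainly: adjusted contrasts
of the three categories must sum to zero when wear is their sum, but the
trial's printed contrasts (−3.6, +1.9, +1.6 h/day) sum to −0.1. The
generator therefore reproduces sitting and stepping exactly and lets
standing absorb the residual: its adjusted estimand is +2.0 h/day against
a printed +1.9 (raw regimen means remain 3.8 vs 5.7).

### Glucose

Glucose is participant baseline (normal, mean 5.4, SD 0.8 mmol/L) + a
small sinusoidal diurnal term + per-meal excursion kernels + Gaussian
epoch noise (SD 0.5 mmol/L), with 3% of epochs deleted at random and
values clipped to the 1.1–27.8 mmol/L sensor range. The excursion kernel
is gamma-shaped (latency then peak at 45 min, effective support about
3 h), which exercises the trapezoid and baseline logic with realistic
postprandial physiology. Excursion sizes are configured directly as
expected 2-h iAUCs and converted to kernel amplitudes through the same
epoch grid, meal-time jitter and missingness the pipeline sees
(`expected_unit_iauc()`), so configured 2-h iAUC contrasts are exact
expectations; the lunch contrast is −1.0 mmol/L per 2 h.

The waking net iAUC contrast (−9.2 mmol/L per 16-h day) is too large to
arise from the three postprandial attenuations alone, so SITless days
additionally lower glucose from late morning until sleep by a plateau
profile that is constant across every meal window (ramp 11:00–11:30,
flat until sleep onset). Because postprandial iAUC subtracts a pre-meal
baseline, a locally constant offset cancels there exactly: the plateau
moves waking net iAUC without biasing any 2-h iAUC. Its magnitude is
solved by `study_calibration()` with a fixed-seed Monte Carlo over day
geometry (wake time, day length, meal jitter, missingness), exploiting
that the contrast is linear in the plateau height. A convenient
side-effect matches the trial: SITless waking mean glucose sits about
0.4–0.6 mmol/L lower.

Amplitude heterogeneity uses mean-one gamma multipliers (participant,
participant-by-regimen, day), so every configured level remains an exact
expectation while between-participant spread stays realistic.

### What the generator does not emulate

No glucose–insulin dynamics, no diet composition, no correlated sensor
error or dropout bursts (missingness is uniform), no naps or split sleep,
and no carryover between regimens (washout days exist but carry no
effect). Passing parameter-recovery tests therefore shows that the
pipeline estimates what the generator encodes under the study's design
and noise scale — not that the physiological model is complete.

## Validation strategy and problem sizes

The test-suite validates three layers with independent oracles: the
trapezoid against closed-form integrals of piecewise-linear profiles
(relative error below 1e-9, with exact interval-splitting additivity);
the bout decomposition against a deliberately naive event-walking
enumerator over 1000 random tilings; and the statistics layer against the
balanced-design identity (mixed-model contrast = mean paired difference)
plus a 1000-trial null calibration of test size at the 5% level.
Parameter recovery runs 200 full simulate-analyse replicates at the study
size (n = 14, 4 + 4 days): each configured contrast must lie inside the
central 95% interval of the replicate estimates. The reproduction script
uses 300 replicates of the four headline contrasts. These sizes were
chosen so Monte-Carlo error is a few percent of each target while the
whole suite stays desk-scale.

## Known limitations

* The waking-window heuristic approximates, but is not, the proprietary
  algorithm used by monitor vendors; windows on real exports should be
  audited (`detect_waking_window()` flags fallbacks).
* The trial's printed 24-h net iAUC magnitudes (~140 mmol/L per 24 h
  alongside mean glucose 6.4 mmol/L) are not reproducible from the stated
  formula in mmol/L-hours under any baseline convention we could infer;
  the package implements the stated formula and validates between-regimen
  differences rather than absolute levels.
* Cohen's d values printed in the trial are not reproducible from its own
  means and CIs under a single formula; both denominator conventions are
  exposed.
* With two conditions, singular mixed-model fits are expected for
  baseline-subtracted outcomes; the paired fallback is statistically
  exact there but callers should note the `method` column.
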