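---
title: "Methods: specification curves, the synthetic cohort, and what a green test establishes"
author: "sleepsca"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: specification curves, the synthetic cohort, and what a green test establishes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## 1. The analytical model

Every specification is one path through four analytical decisions:

| decision | options |
|---|---|
| day type | weekday, weekend |
| sleep measure | reversed banded bedtime (retrospective), diary sleep-onset score, total retrospective sleep time |
| technology measure | diary participation, diary before-bed use, diary time spent, retrospective screen composite |
| control set | demographics; +child; +mother; +family; all |

A "no controls" option is deliberately excluded: simple demographic controls
are routine in this literature, so an uncontrolled model is not a defensible
path. The grid is the full Cartesian product, 120 specifications.

Each specification is an ordinary least squares regression in which the
outcome, the technology predictor and all continuous covariates are z-scored
*on the specification's own analysed rows* (after listwise deletion), and
the mother's-education factor enters as reference-coded dummies. The
reported β is the coefficient on the technology predictor — a standardized
effect per SD — with classical standard errors and a two-sided t-test at
α = 0.05. Curve-level inference uses the percentile bootstrap: each
replicate resamples *participants* with replacement at the original n and
re-runs all specifications on the same resampled table, preserving the
cross-specification correlation; 95% intervals are empirical quantiles per
specification and for the median summaries. No overarching non-parametric
curve test is attempted: the specifications are strongly dependent, and we
follow the source design in reporting the ranked curve, medians, and a
paired t-test over the 60 weekday/weekend pairs instead.

Design choices where the source left the procedure open:

* **Binary technology predictors are z-scored** like continuous ones, so all
  120 coefficients live on one standardized axis (the curve plots them
  together).
* **The weekday/weekend test is a paired t-test** over the 60 matched
  specifications. A "t₆₀" subscript is ambiguous between 60 pairs (df = 59)
  and df = 60; we report df explicitly so either reading can be checked.
  Zero variance of the differences is returned as t = 0, p = 1.
* **Degenerate fits are first-class**: a zero-variance outcome/predictor or
  an n ≤ p cell produces a typed status code in the results table, never a
  silently shortened curve.
* **No survey weights, no imputation** (listwise deletion throughout),
  matching the source analysis.

## 2. Measure construction

Banded self-report items are converted by a midpoint-of-bin rule: bedtime
score + 7.5 gives a PM-decimal clock hour (category 1, "before 9 PM" → 8.5;
category 4, "11–midnight" → 11.5); sleep before midnight is 12 − clock;
wake scores add 4.5 (weekday) or 6.5 (weekend); total sleep is the sum of
the two half-nights. The diary sleep onset is the *last* transition from a
non-sleep code into sleep over the 144 ten-minute slots (4 AM–4 AM), scored
`s = 145 − slot` so higher means earlier; this reproduces both printed
anchors (mean 30.22 ≈ 11 PM weekday, 27.74 ≈ 11:20 PM weekend). Diaries with
no sleep onset at all take the scale minimum s = 1 (the assumption that
such adolescents fell asleep at 4 AM; configurable to 0), while all-sleep
diaries — where no
onset is identifiable — are treated as missing rather than assigned the
fallback. Before-bed use looks at the three complete slots strictly before
the onset slot; the onset slot itself is excluded because the diary codes a
single primary activity per slot.

Two item-direction questions the source leaves open were decided once: the
two "argue" items of the closeness scale are reverse-coded before averaging
(so higher = closer; the printed means ~3.2 are compatible with either
choice), and the "time with child" item is passed through as coded. The
retrospective screen composite, although phrased for a school week, is used
unchanged in weekend specifications, as in the source.

## 3. The synthetic cohort: a stated world

The generator emulates the statistical structure the analysis assumes — it
is not a re-creation of the restricted cohort microdata.

Two independent standard-normal person latents drive everything: **T**
(technology propensity) and **U** (sleep propensity). Every ordinal item is
a thresholded unit-variance latent loading on exactly one of the two; the
cutpoints are solved at configuration time so the discretised distribution
matches the printed mean/SD of the item (a discretised normal fitted by
Nelder–Mead; the solver reproduces the targets to < 0.01 scale points).
Skewed covariates (income, Kessler score, sibling count, word activity) use
a Gaussian copula so their marginals are exact. Key calibration decisions:

* **Printed bedtime means are for the reversed item** ("higher = earlier"),
  so the raw-item targets are 6 − 3.06 = 2.94 (weekday) and 6 − 2.04 = 3.96
  (weekend).
* **Wake-item marginals are not printed.** They are backed out of printed
  quantities: E[wake] = target total sleep − (9 or 11) + raw bedtime mean,
  giving 2.56 (weekday, 5 categories) and 3.49 (weekend, 6). Wake SDs (0.90,
  1.10) and bed/wake loadings on U (0.65; 0.62 weekday, 0.45 weekend) were
  chosen so the *derived* total-sleep SD approximates the printed 1.04/1.23.
* **Daily digital hours are log-normal** (the source describes strong
  positive skew without naming a law) with the printed
  participant-conditional mean/SD
  (3.45/2.49 weekday, 4.59/2.98 weekend). Because participation and
  duration share the technology latent, duration is drawn from the
  participation latent's *conditional* copula among participants — keeping
  the tech correlation while making the participant-conditional marginal
  exact. Hours are laid into at most two contiguous, evening-weighted
  episodes of 10-minute slots.
* **Before-bed use** is an independent Bernoulli "abut" indicator with
  probability `bedtime_use_prob / participation_prob`, so the marginal
  matches the printed 0.46/0.47 exactly; when it is off, a three-slot buffer
  keeps the before-bed window clean.
* **The onset score** is a rounded normal censored at the scale minimum
  (the no-onset fallback); its latent mean is solved numerically so the
  censored, rounded score hits the printed mean exactly.
* **Covariates load on either T or U, never both.** This is deliberate:
  with all true effects zero, technology and sleep are then independent
  given anything, so *every* specification satisfies its null and the
  type-I-error criterion is well-defined. Cross-loading covariates would be
  genuine confounders and would make "all effects zero" a false null for
  under-controlled specifications. The cost is realism: the synthetic world
  has no residual confounding, so a green type-I test says the engine's
  inference is calibrated, not that the real-world design is unconfounded.
* **True effects** are injected additively on the latent onset score and
  (sign-flipped) on the latent raw-bedtime item, scaled by standardized
  pathway quantities, so the matching specification's β estimates the
  configured value. Thresholding attenuates the retrospective outcomes by
  ~4–10% (a 5-category item correlates ~0.95 with its latent; total sleep
  adds the wake item's noise), which is inside the stated ±0.03 recovery
  tolerance for a −0.10 effect. Diary-side recovery is essentially exact
  (slot rounding only).
* Defaults not derivable from printed values (diary wake slot ~7 AM/8:30 AM,
  covariate link strengths ~|0.1–0.25|, missingness rates 1–8% per block,
  age distribution from the printed 13/14/15 counts, male share 5953/11884)
  were chosen once as plausible survey magnitudes and are not tuned against
  test outcomes.

The diary subsample is drawn uniformly at random (the source reports small
covariate differences for its subsample; emulating them is left to the
configurable effects rather than a default tilt, since no usable effect
sizes are printed).

### What the generator does *not* emulate

Multi-activity slots (one primary code per slot), the original 44 activity
codes (collapsed to 7; the analysis never distinguishes non-digital,
non-sleep codes), within-person day-to-day variation, survey design
(oversampling, weights), informative missingness, and measurement error
correlated with usage intensity. Green calibration tests therefore establish
that the pipeline reproduces the *printed marginals* and recovers *known
injected effects* — not that it reproduces the source study's coefficient
curve, which depends on restricted microdata.

## 4. Numerical choices

* Ordinal cutpoint solver: Nelder–Mead on squared moment error, reltol
  1e-14; a miss > 0.01 on the mean warns.
* Onset latent mean: `uniroot` on the exact censored-rounded mean
  (series over 400 slots), tol 1e-10.
* OLS via QR (`lm.fit`) with pivot-aware covariance; an aliased technology
  predictor raises a degenerate error instead of returning NA.
* Percentile intervals use `quantile(type = 7)`; a single replicate yields
  the degenerate interval [β, β].
* Seeds: the generator seeds once at entry; the bootstrap takes its own
  seed; `run_all` derives the bootstrap seed as `seed + 1`.

## 5. Scaled-down acceptance settings

The bootstrap-coverage criterion (B = 200 over 100 generations, scaled down
from the full B = 500) is run on the single matching specification at
n = 2000 rather than the full 120-spec curve: the criterion fixes the
replicate and generation counts, and per-spec coverage is a per-spec
property, so restricting the grid changes runtime (~2 min instead of ~15)
but not the quantity measured. The type-I criterion runs the full grid on
200 cohorts of n = 2000 as stated.

## 6. Known limitations

* The recovery attenuation above means configured effects on retrospective
  outcomes are recovered slightly shrunk (≈0.9×); injecting
  attenuation-corrected effects was rejected as it would misstate the
  latent world.
* With several nonzero pathways, the per-specification marginal β is a
  blend of the configured direct paths (the technology measures are
  correlated through T); single-pathway injections are the intended use for
  parameter-recovery work.
* The flat config dialect covers scalar and per-day/per-pathway keys, not
  the loading or cutpoint structures; those are R-level configuration.
* The before-bed window at the fallback onset (s = 1) is the last three
  in-scale slots; for adolescents genuinely awake past 4 AM the window is
  right-censored like everything else in the diary day.
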