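---
title: "Personalised PHQ-2 forecasting from mobile sensing: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Personalised PHQ-2 forecasting from mobile sensing: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moodcast)
```

`moodcast` implements a complete pipeline for predicting and forecasting
daily depressive-symptom scores (PHQ-2, 0–6) of patients in a digital
depression intervention, from raw smartphone event streams and ecological
momentary assessments (EMA), with three personalisation strategies and
regression-fairness indices. Because clinical mobile-sensing datasets are
access-restricted, the package ships a synthetic-cohort simulator that
reproduces the statistical structure the analysis relies on; every stage is
tested against it.

## The data model

One subject contributes, over an observation window of about 8 weeks:

* **passive streams** — GPS fixes (5-minute cadence), a call log, screen
  lock/unlock events, and app-usage events;
* **active assessments** — affect EMA three times a day (*happy*, *active*,
  *tense*, *sad*, each 0–6), an end-of-day diary (CES-D, BADS-SF, PSQI and
  PDD items), a daily PHQ-2, and a weekly PHQ-9.

From the passive streams, 19 daily features are computed in four groups
(GPS mobility, communication, phone usage, user activity), and the active
data contribute daily EMA means, positive/negative-affect composites and
the diary items — 35 daily feature columns in total (`feature_columns()`).

## The synthetic cohort

Each subject $i$ carries a latent severity trajectory on the PHQ-2 scale,

$$ s_i(t) = b_i + m_i\,t + e_i(t), \qquad
   e_i(t) = \varphi\, e_i(t-1) + \varepsilon_{it}, $$

which drives everything observable: daily PHQ-2 is
$\mathrm{round}(\mathrm{clip}(s_i(t), 0, 6))$; weekly PHQ-9 maps the weekly
mean of $s_i$ onto 0–27; EMA and diary ratings are a subject-specific
affine map $o_i + c_i\, s_i(t)$ plus noise, clipped to the scale (negative
affect increasing in severity, positive affect decreasing); daily excursion
counts and call rates decrease with severity; app/screen streams contain a
per-subject nightly gap (mean 23:30–07:00) so that the sleep rule recovers
a known truth.

The default parameters are the package's statement of the study conditions
it emulates, and deserve justification:

* **Severity dynamics** (`baseline_mean = 3.0`, `baseline_sd = 0.5`,
  `trend_mean = -0.02`, `ar_coefficient = 0.7`, `noise_sd = 1.0`). The
  cohort is a *treatment* cohort: subjects enter with elevated symptoms
  (an inclusion criterion compresses the entry spread) and improve
  heterogeneously over 8 weeks. The split of variance is deliberately
  within-subject-dominated (intraclass correlation ≈ 0.15–0.2): pooled
  daily PHQ-2 SD comes out near 1.6, while day-to-day swings are large.
  Three observable constraints pin this down: the pooled PHQ-2
  distribution of such cohorts; the fact that one-day-ahead forecasting is
  genuinely hard (large innovations); and the fact that a model denied all
  absolute-level information (see SDS below) can still be competitive on
  absolute error — which is arithmetically impossible if stable
  between-subject differences dominate.
* **Response styles** (`response_offset_sd = 0.7`,
  `response_scale_sd = 0.4`). Subjects differ in where and how widely they
  use a 0–6 rating scale; the offset and (log-normal) scale apply to all
  EMA and diary items of a subject. This is the heterogeneity that makes
  subject-dependent standardisation meaningful.
* **Behavioural baselines** (`behaviour_offset_sd = 1.5`). People differ
  in how mobile and communicative they are for reasons unrelated to
  depression, with person-level variation at least as large as the
  severity-driven within-person shifts. Consequently absolute sensor
  levels do not rank subjects by severity — only within-subject change is
  informative, as in real digital-phenotyping data. Without this, a
  population model could read severity straight off the GPS feature level,
  which no real cohort permits.
* **Missingness** (`missing_day_rate`, `missing_feature_rate`, both 0 by
  default). Day-level loss removes all streams *and* labels of a
  subject-day; stream-level loss removes single streams of observed days.
  The cohort records dropped (date, stream) pairs so extraction can
  distinguish "stream lost" (missing features) from "no events occurred"
  (zeros) — a distinction real pipelines must make and naive ones botch.

What the generator does **not** emulate: physiologically realistic GPS
trajectories (transit is instantaneous between stay points), weekday/
weekend structure, measurement reactivity, or intervention *content*
effects. Tests passing on this cohort therefore certify the pipeline's
arithmetic and its comparative behaviour under heterogeneity — not
clinical performance on real patients.

## Feature extraction choices

Significant places are clusters of GPS fixes with cumulative dwell of at
least 10 minutes. The primary clustering is deterministic time-based
stay-point detection (distance threshold 100 m, time threshold 10 min);
DBSCAN (50 m, grid-accelerated) and k-means (k by mean silhouette over
2–8) are available behind the `clustering` switch. Dwell is accumulated
over consecutive same-place fix intervals, capped at 30 minutes so data
gaps do not inflate it. Home is the place with maximal 00:00–06:00 dwell
across the study (ties to the smaller id; a no-overnight-data fallback to
overall maximal dwell is flagged).

Conventions the feature definitions leave open were fixed as follows:
entropies use natural logarithms (the normalised variants divide by a log
of the same base, so the choice cancels); `location_variance` guards the
degenerate single-fix day with $\ln(\mathrm{var} + 10^{-10})$; "working
hours" are 08:00–18:00 local time; distance segments implying more than
200 km/h are treated as GPS jumps and dropped; days are calendar days in
naive local time; sessions crossing midnight are split, the post-midnight
part counting toward the next day's usage duration but not its session
count; `lock_screen_duration` is defined as the complement of usage
duration within 24 h. Sleep is the gap between the last app use of the
previous day (or of the same day before 02:00, if any) and the first use
after 05:00, and is missing when either endpoint is unobserved.

## Quality criteria and windowing

Three criteria are applied in sequence: (1) a subject-day is valid only if
strictly less than 20% of the feature columns are missing; (2) a PHQ label
is kept only if at least 5 of the 7 days of its window are valid; (3) a
subject is kept only with at least 10 retained PHQ-2 and 5 retained PHQ-9
labels. The criterion-2 window for the prediction task is read as the 7
days ending on the label day (the model's own input window); for
forecasting it is the 7 days before. Both readings of "the week prior" are
defensible; the switch `prediction_includes_label_day` selects the other
one. PHQ-9 enters only through criterion 3 — the modelled target is PHQ-2.

Missing cells inside a retained 7-day window are filled with the mean of
that feature over the window's observed days. A feature absent on all 7
days falls back to the subject's past-only mean (days up to the label
date), then to the population past-only mean, and is flagged. Past-only
fallbacks were chosen over training-fold statistics because imputation
runs before the cross-validation split exists; causally restricted means
are leak-free under every subsequent split. Windows are fixed-length
(7 × 35) rather than variable-length with masking: criterion 2 guarantees
at least 5 real days and the recurrent model consumes a fixed block.

## Models

The regressor is a 2-layer GRU (hidden size 30) over the 7 daily feature
vectors (oldest first), followed by a 30-unit fully connected ReLU layer
with 20% dropout after it and a linear output neuron. Training minimises
MAE with Adam (learning rate 0.01, batch size 8) for 100 epochs; the
returned state is the epoch with the best development-set MAE. The
implementation is in C++ (RcppArmadillo) with its own deterministic RNG,
so a fixed seed gives bit-identical parameters regardless of R's RNG
state; gradients are verified against central finite differences in the
test suite, and the parameter count against the closed form
$3(dh + h^2 + 2h) + 3(2h^2 + 2h) + (h f + f) + (f + 1)$.

The four strategies:

* **baseline** — one model for everyone, population-standardised inputs.
* **transfer learning** — the baseline's GRU layers are frozen as a shared
  backbone; the FC + output head is fine-tuned separately per subject
  (same protocol, epoch selected on the subject's development windows),
  continuing from the pretrained head weights rather than re-initialising
  (the more conservative reading; a frozen backbone lets the
  implementation cache the recurrent representation, which makes
  per-subject fine-tuning exact and cheap).
* **subgroup** — one baseline-architecture model per sex, routed at
  inference.
* **SDS** — one common model, but inputs z-scored per subject
  (statistics from that subject's training windows only). SDS removes all
  absolute-level information by construction: its predictions of the
  *absolute* PHQ-2 can only carry the population level plus within-subject
  structure. It therefore shines exactly when feature levels are
  incomparable across subjects.

Standardisers are always fitted on training windows only; features with
zero training variance map to 0. Dropout is active only during training;
output clipping to [0, 6] is available for deployment-style reports but
off for metric computation.

## Evaluation

Cross-validation is subject-dependent: each subject's windows are split
into three chronological segments; each round holds one segment out as
test and splits the rest per subject 80/20 (chronologically; the most
recent 20% is development). Every subject appears in train, development
and test of every round — the property the personalised strategies need.
Chronological rather than random segmentation preserves temporal order for
the forecasting task; random assignment is available via
`chronological = FALSE`. Test predictions are pooled over the three rounds
before computing metrics.

Metrics: MAE; global Spearman's ρ; and local Spearman's ρ — the unweighted
mean of per-subject coefficients, with subjects whose correlation is
undefined (constant targets or predictions) excluded and counted. Average
ranks handle ties. A random-forest screen (50 trees, impurity importances
normalised to sum 1) reports which daily features carry PHQ-2 signal.

## Fairness

Group level (both ideally 0): the *sex fairness score*
$\mathrm{MAE}_\mathrm{female} - \mathrm{MAE}_\mathrm{male}$ and the *sex
fairness bias*
$\overline{(\hat y - y)}_\mathrm{female} - \overline{(\hat y - y)}_\mathrm{male}$,
computed over pooled windows. Individual level, on the vector of
per-subject MAEs: the Gini coefficient
$\sum_{ij} |\mathrm{MAE}_i - \mathrm{MAE}_j| \,/\, (2 n^2\, \overline{\mathrm{MAE}})$
(defined as 0 when the mean MAE is 0, where the formula is 0/0), and the
distance-to-median indices DMLI/DMUI — sums of distances to the median
per-subject MAE over subjects strictly below/above it (even-sized cohorts
use midpoint medians; subjects exactly at the median contribute to
neither). DMLI rewards how far the best-served subjects pull ahead of the
typical one; DMUI caps how far the worst-served fall behind.

## Problem sizes and numerical choices

The shipped tests exercise cohorts of up to 20 subjects × 56 days — the
size of the emulated study — with the full 100-epoch protocol for the
comparative experiments and shorter protocols where only contracts
(determinism, routing, shapes) are at stake; the networks are small enough
that a full four-strategy, two-task experiment runs in minutes on one
core. Noteworthy numerical conventions: seeded determinism end-to-end
(cohort, splits, initialisation, batch order, dropout); ties in home
inference and fold arithmetic broken deterministically; the criterion-1
threshold is strict (`< 20%`), so 5 missing of 24 features invalidates a
day; clustering methods that involve randomness (k-means restarts, forest
bootstraps) take explicit seeds.

## Known limitations

The generator's behavioural links are linear with hand-set slopes, and its
missingness is completely at random, whereas real non-response correlates
with symptom severity; the comparative results among strategies are
reproduced qualitatively (who beats whom, and why), not as calibrated
effect sizes. Timestamps are naive local time: daylight-saving
transitions and timezone travel are out of scope. The fairness analysis
covers biological sex only, as the single group variable the emulated
study records.
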