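---
title: "Validating nocturnal-scratch DHTs against a human video reference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating nocturnal-scratch DHTs against a human video reference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scratchval)
library(dplyr)
```

## The problem

Nocturnal scratching is a direct behavioral readout of itch in atopic
dermatitis (AD), and several digital health technologies (DHTs) — wrist
accelerometers and touchless radio-frequency sensors — claim to measure it
during sleep at home. Before such a device can serve as a clinical-trial
endpoint, its outputs must be validated analytically against a trustworthy
reference. The reference here is human annotation of infrared video:
raters mark the start and end of every scratching episode and of the total
sleep opportunity (TSO) window, and a consensus procedure turns multiple
raters into a single Reference annotation.

`scratchval` implements that validation pipeline end to end, together with
a synthetic-study generator that produces ground truth, rater streams and
device streams with known error parameters, so that every stage of the
pipeline can be tested against a known answer.

## Data model

Everything is built on half-open intervals `[start_s, end_s)` measured in
real-valued seconds from a per-night origin (noon of the evening the night
begins). Half-open semantics make adjacency unambiguous: an event ending at
`t` and one starting at `t` share no time, and durations add exactly. The
noon origin keeps all within-night times positive and monotone across
midnight, and confines calendar arithmetic to the I/O layer.

A long events table (`participant_id`, `night_id`, `source`, `kind`,
`start_s`, `end_s`) is the universal currency; `kind` distinguishes
`scratch`, `sleep_period` and `tso` rows, and `source` distinguishes the
raters (R1–R5), the devices, and the consensus `Reference`.

## The pipeline

1. **Consensus.** Per night (or per motion segment, when a `segment_id`
   column is present), raters R1 and R2 reach consensus when the
   intersection-over-union (IoU) of their scratch annotations *strictly
   exceeds* 0.765; the consensus annotation is the interval-set
   intersection of their labels. Failing that, R3 and R4 repeat the
   exercise (round 2), and failing that R5 decides alone (round 3). Two
   empty annotations have IoU 1 — agreeing that nothing happened is
   agreement, not a degenerate case. TSO consensus: if both endpoints of
   the two raters' TSO labels agree within 60 s the endpoints are averaged
   (averaging is symmetric and unbiased; taking one rater would be
   arbitrary), otherwise a third rater adjudicates verbatim.
2. **TSO.** Device sleep periods separated by gaps strictly under 30 min
   are merged; if several merged periods remain, the longest is the
   night's TSO (the natural main rest period — the merge rule usually
   leaves only one). Any TSO shorter than 3.5 h is excluded, per source:
   a night can be kept for the Reference and dropped for one device.
3. **Bouts.** Scratch events with gaps strictly under 3 s are merged into
   bouts, then bouts shorter than 2 s (inclusive boundary: exactly 2 s is
   kept) are dropped — in that order, for every source alike.
4. **Epoch scoring.** Within the intersection of the Reference and device
   TSO windows, non-overlapping 10 s epochs (1 s for the sensitivity
   analysis) are labeled positive when any part of a scratch event
   overlaps them. Confusion counts are pooled across nights and
   participants *before* computing sensitivity, precision, F1, balanced
   accuracy and prevalence (micro-averaging; no class rebalancing). The
   10 s width is itself the mitigation for imperfect clock
   synchronization between devices and video, so no clock correction is
   applied here.
5. **Night outcomes.** Scratch duration (s per h of TSO) and frequency
   (bouts per h of TSO); participant summaries are offset geometric means
   `exp(mean(log(x + 1))) - 1`; groups are summarized by medians and IQRs
   on the linear scale. Morning itch ratings (0–10 NRS) filtered to the
   4 AM–12 PM validity window stratify nights into itch bands.
6. **Agreement.** TSO duration: repeated-measures Bland–Altman — the
   per-night difference gets a participant random intercept, the bias is
   the model intercept, and the 95 % limits are
   `bias ± 1.96·sqrt(var_between + var_within)`. Scratch outcomes: a
   linear mixed model on the log scale with a fixed source effect, a
   participant random intercept, and a night-within-participant random
   intercept; the ICC is `(σ²_participant + σ²_night) / (σ²_participant +
   σ²_night + σ²_residual)`. Confidence intervals come from a
   participant-level (cluster) bootstrap with 500 resamples.

## Numerical and design choices

Several points are genuinely open in a specification of this kind; the
package resolves them as follows and exposes each as a parameter.

* **Strictness of thresholds.** "Gap < 3 s", "TSO < 3.5 h" and
  "difference > 1 min" are strict; "at least 2 s" and the PRO window
  "between 4 AM and 12 PM" are inclusive. Consensus requires IoU
  *strictly above* the threshold.
* **Epoch anchoring.** Epoch grids are anchored at the start of each
  night's TSO intersection, not at clock boundaries, and a trailing
  partial epoch is discarded so pooled epochs are all the same length.
* **Zero handling on the log scale.** Zero-scratch nights are real and
  must stay in the analysis; logs and geometric means use a configurable
  offset δ (default 1 in original units).
* **Zero denominators.** Metrics whose denominator is empty (e.g.
  precision when a device never fires) are reported as `NA` with a
  warning — never coerced to 0 or 1.
* **Itch bands.** NRS 0 / 1–3 / 4–6 / 7–10, the conventional severity
  banding; edges are configuration.
* **Variance-component fitting.** `fit_variance_components()` fits REML
  via `lme4`; for balanced designs it also offers the closed-form
  balanced-ANOVA ("moment") estimator, which coincides with REML there
  and is orders of magnitude faster. The bootstrap engine picks the
  moment path automatically when every resampled design is balanced
  (participant resampling preserves balance), and falls back to `lme4`
  otherwise. Components are constrained non-negative; boundary fits are
  valid. Non-convergent fits are flagged with their diagnostics, never
  silently replaced.
* **Both ICC definitions.** "Absolute agreement" arguably charges
  systematic source offsets against the ICC, so the unadjusted variant
  (fixed-effect variance added to the denominator) is always computed
  alongside the adjusted one; the adjusted definition is the default
  reported value, matching the convention of the variance-components
  software this analysis style comes from.
* **Bootstrap unit.** The resampling unit is the participant. Nights are
  repeated measures of participants; resampling nights would break the
  dependence structure the mixed model exists to respect.

## The synthetic study

`study_config()` defaults describe the emulated study: 5 healthy
volunteers, 9 mild AD and 14 moderate AD participants, 8 nights each.
Ground truth per night: a TSO drawn around 23:00 with mean duration 8 h,
and scratch bouts as a homogeneous Poisson process over the TSO whose rate
and mean bout duration carry lognormal participant and night random
effects. Cohort calibration targets the medians 2.4 / 3.51 / 4.64 bouts
per hour and 13.1 / 17.4 / 30.0 s per hour (HV / mild / moderate); bout
durations are 2 s plus a lognormal excess whose mean is set so that
duration/frequency ratios match, which also keeps true bouts above the
≥2 s filter. Log-scale variance components default to moderate
heterogeneity (participant 0.09, night 0.04 for frequency; 0.12 / 0.05
for duration — the duration outcome is rate × mean bout length, so its
components are composed as frequency components plus independent
bout-length components sized as the difference). These values keep the
implied ICCs in the moderate-to-good band while leaving cohort medians
recoverable at the study's cohort sizes.

Raters are exchangeable by default: each misses a bout with probability
0.02, jitters kept endpoints by 0.2 s SD (inverted draws are resampled,
not clipped), and adds ~0.1 spurious bouts per hour; TSO labels get 20 s
endpoint jitter, which sends a few percent of nights to the adjudicator.
Devices detect bouts with a logistic probability in bout duration and
differ by preset: the Emerald-like preset has balanced errors, the
Philips-like preset is deliberately oversensitive (3 spurious bouts/h) so
that precision falls below sensitivity, mirroring an oversensitive
actigraphy algorithm. Device sleep periods are the true TSO with Gaussian
endpoint errors whose biases were chosen to yield TSO duration biases of
+0.44 h (Emerald-like) and +0.42 h (Philips-like) with limits of
agreement near (−1.85, 2.73) h; occasional mid-night splits (gap < 30
min) exercise the sleep-period merge rule without altering the derived
window. Morning itch is a monotone noisy map of the night's true bout
rate, so no-itch nights have genuinely lower scratch rates; HVs do not
complete the PRO.

What the generator does *not* emulate: within-night temporal structure
(scratching clusters in real data), correlated rater errors (raters see
the same ambiguous video), device error that depends on posture or
bedding, and informative missingness of video. Passing tests therefore
demonstrate the *pipeline's* correctness and the statistics' calibration,
not any claim about real device performance.

A closed-form twin, `analytic_icc()`, returns the ICC implied directly by
the configured components. For the event-level generator the residual
disagreement between sources is emergent from the error models rather
than set directly, so exact ICC recovery is checked with the
outcome-level simulator `simulate_vc_data()`, and the event-level path is
checked through identity and monotonicity properties instead.

## Worked example

```{r example, eval = FALSE}
study <- simulate_study(study_config(seed = 1))
report <- run_pipeline(study, pipeline_config(n_boot = 200, seed = 1))
report$metrics_cohort
report$bland_altman_table
subset(report$icc_table, definition == "adjusted")
autoplot(report$bland_altman$Emerald)
plot_icc_comparisons(report$icc_table)
plot_outcomes(subset(report$participant_summaries, source == "Reference"))
```

## Problem sizes used in the tests

The test suite exercises the algebra against a 0.01 s-grid rasterization
oracle on 1000 random tracks; runs the full zero-noise study (28 × 8
nights) through the pipeline and requires perfect scores everywhere; and
checks parameter recovery at study scale — 50 replicates for ICC point
recovery and Bland–Altman recovery, 200 replicates × 500 bootstrap
resamples for CI coverage, and ≥20 replicates for each error-model
monotonicity property. Generator calibration is verified by pooling
nights over eight replicate studies, which estimates the generator's
medians with a few percent of Monte-Carlo error against the ±20 %
calibration band.

## Known limitations

* The consensus and TSO rules assume at most one TSO per night and night
  assignment already done (noon-to-noon); fragmented reference recordings
  are out of scope.
* The moment estimator requires a balanced design; unbalanced data fall
  back to `lme4` REML, which is slower in the bootstrap.
* The proprietary device detection algorithms are not modeled — device
  streams are inputs (or synthetic presets), and nothing here estimates
  what a real device would do.
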