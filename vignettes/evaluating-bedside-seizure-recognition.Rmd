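---
title: "Evaluating bedside recognition of neonatal seizures against a dual-expert EEG consensus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating bedside recognition of neonatal seizures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cotside)
```

## The evaluation problem

Neonatal electrographic seizures are defined on continuous multichannel EEG
(cEEG) as at least 10 s of evolving, repetitive stereotyped waveforms; most
have no reliable clinical signs. In a two-arm multicentre trial of
seizure-detection decision support, the question is not whether a detector
fires but whether the *bedside clinical team* recognises seizures, hour by
hour, and treats appropriately. `cotside` implements the complete
evaluation machinery for that design:

1. a dual-expert annotation consensus that defines the gold standard;
2. hour-binned scoring of the clinical record against that gold standard;
3. diagnostic-accuracy statistics with cluster-stratified bias-corrected
   bootstrap confidence intervals and post-hoc logistic interaction tests;
4. a synthetic cohort generator, so that every stage is testable without
   access to the (non-shareable) trial recordings.

## The consensus gold standard

Each recording is annotated independently by two experts as a list of
`[start_s, end_s)` intervals. The final annotation is the set-intersection
of the two annotations, and an electrographic seizure is *confirmed* when
an intersection segment lasts at least 30 s. The 30 s confirmation
threshold sits deliberately above the 10 s seizure definition: inter-expert
agreement on very short events is known to be poor, and requiring 30 s of
overlapping annotation strengthens the gold standard.

Decisions that the published rules leave open, resolved here:

* **Inclusive threshold.** "An overlap of 30 s" is read as `>= 30 s`
  (a segment of exactly 30 s is confirmed); the threshold is exposed as
  `min_overlap_s` in `confirm_events()` and `run_pipeline()`.
* **Confirmed-event extent.** A confirmed event is the intersection
  segment itself — not either annotator's extent and not the union —
  because the final annotation is defined as the periods during which the
  two annotations overlapped. Burden summaries are computed over these
  intersection extents, and sub-30 s overlap periods contribute nothing.
* **One-vs-many overlaps.** One long event in annotation A overlapping two
  separate events in B produces two intersection segments, each tested
  against the 30 s rule independently.
* **Exactly two annotators** are in contract; a neonate with no events
  from one annotator has an empty (not missing) annotation.

Hour bins are consecutive 60-minute windows anchored at recording start
(`[3600k, 3600(k+1))`, index 0). The recordings themselves are the
time base; nothing in the definitions requires wall-clock alignment, and
recording-anchored bins keep the pipeline self-contained. An `offset_s`
parameter allows wall-clock alignment when wanted. The final partial hour
is a valid bin and its burden is reported as the actual overlap in min/h,
without rescaling. A seizure spanning a bin boundary makes both hours
seizure hours. Interval arithmetic is floating point with a 1 ms
tolerance: touching segments merge, and degenerate sub-millisecond
segments are dropped.

Per-neonate burden summaries (`burden_summary()`): total seizure burden
(min), maximum hourly burden (min/h), and median confirmed event duration
(s; absent when no events — the even-count median is the midpoint of the
two central values).

## Scoring the clinical record

The bedside team completes an hourly seizure record form; antiseizure
medication (ASM) administrations are logged per hour (sub-hour timestamps
are floored to their bin, since every rule is stated at hour granularity).
The trial's rules, implemented verbatim in `score_hours()`,
`classify_neonate_clinical()` and `inappropriate_asm()`:

* a neonate is clinically identified as a seizure neonate if any hour is
  form-marked or any therapeutic ASM dose is given;
* a gold seizure hour H is *identified* if the form is marked or ASM given
  in H or H+1 (an H+1 beyond the end of the record contributes nothing);
* a form-marked hour H is a *false detection* if no confirmed seizure
  occurred in H or H−1 (the H−1 clause is skipped at H = 0);
* an ASM dose at hour H is *inappropriate* if no confirmed seizure
  occurred in H or H−1.

The false-detection denominator counts form-marked hours only;
medication-only identifications enter the identification rule but not that
denominator. A medication in hour H+1 does not rescue a form false
detection at H: false detection is defined by form marks and expert
annotation alone, and is implemented exactly as stated. Missing hour rows
are treated as blank with a logged warning (forms could be incomplete; the
medication rule compensates). The optional `asm_therapeutic` column lets
users exclude maintenance doses from the neonate-level rule.

## Accuracy statistics

Neonate-level metrics from the confusion counts: sensitivity
`100·tp/(tp+fn)`, specificity `100·tn/(tn+fp)`, and false detection rate
`100·fp/(fp+tp)` (the share of clinically positive neonates without
seizures). Hour-level: sensitivity `100·identified/gold` and the form
false-detection rate `100·false/marked`. All intermediates are kept at
full precision; one-decimal rounding, half away from zero, is applied only
by `format_report()`. Undefined metrics (zero denominator) are `NA`, never
`NaN`.

### Bias-corrected cluster bootstrap

Randomisation was stratified by hospital and hours cluster within infant,
so interval estimation resamples *neonates* within the 16 group-by-hospital
clusters (simple random sampling with replacement, cluster sizes preserved
exactly), pools the resample, and recomputes the statistic; B = 100 000 in
the confirmatory setting. The interval is bias-corrected (BC, not BCa —
no acceleration constant, matching the stated method): with
\(\hat\theta\) the point estimate from the original data and
\(p = (\#\{\theta^*_b < \hat\theta\} + \tfrac12\#\{\theta^*_b =
\hat\theta\})/B\),

\[ z_0 = \Phi^{-1}(p), \qquad
   \alpha_{1,2} = \Phi(2 z_0 + z_{\alpha/2}),\ \Phi(2 z_0 + z_{1-\alpha/2}), \]

and the endpoints are the \(\alpha_1,\alpha_2\) quantiles of the bootstrap
distribution. Numerical choices:

* ties count half in \(p\), so \(z_0\) stays finite on discrete
  statistics; \(p\) is clamped to \([1/(B{+}1), B/(B{+}1)]\) with a
  warning when the rank degenerates;
* quantiles are type-1 order statistics (`sorted[ceiling(aB)]`), so the
  exhaustive-enumeration oracle is reproducible exactly;
* resamples on which the statistic is undefined (e.g. no seizure neonate
  drawn) are dropped and counted;
* `force_z0_zero = TRUE` collapses the interval to the plain percentile
  interval, an internal consistency switch used by the tests;
* the default B in `run_pipeline()` is 2 000: BC endpoints stabilise well
  below 100 000, which keeps exploratory runs and the test suite fast —
  confirmatory runs should set `bootstrap_config(n_iter = 1e5)`.

Between-group differences reuse the same machinery on the per-iteration
difference of group statistics (`difference_ci()`).

### Interaction tests and sample size

The post-hoc weekday/weekend and day/night-shift contrasts are tested with
a logistic model over per-gold-hour rows,
`identified ~ group * period`, fitted by IRLS (`stats::glm`), reporting a
Wald p-value for the interaction coefficient. The published analysis does
not state the test; Wald is the common default of the era's software. The
model treats hours as independent; the within-infant clustering caveat is
recorded in the result object.

`required_seizure_neonates()` implements the standard two-sample
normal-approximation size
\(n = 2 (z_{1-\alpha/2}+z_{1-\beta})^2 \sigma^2/\delta^2\): with a 25-point
detectable difference, SD 35, power 80 % and two-sided 5 % it yields 31
seizure neonates per group, whereas the trial reported 33 from an unstated
routine; the function returns the formula value and this discrepancy is
documented rather than reconciled. `required_group_size()` then inflates by
expected seizure prevalence: 33/0.40 → 83 monitored neonates per group,
revised to 33/0.25 → 132 when interim annotation showed 25 % prevalence.

## The synthetic cohort generator

`generate_cohort()` emulates the *published marginals* of the trial
population, not its raw data:

* two arms of 130 neonates over 8 hospitals (clusters = group × hospital),
  hospitals filled evenly, seizure prevalence 25 % / 29 %;
* log-normal monitoring duration, median ≈ 50 h, clamped to 2–100 h (the
  protocol's monitoring window);
* seizure neonates receive bouted event trains (negative-binomial event
  count with mean ≈ 20; log-normal event durations with median 105 s;
  exponential within-bout gaps, Poisson bout splitting, long inter-bout
  gaps). These targets give median total burden in the tens of minutes and
  maximum hourly burden near 13 min/h, matching the reported burden
  summaries. The temporal law itself is unpublished, so the bout model is
  a modelling choice exposed in `cohort_config()`;
* two imperfect annotators: independent Gaussian boundary jitter
  (SD 5 s), misses confined to events shorter than 60 s (probability
  0.15 — agreement on long seizures is good), and spurious short events
  (0.03/h, 10–40 s), calibrated so that sub-30 s consensus losses occur
  and the confirmation rule is genuinely exercised;
* hour-level recognition follows a logistic curve in log hourly burden
  (recognition improves with burden, reproducing the qualitative shape of
  the published burden-stratified detection figure), with a weekend
  log-odds offset (−0.4) and per-group intercepts;
* false marks concentrate in neonates under raised clinical suspicion
  (all seizure neonates with probability 0.5, non-seizure neonates with
  probability 0.15, at 0.08 marks per non-seizure hour; background
  0.001/h), and ASM follows marks (probability 0.5 on a true-context mark,
  0.2 on a false mark) plus a 0.001/h background. These rates were chosen
  once so that inappropriate-ASM proportions land near the reported
  30–40 % of seizure neonates and ≈ 10 % of non-seizure neonates.

The latent truth (events, hourly burden, detection probabilities) is
emitted alongside the data and is never consumed by the pipeline.
Everything is deterministic given `seed`: identical configurations produce
byte-identical CSV files.

### Calibrating a planted group effect

`plant_group_effect(config, s_A, s_B)` sets the per-group intercepts so
the *expected* hour-level sensitivity equals the planted targets. A gold
hour H is identified when H or H+1 carries a flag, so its identification
probability is \(1-(1-r_H)(1-r_{H+1})\), with \(r\) the per-hour flagging
probability (the recognition mark for gold hours; the
suspicion-mixture false-mark rate for non-gold hours; background ASM
everywhere). The calibration simulates a large reference population of
seizure-hour structures (3 000 seizure neonates by default) under an
internal seed, evaluates this expression as a function of the intercept,
and inverts it by root finding. The targets refer to the confirmed
(≥ 30 s) gold standard under faithful annotation; the parameter-recovery
and coverage checks therefore use noise-free annotators
(`perfect_annotators()`), so the pipeline's gold standard coincides with
the calibration's and the detection model is isolated from annotation
noise. The default intercepts in `cohort_config()` (−2.00, −2.96) were
frozen from one such calibration targeting the published sensitivities
0.66 and 0.453.

### What the generator does not capture

No EEG waveforms, detector probability traces, artefacts, or paused
recordings; no diagnosis-specific seizure phenotypes or hypothermia
physiology; annotator errors are independent between experts (real experts
share systematic biases); suspicion is a two-level mixture, which
reproduces neonate-level specificity and the ASM proportions but leaves
the *hour-level* form false-detection rate above the reported one — the
real record's false marks are sparser per suspected neonate than this
model's. Passing tests therefore demonstrate correctness of the evaluation
machinery under a faithful-marginal simulation, not fidelity of any
individual synthetic record.

## Problem sizes used by the test suite

The suite runs the consensus oracle on 200 randomised annotation pairs,
enumerates all 512 gold/mark/ASM placements on 3-hour records, validates
the BC interval against an exhaustive 27-resample enumeration, checks
95 % interval coverage of the planted 21-point contrast over 100 seeded
trials at B = 2 000, recovers the planted contrast over 50 seeds, and
checks Wald-p uniformity over 1 000 null replicates. These sizes were
chosen as the smallest at which each property is sharp (binomial bands,
KS at 1 %); the confirmatory bootstrap size remains 100 000 in
`bootstrap_config()`'s default.

## Known limitations

* Burden is computed over intersection extents; if a study instead uses a
  designated annotator's extents after confirmation, totals will differ
  slightly (the published definition supports the intersection reading).
* The bootstrap requires every cluster to be non-empty; single-neonate
  clusters are carried through deterministically.
* The interaction model is unadjusted for within-infant clustering of
  hours, as published; its p-values are anti-conservative when hours
  within an infant are strongly correlated.
* Confidence intervals and interaction p-values from the real trial
  depend on individual-level data that are not shareable; the package
  reproduces point estimates exactly and validates its interval machinery
  by construction (enumeration, coverage, null calibration) instead.
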