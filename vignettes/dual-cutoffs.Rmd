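---
title: "Cut-off strategies and dual cut-offs for discrete cognitive screening scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cut-off strategies and dual cut-offs for discrete cognitive screening scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screendx)
```

## The problem

Cognitive screening instruments such as the MoCA (Montreal Cognitive
Assessment) and the MMSE (Mini Mental State Examination) produce discrete
integer scores from 0 to 30, with lower scores indicating more impairment. In
a memory clinic, such a screen must separate patients with a neurocognitive
disorder (NCD) — mild NCD, roughly mild cognitive impairment, and major NCD,
roughly dementia — from people whose cognition is normal. Two reference groups
matter and behave differently: community-recruited normal controls (NC), and
clinic patients whose full diagnostic workup yields normal findings (NF). The
NF group is the clinically realistic comparison, because those are the people
who actually sit in the waiting room.

A single cut-off on a discrete score cannot be both sensitive and specific
when the patient and control distributions overlap: moving the threshold up
by one point trades a block of false positives against a block of false
negatives, with nothing in between. `screendx` implements the standard
single-cut-off strategies, the supporting ROC and inference machinery, and a
dual-cut-off procedure that makes the trade-off explicit instead of hiding
it: two thresholds with an *indecisive area* between them, in which the screen
abstains and defers to further examination.

## Conventions

Throughout the package the orientation is fixed: **lower score = impaired**,
and a cut-off written `t/(t+1)` classifies scores `<= t` as positive. All
proportions are carried at full precision; display formatting rounds
percentages half away from zero (so a correct classification rate of 78.5%
prints as 79%), via `format_percent()`.

Derived measures follow the screening literature:

* sensitivity `= TP / (TP + FN)`, specificity `= TN / (TN + FP)`;
* Youden's index `J = sensitivity + specificity - 1`;
* correct classification rate `CCR = (sensitivity + specificity) / 2`, the
  accuracy under equal group weighting, so `CCR = (J + 1) / 2` identically.

## Single cut-off strategies

`metrics_at_all_thresholds()` evaluates the confusion table at every grid
threshold (`-1..30` for integer scores — the anchors where sensitivity is 0
and specificity is 1 — or the observed values for continuous z-scores). On
top of that table:

* **fixed** (`fixed_cutoff()`): a pre-specified literature threshold, for the
  MoCA the originally proposed 25/26;
* **balanced** (`balanced_cutoff()`): minimises
  `|sensitivity - specificity|`;
* **Youden** (`youden_cutoff()`): maximises `J`, weighting false positives
  and false negatives equally;
* **percentile-in-controls** (`percentile_cutoff()`): ignores patients
  entirely and places the threshold at the lower `q`-quantile (default the
  10th percentile) of the control scores, targeting specificity of about
  `1 - q`; the threshold is then validated in the clinic contrast.

Tie-breaking in the balanced and Youden searches goes to the *lower*
threshold, i.e. the higher-specificity side — in screening, a false positive
sends a healthy person into an invasive diagnostic workup, so when two
thresholds are otherwise equivalent the one that flags fewer healthy people
wins. The percentile quantile uses the linear-interpolation convention
(`stats::quantile` type 7) followed by flooring; the stricter
"largest threshold with cumulative frequency below q" rule would
systematically land one point lower on realistic control distributions and
disagree with how percentile cut-offs are reported in practice. A published
balanced cut-off can disagree with the strict arg-min by one point when the
printed percentages round ambiguously; `screendx` always applies the strict
rule and leaves the reconciliation to the reader.

ROC analysis uses the Mann-Whitney AUC (ties counted one half, computed via
midranks), which is exactly the trapezoidal area under the empirical ROC
polygon; `compare_auc_paired_bootstrap()` compares two markers measured on
the same subjects by resampling subjects with replacement *stratified by
class* — per-class sample sizes are preserved in every replicate — and
standardising the observed AUC difference by the bootstrap SD of the
difference, with a two-sided normal p-value. The default of 2000 replicates
is the common choice for this test; the DeLong variance method is deliberately
out of scope because the bootstrap route is the one named for this design.

## The dual-cut-off procedure

`cumulative_curves()` computes, for every score `s`, the cumulative fraction
of patients at or below `s` (sensitivity of cut-off `s/(s+1)`) and the
complementary cumulative fraction of controls above `s` (its specificity).
`find_dual_cutoffs()` then reads the two curves at *different* scores:

* the **not-healthy** cut-off `lower_t` is the largest score at which
  specificity still meets its target — scores this low are rare among healthy
  controls, so such a result is probably pathological;
* the **not-pathological** cut-off `upper_t` is the smallest score at which
  sensitivity meets its target — scores above it are rare among patients, so
  such a result is probably normal;
* scores in `lower_t + 1 .. upper_t` form the **indecisive area**: the screen
  abstains and the decision moves to further examination.

The analogy is to z-score-based normative reasoning: a distribution of scores
is assumed for each population, and values extreme *for that population* are
treated as improbable under it. Raising both targets widens the indecisive
band monotonically; the package tests assert this.

Two selection rules are provided because prose descriptions of "approximately
90%" targets are ambiguous. The default `"strict"` rule requires the achieved
value to be at least the target. The `"nearest"` rule instead picks the score
whose achieved value is closest to the target, which can land one point lower
when the achieved value just misses (e.g. accepting 88% specificity against a
90% aim). Both are deterministic; the choice is recorded in the result.

When the groups separate completely the two cut-offs cross (`lower_t >
upper_t`); the indecisive set is then empty, every score is decided, and
`classify_score()` gives precedence to *not pathological* above `upper_t`.
This case never arises in overlapping clinical data and is defined purely for
totality.

The headline contrast for the dual procedure is mild NCD (the hard case for
sensitivity) against NC (the clean reference for specificity); the groups are
arguments, not constants.

## Score adjustments

`education_adjust()` implements the instrument's low-education correction:
one point added below 12 years of education, capped at the instrument maximum
of 30 (the cap is the instrument's standard scoring convention). The adjusted
score is always *derived* — cohort I/O never reads it from file — so the rule
cannot be applied twice. Demographically corrected z-scores are a linear
normative model (`norm_model()`): intercept, age, education and sex
coefficients plus a residual SD, with sex coded as an indicator for male. The
package does not ship published normative coefficients;
`default_norm_model()` is a clearly labelled synthetic placeholder (intercept
26.5, residual SD 2.4, zero demographic slopes) calibrated only so that
simulated normal controls standardise to mean ≈ 0, SD ≈ 1. When an input file
already contains z-scores, the file values win and the model is not applied.

## The synthetic cohort generator

No subject-level data are distributed with studies of this kind, so the
generator is a first-class module: every downstream stage is exercised on
cohorts with the published group-level structure. The default
`default_cohort_spec()` encodes a memory-clinic study with 283 NC, 49 NF,
159 mild NCD and 288 major NCD (447 patients; clinic prevalence
447/496 = 90.1%), MoCA moments NC (26.5, 2.4), NF (26.5, 2.2), mild
(22.0, 3.6), pooled patients (19.1, 4.5), MMSE and z-score moments likewise,
ages 65-91 and education 7-20 from range-truncated normals, and per-group
female fractions.

Two design choices deserve explanation:

* **Major-NCD parameters are solved, not assumed.** Only pooled patient
  moments and the mild subgroup's moments are published.
  `solve_mixture_component()` inverts the two-component mixture moment
  identities so that the 159:288 mild:major mixture reproduces the pooled
  mean and SD exactly — giving major-NCD MoCA (17.50, 4.13), MMSE
  (23.94, 3.55), z (-2.43, 0.83), and analogously for age, education and sex
  fraction.
* **Printed moments are treated as observed moments.** Scores are generated
  as `round(Normal(mean, sd))` clipped to `[0, 30]` (rounding half away from
  zero). Rounding inflates variance slightly and the 0/30 bounds truncate it;
  near the ceiling — MMSE controls average 29.2 of 30 — naive generation at
  the printed parameters would shift the observed mean down by ~0.08 points
  and shrink the SD by ~9%, visibly distorting the emulated study.
  `calibrate_latent()` therefore solves, by fixed-point iteration on the
  exact discretised moments, for the latent normal whose rounded, clipped
  scores have the printed mean and SD. `calibrate = FALSE` switches back to
  the literal mechanism.

Randomness is governed by one master seed; each group draws from a substream
seed derived deterministically from it, so any subset of groups can be
regenerated identically regardless of the other groups' sizes.

What the generator deliberately does **not** emulate: the left skew of real
patient score distributions (published patient ranges reach down to 2 points;
a symmetric normal understates the tail, which is why the package's simulated
AUCs sit 1-2 points below the published 0.94/0.86), within-subject
correlation between MoCA and MMSE (scores are drawn independently), and any
age or education gradient in the scores. Passing tests on synthetic cohorts
therefore validate the *machinery* — the estimators, selection rules and
their invariants — not the clinical values themselves.

## Inference helpers

Sensitivity/specificity intervals are exact Clopper-Pearson by default
(`clopper_pearson()`, beta-quantile form, conventional 0/1 endpoints);
`bootstrap_ci()` provides percentile intervals from stratified resampling.
Percentile rather than BCa is a simplicity-and-determinism choice, and every
interval records its method tag, because published tables of this kind often
omit the CI method and the two families are not interchangeable. Paired
accuracy comparisons use McNemar's test (`mcnemar_paired()`): exact two-sided
binomial on the discordant pairs when there are fewer than 25 of them (the
standard small-sample practice), otherwise chi-squared with a continuity
correction capped at zero, `max(0, |b - c| - 1)^2 / (b + c)` — the cap
prevents the correction from manufacturing a discrepancy when the discordance
is perfectly balanced (exact p = 1 there, and the capped statistic agrees;
the uncapped textbook form would report p ≈ 0.84). Families of comparisons
are adjusted with Holm's step-down procedure (`holm_adjust()`, wrapping
`stats::p.adjust`), applied within whatever comparison family the caller
declares.

Degenerate inputs are defined, not left to error: a constant bootstrap
statistic yields a zero-width interval with a warning; a zero bootstrap SD in
the AUC comparison yields p = 1 when the observed difference is also zero and
an error otherwise; predictive values at prevalence 0 are (PPV 0, NPV 1) and
at prevalence 1 are (PPV 1, NPV 0).

## Problem sizes used in the tests

The test suite and acceptance script simulate 10,000 subjects per group for
moment-recovery and headline-accuracy checks (standard errors ~0.02-0.04
score points, binomial SE ~0.3 percentage points), 200 random small instances
for each brute-force oracle equivalence, 2000 replicates per cell for the
Clopper-Pearson coverage sweep, and a few hundred bootstrap replicates where
only determinism or null behaviour is being asserted (the package default
stays at 2000). These sizes put Monte-Carlo noise well inside the asserted
tolerances while keeping the full suite around twenty seconds.

## Limitations

* The Gaussian score emulation understates real left-skewed patient tails;
  simulated AUCs and accuracies approximate, but do not reproduce, values
  estimated on real cohorts.
* The normative z-score model is configuration; no published coefficients are
  bundled, and the default placeholder must not be used substantively.
* Cost-weighted cut-offs, ROC01/closest-to-corner criteria,
  covariate-adjusted cut-points, DeLong variances, partial AUC and ROC
  smoothing are out of scope.
* The dual-cut-off procedure assumes a discrete bounded score; the z-score
  pathway supports single cut-offs only.
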