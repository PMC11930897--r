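---
title: "Rule-based risk stratification of pure ground-glass nodules: models, metrics, and the synthetic cohort"
author: "lungrads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based risk stratification of pure ground-glass nodules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lungrads)
```

## The problem and the model

A pure ground-glass nodule (pGGN) is a screening-detected lung nodule with
no solid component. Its management depends on whether the lesion is
*invasive* — minimally invasive or invasive adenocarcinoma, for which
surgery is indicated — or *noninvasive* (benign, inflammatory, or an
adenomatous precursor lesion), for which follow-up suffices. Diameter-only
Lung-RADS rules leave almost every pGGN in categories 2–3, so a complementary
system additionally grades the nodule–vessel relationship (GVR): I, vessels
pass beside the nodule; II, vessels pass through unchanged; III, vessels
pass through with localised thickening; IV, increased, thickened, twisted,
convoluted vessels. Vascular recruitment and distortion track angiogenesis,
which is why the GVR grade carries invasiveness information that size alone
does not.

The three rule engines implemented here are pure functions of
(diameter, GVR, suspicious-feature flag):

* **Lung-RADS 1.0**: category 2 below 20 mm, 3 at or above; a category-3
  nodule with *other suspicious malignant imaging features* upgrades to 4x.
* **Lung-RADS v2022**: the same with the cutoff moved to 30 mm.
* **cLung-RADS v2022**: GVR I < 30 mm is 2; GVR I ≥ 30 mm or GVR II is 3;
  GVR III is 4a and GVR IV is 4b at any size; base categories 3/4a/4b with
  suspicious features upgrade to 4x.

The binary invasiveness call is category 4a–4x for cLung-RADS v2022. For
the baselines we take positivity at 4x: it is the only reachable category
at or above 4 for pGGNs under those rules, and the only choice consistent
with the small baseline positive counts in the benchmark confusion cells.
This cutoff is a documented convention of the package, exposed through
`is_positive()`, not a tunable.

Three boundary conventions matter and are fixed deliberately:

* diameters are compared raw (no pre-threshold rounding), and the 20/30 mm
  thresholds are inclusive (`>=`), exactly as the criteria tables print them;
* the 4x upgrade is applied after base categorisation and only to base
  categories 3/4a/4b — a suspicious category-2 nodule stays category 2;
* size alone never triggers 4x. The suspicious-feature flag is an input:
  what counts as a suspicious feature is never enumerated by the published
  criteria, so the package refuses to infer it from other fields.

## Metrics

All metrics are computed from the exact integer confusion cells
(TP = predicted invasive and pathology invasive, etc.). Percentages are
rounded half-up to one decimal *only at display time*; this matters because
several published F1 values were evidently computed from pre-rounded
percentages and differ from the exact values by up to ~0.1 point (and one
published MCC, 60.2% for the training cLung-RADS column, is not consistent
with its own printed cells — the exact value from TP=131, FP=14, FN=7,
TN=17 is 55.2%). The package always reports the exact computation.

* Recall TP/(TP+FN), precision TP/(TP+FP), accuracy (TP+TN)/n.
* F-beta = (1+β²)PR/(β²P+R), default β = 0.5 to weight precision and damp
  the influence of false negatives. β → 0 recovers precision and β → ∞
  recovers recall; the test suite checks both limits.
* MCC with the 0/0 → 0 convention; undefined recall/precision (empty
  denominators) are flagged `NA`, never silently zeroed.
* **AUC**: the ordinal category rank (2 < 3 < 4a < 4b < 4x) is the score —
  the only information-preserving scoring for an ordinal system — and AUC
  is the tie-corrected Mann–Whitney probability, computed via midranks in
  O(n log n). A completely tied score yields AUC = 1/2 (an uninformative,
  not an invalid, classifier). For a binary score AUC equals
  (sensitivity+specificity)/2 identically.
* **DeLong**: variances and paired comparisons use the placement-value
  (structural-component) decomposition; the paired variance includes the
  covariance term, z is referred to the standard normal, p-values are
  two-sided, and a degenerate zero variance with zero AUC difference
  reports p = 1. Confidence intervals are normal-approximation at 95%,
  truncated to [0, 1].
* **ICC**: inter-rater agreement is ICC(2,1) — two-way random effects,
  absolute agreement, single rater — on ordinal category ranks, from the
  mean-squares decomposition. Absolute agreement is the right variant
  because a rater who systematically over-grades should be penalised. An
  all-identical ratings matrix returns 1 by convention, flagged as
  degenerate.

The AUC and DeLong implementations are verified in the test suite against
independently coded brute-force oracles (O(n²) pairwise counts and explicit
double loops over placement values) to 1e-10 or better, and cross-checked
against pROC where available.

## The synthetic cohort generator

No nodule-level data are distributed with the package, so the generator
emulates the development study's composition and is itself first-class,
tested code. A `generator_config()` preset fixes:

* 526 patients with nodule multiplicity 1/2/3 in proportions 487/32/7
  (pooled preset; per-set presets carry 157 and 369 patients), or a fixed
  nodule count via `n_nodules`;
* the GVR mix — training (15, 19, 19, 116)/169, validation
  (35, 41, 51, 276)/403, pooled their sum;
* diameters lognormal, moment-matched to the reported mean ± SD
  (13.8 ± 6.4 mm training, 13.5 ± 6.0 validation). The reports give only
  the first two moments; the lognormal is chosen because nodule sizes are
  positive and right-skewed, and moment matching makes the configured
  mean/SD exact. Long/short axes are split from the mean diameter with a
  uniform 0.75–1 axis ratio so the stored mean is exactly their average;
* age normal (truncated to 18–90 years), sex, and follow-up months from
  the reported per-set summaries;
* per-GVR suspicious-flag probabilities (0.05, 0.42, 0.20, 0.25). The GVR
  II value is backed out of the benchmark cells — about 10 of the 24
  category-3-eligible training nodules must carry the flag to reach the
  published 145 positives — and the others are mild plausible rates chosen
  once;
* invasiveness conditionals P(invasive | GVR) rising with GVR type. Values
  0.25/0.45/0.75 for I–III are fixed as plausible, and the GVR IV rate is
  solved in closed form so that the expected invasive fraction over the
  preset's GVR mix equals the reported pathology split (421/572 pooled,
  giving 0.839 for GVR IV). By default the flag does not alter invasiveness;
  it only drives the 4x upgrade.

One published inconsistency forces a modelling decision: the validation
cLung-RADS positives (TP+FP = 310) are *fewer* than the validation GVR
III+IV count (327), although the rules make every III/IV nodule positive.
No single generating process can therefore reproduce both sets' cells
jointly, and the joint GVR × pathology table is unpublished. The defaults
reproduce the stated marginals (GVR mix, diameter moments, invasive rate);
reproducing any one system's cells is delegated to calibration:

* `calibrate_to_cells()` solves, in closed form, flag probabilities such
  that P(predicted-positive stratum) = (TP+FP)/n under the target system,
  and sets P(invasive | positive) = TP/(TP+FP),
  P(invasive | negative) = FN/(FN+TN), making the *expected* cells equal
  the target exactly. Infeasible targets (positives below the GVR III+IV
  mass for cLung-RADS, or above the achievable flagged mass for the
  baselines) raise errors naming the violated constraint.
* `fixture_exact_cohort()` deterministically builds a minimal cohort whose
  stratification reproduces target cells *exactly* — GVR IV nodules (or
  flagged nodules above the cutoff for baselines) for the positive cells,
  small GVR I nodules for the negative cells — and is the basis of the
  benchmark-reproduction tests.

Randomness is driven by one explicit integer seed; the caller's RNG state
is saved and restored, so the generator has no global side effects and is
bit-reproducible.

What the generator does **not** emulate: correlation of nodules within a
patient (nodules are independent given the patient), any diameter–flag or
diameter–pathology dependence beyond what GVR induces, longitudinal growth,
and reader error in GVR typing. Tests passing on synthetic cohorts
therefore validate the rule engines, metrics and calibration algebra — not
the clinical performance of the rule sets on real populations.

## Numerical and degenerate-input choices

* Ties in ordinal scores: midranks throughout; complete ties give AUC 0.5.
* Comparing a system with itself (or two systems that agree everywhere)
  gives a zero-variance DeLong statistic, reported as difference 0, p = 1.
* Single-class pathology: AUC is omitted with a warning; the metric panel
  is still produced (`evaluate_system()`), since cells remain meaningful.
* Empty marginals: MCC 0 by convention; recall/precision flagged undefined.
* MCC products are accumulated in double precision to avoid integer
  overflow on large cohorts.
* CSV output writes doubles at 17 significant digits so write/read round
  trips are exact; booleans serialise as `true`/`false`, missing fields as
  empty strings.

## Problem sizes used by the shipped checks

The test suite exercises the AUC oracle on 200 random instances of up to
200 subjects, the DeLong oracle on instances up to 100 subjects, simulator
parameter recovery on cohorts of 10^5 nodules (within 3 standard errors),
and the invasive-count calibration on twenty 572-nodule cohorts against the
99% binomial interval around the expected 421 invasive lesions. These sizes
make the checks sharp while keeping the default suite fast on a laptop.

## Known limitations

* The published per-category × pathology cross-tabulations behind the
  reported AUCs (e.g. 0.718 training cLung-RADS) were never printed, so
  those AUC values cannot be recomputed from first principles; the AUC
  machinery is validated by oracle properties instead, and the AUC a
  fixture cohort yields depends on how its cells are laid out across
  categories.
* Evaluation is per-nodule; no per-patient aggregation rule is applied for
  multi-nodule patients (the analysis unit of the benchmark tables is the
  nodule).
* The follow-up-stability inclusion criterion (stable or enlarged over ≥ 3
  months) is not enforced by the rule engines; it is a property of the
  input data.
* ICC confidence intervals and bootstrap AUC inference are out of scope.
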