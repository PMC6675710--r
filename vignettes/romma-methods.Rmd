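---
title: "RoMMa: models, decision rules, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{RoMMa: models, decision rules, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(romma)
```

## The problem

Oncotype DX (ODX) is a 21-gene assay for estrogen-receptor-positive breast
cancer that returns a recurrence score (RS) in 0–100, banded low (< 18),
intermediate (18–30), and high (> 30); RS < 26 is the TAILORx lower-risk
band in which older patients gain little from chemotherapy. The assay is
expensive, and much of the information it summarizes — grade, hormone
receptor levels, HER-2, proliferation — is already measured on every case
during routine pathology workup.

The Rochester Modified Magee algorithm (RoMMa) exploits that redundancy.
The published Magee equations are linear regressions that predict the ODX
RS from routine variables; RoMMa averages them into a single score per case
(the average modified Magee score, **amMs**) and applies threshold rules to
decide which cases genuinely need send-out testing. This package implements
the scoring engine, the decision rules, the validation analytics used to
check agreement with ODX, and a synthetic-cohort generator so everything is
testable without patient data.

## Scoring model

Each Magee equation has the form

$$\widehat{RS} = \beta_0 + \beta_{NS}\,NS + \beta_{ER}\,ER_H +
\beta_{PR}\,PR_H + h(\mathrm{HER2}) + \beta_{size}\,size +
\beta_{Ki67}\,Ki67,$$

where \(NS\) is the Nottingham score (3–9), \(ER_H\) and \(PR_H\) are
modified H-scores (0–300), \(h(\cdot)\) maps the resolved HER-2 status to
an additive term, tumor size is in cm, and Ki-67 is a percentage. The three
equations use different predictor subsets (equation 2 omits Ki-67, equation
3 omits grade and size). Coefficients are deliberately kept in a YAML
config — `inst/extdata/magee_equations.yaml`, transcribed from the public
Magee-equation calculator, with provenance in the file header — rather than
hard-coded, so the arithmetic is auditable and replaceable.

Per-case, every computable equation is evaluated and the amMs is their
arithmetic mean. An equation is not computable when a required input is
missing; the case's mean simply uses the remaining equations, and
`n_equations_used` plus `missing_inputs` record the provenance. H-scores
are accepted as already-computed integers; the derivation of the *modified*
H-score from staining intensity/percentage classes is upstream pathology
work, out of scope here.

Two normalization rules matter:

* **HER-2.** IHC 0/1+ is negative, 3+ positive, and an equivocal 2+ is
  resolved by FISH, the FISH result always overriding IHC. A 2+ with no
  FISH stays *equivocal*: the equations are not evaluated for such a case
  (the config still carries equivocal term values for completeness), and
  validation flags it rather than guessing a direction.
* **Rounding.** Scores are carried unrounded end to end; display rounds to
  one decimal. Threshold comparisons always use the unrounded value, so a
  case at 12.04 is not dragged under a cutoff by display rounding.

## Decision rules

With the default `romma_thresholds()`, a scored case is classified in this
order:

1. amMs ≤ 9 → **lowest risk**;
2. amMs ≤ 12, *or* the histologic low-risk criterion → **low risk**;
3. amMs > 30 → **high risk**;
4. otherwise → **intermediate**, the only category with
   `send_for_odx = TRUE`.

The histologic criterion is Nottingham score < 6 **and** ER H-score ≥ 150
**and** PR H-score ≥ 150 **and** Ki-67 < 10%. Two readings were open in the
source material and are fixed here as package decisions: the ER/PR
condition demands *both* markers clear 150 (the conjunction reading of
"ER and PR H-score ≥ 150"), and the Nottingham bound is part of the rule
(the tabular statements of the rule include it even where prose omits it).
Cases missing an input to the rule evaluate `FALSE` with an
`histologic_indeterminate` flag, never `TRUE` by default.

The predicted ODX band is `high` for high-risk cases, `low` (RS < 18) for
amMs ≤ 12, `below_26` for any other case with amMs ≤ 18, else
`indeterminate`. The ≤ 18 boundary is inclusive. A histologically low-risk
case with amMs in (12, 18] is therefore called low risk but predicted
`below_26` rather than `low` — the score, not the histology, carries the
band prediction.

All cutoffs are config-overridable; the defaults pin the published
algorithm and are the only values exercised by the shipped checks.
Case-level versus patient-level granularity follows the source convention:
scoring and concordance run on cases, outcome statistics on patients, a
multi-tumor patient taking the highest-risk call
(`collapse_to_patients()`).

## Validation analytics

* `band_agreement()` builds the cumulative amMs-group table (< 9, ≤ 10,
  ..., < 18, the histologic row, > 30) against ODX bands, with the percent
  in the concordant band (ODX-low, except ODX-high for the > 30 row).
* `two_by_two()` + `diagnostic_metrics()` give the screening 2×2 of
  amMs ≤ 18 versus RS < 26 with sensitivity, specificity, PPV, NPV, the
  cross-product odds ratio, and a two-sided Fisher exact p-value. Fisher's
  exact test is used deliberately instead of an unnamed web-calculator
  method: it is exact, reproducible, and has no continuity-correction
  ambiguity; on large cells it reproduces the same "P < 0.0001" headline.
  The odds-ratio 95% CI uses the Woolf log method and is a package
  addition, not a reproduced figure. Zero cells yield an explicit `Inf` (or
  undefined) odds ratio with a note — never a silent continuity fudge.
* `discordance_report()` grades each case concordant / one-step / two-step
  by placing both scores into the ODX bands; two-step cases (low on one
  system, high on the other) carry the full record for review.
* `distribution_tests()` compares two populations' score-group frequency
  vectors (Pearson) and threshold splits (chi-squared test of
  independence, uncorrected by default).
* Outcome associations: `covariate_odds_ratio()` (2×2 odds ratio with
  Fisher p; `unknown`/`suspicious` levels excluded from denominators, never
  imputed) and `group_mean_test()` (Welch's unequal-variance t-test — the
  source says only "t-test", and Welch is the robust choice when one group
  has ~18 patients and the other ~280). One printed figure is knowingly not
  reproduced: the lymph-node odds ratio printed as 2.0 is inconsistent with
  its own printed counts (5/18 vs 47/270 gives ≈ 1.8); the package computes
  from counts and reports 1.8.

The fixture functions (`example_validation_scores()`,
`example_screening_scores()`, `example_outcome_tables()`) reconstruct
per-case score pairs from the published summary counts — each count becomes
that many cases holding a representative value inside its band — so the
analytics can be demonstrated and tested end to end without any patient
data. They are synthetic reconstructions, labelled as such, not the study's
per-patient records. One internal tension in the published tables is
resolved in favor of the counts: the narrative places the single two-step
discordant validation case at amMs 15.4, while the cumulative counts put
the only ODX-high low-score case in the ≤ 15 group; the fixture follows the
counts (amMs 14.9, RS 31), and either placement yields exactly one two-step
case.

## Cost model

`institutional_savings()` is exact arithmetic: avoided send-outs × list
price ($4,620 default). `national_extrapolation()` scales the algorithmic
low + high fraction to the national testing volume:
`pool = round(126740 × 0.85)`, then `avoidable = pool × (frac_low +
frac_high)`. The *unrounded* avoidable count is kept in the dollar product
and only the final figure is rounded — rounding the case count first loses
about $200 and does not reproduce the published figure. Where the source
prints the high-risk fraction both as 2.8% and 2.5%, 2.8% is used: it
matches the printed count (25/903) and the printed dollar amount.

## Synthetic cohorts

`simulate_cohort()` exists so that every stage — validation, scoring,
classification, concordance, outcomes, cost — runs on data with the
statistical structure the analyses assume. Design:

1. **Clinicopathologic marginals.** Candidate records draw Nottingham
   scores centered on 5–7, right-skewed ER/PR H-scores (ER high, PR more
   dispersed, as in an ER-positive cohort), HER-2 mostly negative with
   ~27% IHC-equivocal cases always resolved by FISH, gamma-distributed
   Ki-67 (mean ≈ 16%), and log-normal tumor size (median 1.5 cm). Ki-67 is
   deleted in 5.9% of cases and size in 0.3% (the availability rates of the
   study population), never both in one case.
2. **Quota-stratified sampling.** Candidates are scored with the real
   equations and classified with the real rules; the generator then samples
   candidates per category until the realized fractions hit the targets —
   20.8% algorithmic low risk (lowest + low, including histologic-only) and
   2.8% high risk, the study's total-population fractions. This guarantees
   the marginal stratum structure exactly rather than hoping a parametric
   model lands on it.
3. **Score link.** `odx_rs = round(slope·amMs + intercept + N(0, sd))`
   clipped to 0–100, defaults slope 1, intercept 1, sd 4. The sd was chosen
   once so that the fraction of amMs ≤ 18 cases with RS < 26 is ≥ 95%,
   mirroring the reported ~98% without overfitting to it; the observed
   value on generated cohorts sits around 99%.
4. **Outcomes.** Recurrence is Bernoulli with logit
   `-2.94 + 0.05·Ki67 − 0.005·PR + 0.7·LN⁺ + 1.8·LVI`, giving a ~6% base
   rate and the reported directionality (higher Ki-67, lower PR, nodal
   involvement, and LVI raise risk; the LVI coefficient corresponds to an
   odds ratio near 6). Follow-up is 5–11 years for non-recurring patients
   (2–11 for recurring), therapies are assigned with plausible frequencies
   (chemotherapy probability rising with risk category), and ~1.5% of
   patients carry two tumors so patient-level collapse has work to do.

What the generator does *not* emulate: real joint dependence between grade,
receptor status, and proliferation beyond what the equations induce;
inter-observer variation in IHC reading; pre-analytic tissue effects;
informative missingness; calendar-time treatment drift. Passing tests on
generated cohorts therefore demonstrate the *machinery* — partition
invariants, threshold behavior, parameter recovery, calibration of the
generator to its own targets — not clinical performance on real cases,
which only the reconstructed published counts speak to.

`recover_link()` closes the loop: OLS of RS on amMs recovers the link slope
within a few standard errors on cohorts of a couple thousand cases (the
integer rounding and 0-clip of the reported score attenuate the slope very
slightly, visibly only in the third decimal).

## Numerical and testing choices

* Threshold comparisons and boundary cases are pinned by tests: amMs = 12
  is low, 30 intermediate, 18 inside the below-26 band.
* Statistical calls go through the standard R machinery
  (`fisher.test`, `t.test`, `cor.test`, `chisq.test`, `lm`); the test suite
  checks them against independent oracles (exhaustive hypergeometric
  enumeration over all small 2×2 tables, a Monte-Carlo permutation null for
  the chi-squared test, direct cross-product arithmetic).
* Simulation-based checks use 2,000-case cohorts for link recovery and the
  monotone band-agreement pattern and a 5,000-case cohort for the
  calibration checks in `scripts/acceptance.R`; these sizes make the
  smallest cumulative group tens of cases and keep the whole suite under
  half a minute.
* The chi-squared-versus-permutation comparison allows a 0.02 absolute gap:
  the asymptotic p-value approximates the conditional (permutation) null
  from below on small tables, and the tolerance covers that plus
  Monte-Carlo error at 4,000 permutations.

## Known limitations

* The equation coefficients are transcribed from the public calculator; if
  the upstream equations are revised, the YAML config must be updated (its
  header records the transcription date).
* The package predicts ODX *bands*, not the score itself, and neither RoMMa
  nor the amMs can reliably predict an RS < 11 (relevant to staging rules);
  no such prediction is offered.
* No time-to-event modeling: follow-up is summarized descriptively, as in
  the source analyses. Survival methods would need per-patient event times
  the published material does not provide.
* The histologic rule's either/both ER–PR ambiguity is resolved as *both*;
  users wanting the disjunctive reading can lower one bound via
  `romma_thresholds()` and re-run — a sensitivity analysis, not a default.
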