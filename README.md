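# romma

Scoring and triage engine for the **Rochester Modified Magee algorithm
(RoMMa)**: a decision rule that uses routine pathology variables to decide
which estrogen-receptor-positive breast cancer cases actually need send-out
Oncotype DX (ODX) recurrence-score testing, plus the full validation
analytics around it.

## Who this is for

Breast pathologists, oncology groups, and health-services researchers who
want to (a) compute average modified Magee scores and RoMMa calls on a
cohort CSV, (b) quantify how well those calls agree with ODX recurrence
scores, (c) relate risk strata to recurrence outcomes, and (d) estimate the
testing cost avoided by not sending algorithmically low- or high-risk cases
out for the assay.

## The model in brief

Each published Magee equation is a linear predictor of the ODX recurrence
score (RS):

> RS-hat = β₀ + β_NS·NS + β_ER·ER_H + β_PR·PR_H + h(HER2) + β_size·size + β_Ki67·Ki67

with NS the Nottingham score, ER_H/PR_H modified H-scores (0–300),
h(·) a HER-2 status term, size in cm, and Ki-67 in percent. The three
equations (different predictor subsets; coefficients shipped in an
auditable YAML config) are averaged per case into the **amMs**. RoMMa then
classifies:

| Rule | Category | Action |
|---|---|---|
| amMs ≤ 9 | lowest risk | no send-out |
| amMs ≤ 12, or NS < 6 & ER_H ≥ 150 & PR_H ≥ 150 & Ki-67 < 10% | low risk | no send-out |
| amMs > 30 | high risk | no send-out |
| otherwise | intermediate | send for ODX |

amMs ≤ 18 additionally predicts RS < 26, the TAILORx lower-risk band.

## Worked example

```r
library(romma)

cohort <- simulate_cohort(300, seed = 42)   # or read_cohort("cases.csv")
calls  <- romma_classify(cohort)
romma_summary(calls)
#> # A tibble: 4 × 3
#>   category         n   pct
#>   <chr>        <int> <dbl>
#> 1 lowest_risk      4  1.33
#> 2 low_risk        58 19.3
#> 3 intermediate   230 76.7
#> 4 high_risk        8  2.67
```

About 22% of this generated cohort (lowest + low) meets low-risk criteria
and 2.7% high-risk criteria: those ~67 cases would not reflex for ODX
testing; the 230 intermediate cases would.

Diagnostic accuracy of the amMs ≤ 18 rule for RS < 26, on the 903
reconstructed score pairs of the published total population:

```r
diagnostic_metrics(two_by_two(example_screening_scores()))
#>            ODX RS < 26 complement
#> amMs <= 18         524         13
#> complement         233        133
#> Sensitivity: 0.692
#> Specificity: 0.911
#> Positive predictive value: 0.976
#> Negative predictive value: 0.363
#> Odds ratio: 23.0 (95% CI 12.8-41.5), Fisher exact P = 2.42e-44
```

Read: 97.6% of cases the rule calls "below 26" truly score below 26 (PPV),
and 91% of cases at or above 26 are correctly left above the cutoff
(specificity) — the rule is highly specific and predictive for RS < 26,
at the price of modest sensitivity.

Band agreement across cumulative amMs groups (validation population), and
the national cost extrapolation:

```r
band_agreement(example_validation_scores())
#> 1 amMs <9                 4        0                0       4          100
#> 4 amMs <=12              97        0               13      84           86.6
#> 9 amMs >30               17       17                0       0          100

national_extrapolation(cost_scenario())
#>   candidate_pool n_avoidable savings_usd
#> 1         107729       25424   117459083
```

Every amMs > 30 case was ODX-high; 86.6% of amMs ≤ 12 cases were ODX-low.
At the national testing volume, triaging the 23.6% algorithmic low + high
cases away from send-out corresponds to ~25.4k avoided tests, about $117M
at list price.

See `vignette("romma-methods")` for the model, decision rules, generator
design, and the package's documented departures from ambiguous or
internally inconsistent printed figures.

## Package tour

| Area | Functions |
|---|---|
| Data model | `read_cohort()`, `write_cohort()`, `normalize_her2()`, `validate_cohort()` |
| Scoring | `magee_equations()`, `score_equation()`, `score_magee()` |
| Classification | `romma_thresholds()`, `histologic_low_risk()`, `romma_classify()`, `classify_cohort()`, `romma_summary()`, `collapse_to_patients()` |
| Concordance | `band_agreement()`, `two_by_two()`, `diagnostic_metrics()`, `discordance_report()`, `distribution_tests()`, `odx_band()` |
| Outcomes | `recurrence_by_stratum()`, `covariate_odds_ratio()`, `group_mean_test()` |
| Cost | `cost_scenario()`, `institutional_savings()`, `national_extrapolation()` |
| Synthetic data | `cohort_spec()`, `simulate_cohort()`, `recover_link()` |
| Reporting | `run_report()`, `plot_concordance()`, `plot_band_agreement()`, `autoplot()`, `tidy()`/`glance()` methods |

A thin command-line wrapper with `score`, `classify`, `concordance`,
`outcomes`, `cost`, `simulate`, and `report` subcommands ships at
`inst/cli/romma.R`.
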