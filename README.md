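# prscreen

Screening-performance calculus for polygenic risk scores (and any other
continuous risk marker with Gaussian, equal-SD distributions in affected
and unaffected groups).

Published evaluations of polygenic risk scores almost never report the
quantities that matter for screening — the detection rate (DR, the share
of future cases flagged) and the false positive rate (FPR). They report
odds ratios per standard deviation, odds ratios comparing extreme
quantile groups, or the AUC. Under the equal-variance Gaussian (binormal)
model all of these are interchangeable functions of one parameter: the
separation δ between the affected and unaffected score means, in
unaffected-SD units. `prscreen` implements that calculus for
epidemiologists, screening programme analysts and anyone appraising a
published score:

* **Metric conversions** — δ ↔ DR/FPR (`dr_at_fpr`,
  `delta_from_operating_point`), δ ↔ OR/SD (`delta_from_or_per_sd`,
  δ = ln OR/SD), δ ↔ AUC (`auc_from_delta`, AUC = Φ(δ/√2)),
  δ ↔ extreme-quantile OR (`extreme_quantile_or` and its bisection
  inverse), plus a dispatcher `delta_from_metric()`.
* **Risk profiles and predictive values** — likelihood ratios
  (LR(z) = exp(δz − δ²/2), log-linear in z), Bayes posterior risk across
  centiles (`risk_profile`), and `ppv_from_operating_point`.
* **Stratification** — exhaustive per-stratum population/case/non-case
  shares, relative and absolute risks over any centile partition
  (`stratification_table`), and the prevention-paradox summary.
* **Policy arithmetic** — events prevented, number needed to genotype
  (`nng_from_events`, `nng_from_operating_points`), strategy comparison.
* **Metric tables** — read a CSV of published metrics, normalise every
  record to δ/DR5/AUC/OR-SD (`normalize_records`), summarise by disease.
* **Synthetic cohorts** — seedable individual-level simulation of the
  model, with empirical estimators that validate every closed form by
  Monte Carlo, and a between-score instability experiment.

## Worked example

A coronary artery disease score reported with OR/SD = 1.73:

```r
library(prscreen)
model <- delta_from_or_per_sd(1.73)
metric_equivalents(model)
#>                    metric     value          display
#> 1                delta_sd 0.5481214              0.5
#> 2                     dr5 0.1363792              14%
#> 3                     auc 0.6508367             0.65
#> 4               or_per_sd 1.7300000              1.7
#> 5 extreme_quantile_or_0.2 4.6725834                5
```

An impressive-sounding odds ratio per SD of 1.73 is a test that detects
14% of future cases at a 5% false positive rate. Applying a typical
score (DR 11% at FPR 5%) to a population with 10% background risk:

```r
ppv_from_operating_point(dr = 0.11, fpr = 0.05, prior_odds = "1:9")
#> [1] 0.1964286
```

— a positive predictive value of 20%: four in five positives are false.
Stratifying a breast-cancer score with DR5 = 15% at the 3rd/40th/60th/97th
centiles shows where the cases actually are:

```r
bc <- delta_from_operating_point(dr = 0.15, fpr = 0.05)
stratification_table(bc, c(0.03, 0.40, 0.60, 0.97))[, c(1, 4, 5, 7)]
#>   stratum_label population_share  case_share rr_vs_remainder
#> 1          0-3%             0.03 0.006401297       0.2083087
#> 2         3-40%             0.37 0.188006483       0.3942386
#> 3        40-60%             0.20 0.166859621       0.8011117
#> 4        60-97%             0.37 0.537112353       1.9757336
#> 5       97-100%             0.03 0.101620245       3.6573857
```

The top 3% ("high risk") holds 10% of cases; the unremarkable middle of
the distribution holds the majority — the prevention paradox. And the
yield of adding a score to an existing risk model, from published event
counts:

```r
nng_from_events(100000, 957, 974)
#> Events prevented: 957.0 (baseline) -> 974.0 (with score); gain 17.0
#> Number needed to genotype per additional event prevented: 5882 (5882.35)
```

See `vignettes/screening-performance.Rmd` for the model, conventions and
design decisions.

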