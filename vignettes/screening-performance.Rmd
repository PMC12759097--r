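---
title: "The screening-performance calculus behind prscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The screening-performance calculus behind prscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prscreen)
```

## The model

A polygenic risk score, viewed as a screening test, is a continuous marker
whose distributions in affected and unaffected individuals are Gaussian
with equal standard deviations. `prscreen` works throughout in
unaffected-SD units: the unaffected distribution is standard normal and
the affected distribution is normal(&delta;, 1), where &delta; is the
difference between the group means. This single parameter fixes the whole
ROC curve, and therefore every performance summary in circulation:

* **Detection rate at false positive rate f.** A cut-off at the
  (1&minus;f) quantile of the unaffected distribution gives
  DR = &Phi;(&delta; &minus; &Phi;<sup>&minus;1</sup>(1&minus;f)).
  DR5 (f = 0.05, the cut-off at the 95th unaffected centile) is the
  single-number summary used throughout the package.
* **AUC.** &Phi;(&delta;/&radic;2) — the binormal equal-variance closed
  form, verified in the test suite against numerical integration of the
  ROC curve.
* **Odds ratio per SD.** The log odds of disease is linear in the score
  with slope &delta;, so OR/SD = e<sup>&delta;</sup>. This is exact in the
  rare-disease limit; hazard ratios per SD are put through the same
  conversion and flagged as a rare-disease approximation, since published
  comparisons place HR- and OR-based scores on one scale.
* **Extreme-quantile OR.** Comparing the top and bottom fraction q of the
  distribution (cut-offs on the unaffected distribution), with
  z\* = &Phi;<sup>&minus;1</sup>(1&minus;q):
  OR = &Phi;(&delta;&minus;z\*) / &Phi;(&minus;z\*&minus;&delta;). This is
  inverted by bisection on &delta; &isin; [0, 15] (monotonicity guarantees
  convergence; relative tolerance 10<sup>&minus;10</sup>); values below 1
  are reflected to negative &delta; by symmetry rather than rejected.
* **Likelihood ratio.** LR(z) = &phi;(z&minus;&delta;)/&phi;(z) =
  exp(&delta;z &minus; &delta;&sup2;/2): log LR is linear in z with slope
  &delta;, so on a logarithmic risk scale the risk gradient is a straight
  line with no threshold, and LR = 1 exactly at z = &delta;/2. The
  apparent "uptick" in risk above the 95th centile seen in arithmetic-axis
  centile plots is an artefact of plotting the same log-linear gradient on
  a scale that compresses values below 1.

```{r}
model <- delta_from_or_per_sd(1.73)
metric_equivalents(model)
```

## Worked consequences

Posterior risk follows from Bayes in odds form. A score detecting 11% of
future cases at a 5% false positive rate, applied at background odds 1:9
(10% risk), yields posterior odds (0.11 &times; 1) : (0.05 &times; 9) — a
positive predictive value of about 20%:

```{r}
ppv_from_operating_point(dr = 0.11, fpr = 0.05, prior_odds = "1:9")
```

Stratification is the same calculus with several cut-offs. The share of
cases in a centile band [l, u] is
&Phi;(&Phi;<sup>&minus;1</sup>(u)&minus;&delta;) &minus;
&Phi;(&Phi;<sup>&minus;1</sup>(l)&minus;&delta;);
`stratification_table()` always emits the exhaustive partition, including
the middle strata that selective displays omit — which is where most cases
sit (the prevention paradox):

```{r}
bc <- delta_from_operating_point(dr = 0.15, fpr = 0.05)
stratification_table(bc, c(0.03, 0.40, 0.60, 0.97))[, 1:5]
```

## Parameters and conventions

* **Rates are proportions internally.** Percent appears only at the
  reporting boundary, rounded half to even (base `round()`) to the
  precision conventionally printed: integer percent for detection rates,
  2 dp for AUC, 1 dp for &delta; and OR/SD, nearest integer for
  extreme-quantile ORs. The CLI accepts rates with or without a `%` sign;
  bare values at or below 1 are read as proportions.
* **Quantile cut-offs sit on the unaffected distribution** by default,
  approximating population centiles for uncommon disease; this is the
  convention that reproduces published stratification tables. A
  prevalence-aware mode (`quantiles = "population"`) solves the mixture
  CDF numerically; for prevalence up to 10% the two differ by under 0.01
  in any stratum share.
* **Absolute risk per stratum** applies the stratum likelihood ratio
  (case share over non-case share) to the prior odds implied by the
  supplied average prevalence. Age-specific incidence curves are out of
  scope.
* **Number needed to genotype.** Events prevented are
  n &times; incidence &times; DR &times; RRR under full adherence; the NNG
  is n over the gain in events prevented when a score is added, reported
  rounded to the nearest integer with the unrounded value retained.
  Changes in the false positive rate alter the treated-population size
  (reported for transparency), not the events prevented, matching the
  accounting convention of the published re-analyses.
* **IQR convention.** Per-disease summaries interpolate linearly between
  order statistics (`quantile()` type 7); medians of even counts are
  midpoint means.

## The synthetic-cohort generator

`simulate_case_control()` and `simulate_population()` draw scores from
exactly the model above (standard normal unaffected, shifted affected;
Bernoulli status in population mode) with the Mersenne-Twister generator
recorded alongside the seed in every output. The generator's role is
validation: every closed form has an empirical counterpart
(`empirical_operating_point()` with nearest-rank thresholds,
Mann&ndash;Whitney `empirical_auc()`, pooled-SD `empirical_delta()`), and
the test suite checks agreement on million-individual cohorts within
three Monte-Carlo standard errors, plus unbiased recovery of &delta;
across the separations the package is typically used at (0 to 2.5 SD).

What the generator deliberately does *not* emulate: genotype-level
structure (SNP effects, linkage disequilibrium), non-Gaussian or
unequal-variance markers, age structure and competing risks. Passing
tests therefore establish the internal consistency of the calculus and
its finite-sample estimators — not that any real score follows the
equal-SD Gaussian model, which is an empirical premise taken from the
literature.

The between-score instability experiment draws, per individual, two
scores with equal marginal &delta; and a chosen cross-correlation via a
shared-component construction (weights &radic;r and &radic;(1&minus;r)),
the simplest structure that preserves each score's marginal performance
while letting individual centiles disagree. The published observation it
emulates is qualitative — the same person can land at opposite extremes
of two scores for the same disease — so the experiment is tested as a
property (zero discordance at r = 1, discordance monotone as r falls),
not against a numeric target.

```{r}
res <- score_instability_experiment(0.4, score_correlation = 0,
                                    n = 20000, seed = 61)
res$fraction_discordant_gt
```

## Design choices and known discrepancies

* Conversions are anchored on the OR/SD relation &delta; = ln(OR/SD),
  which reproduces the published 1.49 &rarr; 11% and 1.73 &rarr; 14%
  DR5 values. For DR5 = 11% some sources print OR/SD 1.6 where the
  ln-conversion gives 1.52 (and 1.6 would imply DR5 &asymp; 12%); both
  values are surfaced here, and the self-consistent conversion is the one
  tested.
* The often-quoted quintile OR of 2284 for a DR5 = 80% test corresponds
  to &delta; = 2.5 exactly; the unrounded
  &delta; = &Phi;<sup>&minus;1</sup>(0.8)+&Phi;<sup>&minus;1</sup>(0.95)
  = 2.4865 gives 2173. The package computes from unrounded &delta; and
  documents the difference rather than matching the rounded figure.
* The 60th–97th centile stratum of a DR5 = 15% score computes to 53.7%
  of cases (rounds to 54%) while 53% is sometimes printed — consistent
  with a &delta; derived from the score's unrounded OR/SD rather than the
  rounded DR5. The table is asserted within one percentage point there.
* Published event counts of 974 vs 957 prevented per 100,000 are rounded
  from an unprinted incidence (back-solving gives roughly 7,980 per
  100,000 over the horizon); no single incidence reproduces both printed
  counts exactly. The NNG of 5882 is therefore reproduced from the
  printed inputs (100,000 / 17), and the operating-point route documents
  its own unrounded composition.

## Problem sizes

Closed-form checks are instantaneous. The Monte-Carlo validations use
10^6 individuals per class for estimator agreement, 4&ndash;5 &times;
10^4 per replicate for bias and convergence studies, and 2&ndash;3 &times;
10^4 individuals for the instability experiment — sizes at which the
Monte-Carlo standard errors are an order of magnitude tighter than the
effects being checked.

## Limitations

The package evaluates *reported* performance under a stated model; it
does not construct scores from genotypes, fit empirical ROC curves, or
model demography, adherence or cost-effectiveness. Where a published
figure depends on external data (per-disease catalogue summaries,
age-specific screening yields), only the generic arithmetic is provided
and the external inputs must be supplied by the user.
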