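---
title: "From ECDI item responses to global prevalence projections: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From ECDI item responses to global prevalence projections: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecdiglobal)
```

This vignette explains the model behind `ecdiglobal`, the assumptions it
makes, the knobs that matter, and what its synthetic-data tests do and do
not demonstrate about real survey data.

## The measurement model

The Early Childhood Development Index (ECDI) is a ten-item caregiver
questionnaire for children aged 36–59 months. Each item is answered
yes/no and scored so that 1 is favorable; for three items ("too sick to
play", "kicks, bites, or hits", "easily distracted") a "yes" indicates a
problem, so their raw responses are inverted (`apply_reverse_coding()`).
Only two of the four ECDI domains are analyzed here — learning/cognition
(2 items) and socioemotional development (3 items) — because the
literacy-numeracy items measure school-readiness skills few 3–4-year-olds
have, and the physical items are poor measures of development at this age.

A child is classified "low development" in a domain on **more than one**
zero score. We read that cutoff literally: at least two failures, which for
the two-item cognitive domain means failing both items. The headline
outcome is *low in either domain*. The cutoff is treated as fixed — it is a
screening convention, not a validated diagnostic threshold, and the package
deliberately does not make it tunable per age.

Children missing any of the five in-scope responses are excluded from all
analyses; missingness on out-of-scope items is ignored, since those items
never feed a classification. Exclusion is child-level: we do not impute.

## Design-based prevalence

Prevalence is the Hájek ratio estimator `sum(w*y)/sum(w)`. Its variance
uses Taylor linearization with a with-replacement first-stage
approximation: linearized scores are summed within first-stage clusters
(PSUs) and their between-cluster variance is accumulated within strata.
This is the standard estimator for MICS/DHS two-stage designs; the surveys'
exact stratification and weight construction are not public, so the
package takes cluster and stratum labels as given and claims nothing about
any specific survey's design. With equal weights and independent children
the estimator reduces exactly to `p(1-p)/(n-1)`, and the point estimate to
`n_low/n` — which is how the published country tables are reproduced from
their printed counts. A stratum with a single cluster leaves the SE
undefined (returned as `NA` with a warning) rather than silently lonely-PSU
adjusted.

Published country percentages almost all equal their raw count ratios, but
not all (one Balkan survey differs by 0.1 point, presumably weighting), so
`weighted_prevalence()` always reports both the unweighted counts and the
weighted estimate, and report tables format proportions with half-up
rounding to one decimal only at display time.

The cognitive-stimulation index counts six caregiver activities (reading,
playing, storytelling, counting, singing, outings). Quintiles cut the raw
0–6 score at weighted 20/40/60/80th percentiles with ties assigned to the
lower quintile; because the score takes only seven values the "quintiles"
are necessarily lumpy. They are computed on the pooled weighted sample by
default — the reference population is a genuine open choice, and pooling
matches how the subgroup figures are usually read; a per-country analysis
can simply pass per-country subsets.

## Country-level models, cross-validation, selection

Across surveyed countries the prevalence is regressed by OLS on the 2010
stunting proportion, the 2010 HDI, or both. The regression is unweighted
across countries: each country is one design point, not a number of
children. Standard errors are heteroskedasticity-consistent; HC1 is the
default flavor (the common "robust SE" default in country regressions) and
is configurable.

Model selection uses exhaustive leave-*k*-out data splitting: all C(n, k)
held-out subsets for k = 1 and k = 2, squared prediction error on every
held-out country, RMSE over all held-out predictions. At n = 35 that is 35
and 595 splits — the enumeration is deterministic, never sampled. One
published footnote describes the second scheme as "sample size 30", which
is inconsistent with its own split count (C(35,2) = 595 implies training
size 33); the package implements leave-2-out with training size 33 and
records the training size in the result so either reading is auditable.
Predictions are *not* clipped to [0,1] during cross-validation — clipping
would break the exact leave-one-out PRESS identity
`rmse = sqrt(mean((e_i/(1-h_ii))^2))` that the test suite verifies to
1e-10 — clipping applies only at projection time.

The selector takes the candidate minimizing the leave-1-out RMSE, breaking
ties toward fewer predictors and then declaration order; leave-2-out is
always computed alongside as a concordance check. Both RMSEs and the
chosen model are logged.

## Projection and intervals

The selected model predicts every LMIC's prevalence (clipped to [0,1]).
The 95% interval is `prediction ± 1.96 × CV-RMSE`, clipped, then scaled by
the country's population aged 3–4 years to give counts. The CV-RMSE is an
estimate of out-of-sample prediction error, so this interval is a
prediction interval built from empirical errors rather than a
model-variance interval; the leave-2-out RMSE is the default
(`rmse_k = 2`), with k = 1 available by flag. Regional and global counts
are sums of country counts, and interval bounds are sums of country
bounds — deliberately conservative (it ignores that prediction errors
partially cancel across countries) but exactly additive, so the global
interval always equals the sum of the regional ones. A variance-pooling
alternative was considered and rejected as the default because additivity
is what published regional tables exhibit.

Surveyed countries get model predictions by default, for uniform treatment
across all LMICs; `use_observed = TRUE` substitutes their observed survey
prevalences instead. Region membership travels with the macro table (and
the generator emits it), since no canonical region list is bundled beyond
the five standard labels.

The combined-deficit calculation adds to the overall low-score prevalence
the share of children stunted but *not* low-scoring,
`stunting_prev * (1 - p_low_given_stunted)`, under the logged assumption
that stunting among 3–4-year-olds matches the under-5 rate.

## What the synthetic generator emulates

`generate_country_panel()` draws LMICs with HDI uniform on a configurable
range (default 0.30–0.90), stunting negatively related to HDI with noise,
log-normal populations of 3–4-year-olds, and ancillary indicators (life
expectancy, schooling, GNI) increasing in HDI. `generate_microdata()`
draws, for each surveyed country, a two-stage cluster sample: PSUs carry
urbanicity and a random intercept (default SD 0.3 on the log-odds scale,
a modest design effect); children carry sex (P(male) = 0.5), age
(3 vs 4, even split), wealth quintile (uniform), stunting at the country's
stunting proportion, and unit-mean log-normal weights (sdlog 0.3). These
marginals match the variables the analysis stratifies on without inventing
structure no one has published; the defaults for the scale of the exercise
(138 LMICs, 35 surveyed, 100 clusters × 28 children ≈ 2,800 children per
survey) mirror the observed study setting of ~99,000 children across 35
surveys.

Each ECDI item fails with probability
`logistic(country offset + item baseline + covariate effects + cluster
effect)`; reverse-coded items are emitted on the raw yes/no scale. When a
prevalence link `a + b*HDI` is configured (default `1.00 − 1.06×HDI`,
chosen so mid-range HDI countries sit near one-third prevalence and the
range spans roughly 5%–65%), the country offset is *calibrated*: the
common in-scope failure probability `q` solving
`P(low either | q) = a + b*hdi` is found by root-finding on the closed
form `1 − (1 − q²)(1 − 3q² + 2q³)`, and covariate effects are centered
within country. With covariate effects and cluster effects switched off the
calibration is exact up to binomial noise (and the tests verify
convergence at that tolerance); with heterogeneity on, logistic averaging
introduces a small attenuation of extreme targets (a percentage point or
two) — the generated world is then only approximately linear in HDI, which
is itself faithful to the application. Missingness is applied uniformly at
random at the child level (default 1%), matching the analysis's
missing-data exclusion rather than any survey's nonresponse mechanism.

What passing tests on this world show: the scoring rule, the weighted
estimator, the cross-validation machinery, the selection logic and the
projection arithmetic are correct, and parameters designed into the world
are recovered at the advertised uncertainty. What they cannot show: that
real caregiver reports behave like independent logistic items, that real
survey weights look log-normal, or that real country prevalence is truly
linear in HDI. The published-count fixtures pin the arithmetic to real
published numbers precisely to keep that gap visible.

## Numerical choices and degenerate inputs

* Half-up rounding to one decimal for displayed percentages; stored values
  stay full precision to avoid double rounding.
* Weighted quantiles take the smallest value whose weighted CDF reaches
  the probability; ties therefore land in the lower quintile consistently.
* `uniroot` tolerance 1e-10 for the prevalence-link inversion; target
  prevalences of exactly 0 or 1 map to degenerate item probabilities with
  clamped (±20) log-odds.
* A constant regression outcome returns slope 0 and R² 0 (not NaN); a
  rank-deficient design errors naming the collinear predictor rather than
  silently dropping it.
* Cross-validation refits use the QR-based `.lm.fit` on a prebuilt model
  matrix, so the 595-split enumeration costs milliseconds.
* Test problem sizes are scaled to keep the suite fast (panels of n = 35
  countries, microdata of a few thousand children, 100–500 Monte-Carlo
  replicates); each property states the tolerance implied by its own
  Monte-Carlo error.

## Known limitations

* Variance estimation ignores finite-population corrections and
  second-stage sampling; replication-weight (jackknife/BRR) variance is
  out of scope, though a cluster-jackknife cross-check appears in the
  tests.
* The robust-SE coverage of HC1 at n = 35 runs a little below nominal
  (≈94% in simulation) — a known small-sample property, accepted rather
  than patched with HC3 to stay with the conventional estimator.
* Regional interval bounds summed across countries overstate joint
  uncertainty; the package reproduces that convention knowingly.
* The generator's covariate effects are additive on the log-odds scale
  with no interactions; real gradients (e.g. wealth × urbanicity) are
  richer.
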