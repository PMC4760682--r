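---
title: "The Drug Derived Complexity Index: model, derivation and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Drug Derived Complexity Index: model, derivation and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddci)
```

## The problem

Population-level risk stratification usually relies on hospital data:
comorbidity indices such as the Charlson Comorbidity Index (CCI) score
discharge diagnoses, so they say nothing about the large majority of
citizens who were never admitted. Community pharmacy claims, by contrast,
cover almost everyone. The Drug Derived Complexity Index (DDCI) exploits
this: chronic exposure to specific drug classes, read off ATC-coded
dispensing records, serves as a proxy for underlying chronic disease, and a
weighted sum of class exposures becomes an integer complexity score that
predicts mortality, unplanned hospitalization and readmission for an entire
insured population.

This package implements the full DDCI pipeline — exposure rules, scoring,
weight re-derivation, the CCI comparator, and the discrimination /
reclassification evaluation battery — together with a synthetic
claims-cohort generator so that every stage can be exercised and tested
without access to real administrative data.

## Exposure rules

Baseline exposure is assessed over the year before a common index date,
the half-open window `[index − 365 d, index)`: a package dispensed exactly
365 days before the index date counts, one dispensed on the index date does
not. Each of the 19 drug classes is a rule over that window: a set of ATC
include prefixes, optional exclude prefixes, and a minimum total package
count. Most classes require at least 3 packages in 12 months;
antihyperglycemic therapy (A10) requires 2; the neurological classes
(anti-Parkinson N04, antipsychotics N05A, and the two N06 classes) require
a single package. "Packages" sums the dispensed package quantities, not
prescription rows, matching how Italian pharmacy claims record
dispensations.

Two rules need care:

* **Opioids** — N02A excluding codeine and tramadol. The source names the
  substances rather than codes; the default exclusion list is
  `N02AA59, N02AA79, N02AX02, N02AX52` (plain and combination forms) and is
  configurable on the rule.
* **Hypertensive heart disease** — a 45-day combination rule: the flag is
  raised when, within any sliding 45-day sub-window of the baseline year,
  either prescriptions matching at least two *distinct* entries of the set
  `{C01AA05, C03CA01, C03DA01, C07AG02, C07AB07, C07AB03, C09}` occur, or
  at least two dispensations of digoxin (C01AA05) occur. The printed
  definition ("any combination of drugs … at least 2 prescriptions of
  C01AA05") does not say whether "combination" means simultaneous
  co-prescription; we adopt the weaker, operational reading — any two
  distinct agents inside the window — because claims data carry no
  co-prescription linkage.

A further quirk of the printed table: it assigns "Anti-dementia drugs" to
N06A and "Antidepressants" to N06D, the reverse of standard ATC semantics.
`default_rule_table()` follows the table verbatim;
`default_rule_table("standard")` swaps the prefixes back. Everything
downstream is indifferent to the labelling as long as the rule table and
the data agree.

## Score and risk classes

The raw score is the algebraic sum of integer class weights over raised
flags. With the published weights it ranges from −3 (statin +
immunosuppressant, both protective) upward; negative and zero scores are
folded into risk class 0, scores of 11 or more into class 11, giving exactly
12 classes. The published text quotes a maximum of 33 although the positive
weights sum to 36; no exclusivity rule between classes is printed, so the
implementation imposes none — the discrepancy is immaterial because
everything above 11 is capped into the top class anyway.

```{r}
w <- default_weight_table()
scores <- enumerate_scores(w)   # all 2^19 exposure combinations
range(scores)
length(unique(assign_class(unique(scores))))
```

## Weight derivation

Weights are re-derived from data by a multivariate Cox proportional-hazards
fit of overall mortality on the 19 exposure flags (Efron tie handling;
convergence when the relative log-partial-likelihood change falls below
1e−9, at most 100 Newton iterations). Classes not significantly associated
with mortality (two-sided Wald p ≥ 0.05) are excluded from the final model;
they keep their key in the returned table with weight 0 so that tables
remain comparable. For retained classes,

> weight = round(coefficient / 0.3), halves away from zero.

None of the 19 published coefficients sits on a rounding tie, so the
tie-break is observationally free there, but it must be fixed for derived
coefficients; half-away-from-zero treats protective and harmful classes
symmetrically. Applying the rule to the published coefficient column
reproduces the published weight column 19/19.

One printed-number caveat: the published hazard-ratio column is computed
from unrounded coefficients, so `exp(0.368) = 1.4449` prints as 1.45. The
package therefore checks HR consistency as *rounding-interval overlap*
(`check_hr_consistency()`): `exp(c ± 0.0005)` must overlap `HR ± 0.005`.
All 19 rows pass; a naive half-ULP comparison would fail exactly that row.

### Adjustment covariates

Whether the original derivation adjusted for anything beyond the drug
classes is not documented; the published table is presented as flags-only.
This package's `derive_ddci_weights()` adjusts for age and sex by default
and discards their coefficients. The reason is statistical rather than
cosmetic: mortality has a steep age gradient (in our generator, 0.08 per
year, i.e. an omitted linear-predictor standard deviation above 1), and a
Cox fit that omits so strong an independent covariate attenuates the
marginal drug-class coefficients by enough (5–15%) to push several classes
across a 0.3-wide rounding boundary systematically. Adjusting restores the
conditional effects that the weights are meant to encode. The flags-only
fit remains available (`adjust_age_sex = FALSE`).

## Charlson comparator

The CCI is computed from baseline-year discharge diagnoses (admission
within the same 12-month window used for prescriptions) with the Deyo
ICD-9-CM adaptation and original Charlson weights; the mapping ships as an
editable CSV (`charlson_icd9_deyo.csv`) with prefix matching on dotless
codes and the standard hierarchy (complicated diabetes over diabetes,
metastatic tumor over any malignancy, severe over mild liver disease).
Persons without a baseline hospitalization score 0.

## Evaluation battery

* **Kaplan–Meier curves** per risk class (`km_estimate()`).
* **Class-wise hazard ratios** versus class 0, adjusted for age and sex
  (`classwise_hazard_ratios()`); empty classes are omitted with a warning.
* **Harrell's survival C-index** (`harrell_c()`): concordance over usable
  pairs with half credit for tied scores; Noether-type asymptotic CI, with
  a seeded 200-resample bootstrap option for small cohorts.
* **Net Reclassification Improvement** (`nri()`): the *category-free*
  variant. The published component values (e.g. 0.6563 of non-events
  correctly reclassified) are not compatible with any plausible small set
  of risk categories, and no categories are documented, so the continuous
  definition — net proportion of events whose predicted risk rises plus
  net proportion of non-events whose risk falls — is used. Persons censored
  before the horizon are excluded from the NRI denominator by default; an
  inverse-probability-of-censoring weighting option exists
  (`compare_models(..., ipcw = TRUE)`).
* **Model comparison** (`compare_models()`): fits reference and augmented
  Cox models, predicts horizon risk as `1 − S0(t)^exp(lp)` with the Breslow
  baseline, and reports both C-indices and the NRI. The four designs of the
  published analysis are supported: age+sex vs +DDCI (Model A; Model B on
  the hospitalized subcohort), vs +CCI (Model C), and age+sex+CCI vs +DDCI
  (Model D). Both a 1-year and the overall 7-year horizon are available.
* **Readmissions** (`readmission_history()`, `readmission_irr()`):
  follow-up starts at the discharge of the first unplanned admission after
  the index date, every subsequent admission counts, and incidence rate
  ratios versus class 0 come from a Poisson model with a log person-years
  offset, adjusted for age (continuous) and sex. With one binary class and
  no covariates the modeled IRR equals the crude rate ratio exactly, which
  the tests assert.

## The synthetic cohort

`simulate_cohort()` generates the three claims tables plus a ground-truth
table under configurable study conditions. The defaults are the published
cohort's: the 19 training-set exposure prevalences (29.45% arterial
hypertension drugs down to 0.05% opioids), the published coefficients as
true log hazard ratios, age ~ Normal(60.17, 13.58²) truncated at 40, 46.29%
male, and a 7-year horizon. Values the source does not pin down were chosen
once, as follows, and not revisited:

* `baseline_hazard = 0.0051`/yr — calibrated so the default configuration
  yields the published ~10.67% 7-year cumulative mortality (grid search at
  n = 300,000).
* `migration_rate = 0.005`/yr — the published mean follow-up (6.62 y of 7)
  and 89.3% alive-at-end imply near-negligible out-migration.
* `beta_age = 0.08`/yr and `beta_sex = 0.25` — a realistic adult mortality
  age gradient and male excess, so the age/sex-adjusted evaluation paths
  carry signal.
* `cci_log_hr = 0.15` per Charlson point — baseline hospitalizations are
  generated with Charlson diagnoses and feed back into the death hazard,
  so the CCI comparison models (C and D) have genuine signal to find.
* `admission_rate_base = 0.10`/person-year with a ×1.17 step per risk
  class — the base reproduces roughly the published 48.6% of persons with
  at least one follow-up hospitalization; the step is the 11th root of the
  published top readmission IRR (5.62).

Prescription rows are emitted so that a positive person satisfies exactly
the intended rule (codes are chosen per class so that no emitted code
matches any other class's rule) and a configurable fraction of negatives
receive sub-threshold rows, including tramadol-only opioid negatives.
Exposures are drawn independently across classes by default; a Gaussian
copula option (`exposure_correlation`) emulates real-world comorbidity
clustering for stress tests. That is also the generator's main departure
from real data: in a real population, the same patients accumulate many
drug classes, so high risk classes (8–11) are far better populated than
independence produces. Passing tests on synthetic data therefore establish
correctness of the machinery and qualitative gradients, not the published
cohort-specific magnitudes.

```{r, eval = FALSE}
sim <- simulate_cohort(simulation_config(n_persons = 20000, seed = 1))
ex  <- detect_exposures(sim$prescriptions, sim$persons)
sv  <- derive_survival(sim$persons)
w   <- derive_ddci_weights(ex, sv, sim$persons)
reproduce_table2(w)$n_match
```

## Numerical choices and degenerate inputs

* Date arithmetic is in days; years = days / 365.25. Files are comma
  separated with ISO-8601 dates — one documented dialect, no locale drift.
* Persons dead or emigrated before the index date, under 40 at index, or
  with malformed fields are rejected at load into a counted report; a
  missing file or wrong header is fatal.
* `derive_survival()` takes the earliest of death, migration and horizon;
  ties between death and the horizon count as events.
* Classes with constant exposure in a (small) training set are inestimable
  and are excluded from the Cox fit with a warning, reported at weight 0.
* Cox fits flag suspected separation (standard error > 10); non-converged
  fits refuse to produce weights.
* `harrell_c` and `nri` reject degenerate inputs (no usable pairs, no
  events, no non-events) rather than returning NaN.

## Problem sizes used by the test suite

The packaged tests run the parameter-recovery experiment at n = 100,000
(the size at which the weight-agreement property is specified), the
prevalence and gradient checks at n = 50,000, and the remaining simulation
checks at 20,000 or below; these sizes keep the full suite in the
few-minute range on a single core while leaving every binomial 3-SE check
well-powered. At n = 100,000 (~10,700 deaths) the Cox coefficient standard
errors range from 0.02 for common classes to ~0.3 for the rarest (opioids,
0.05% prevalence), so re-derived coefficients match the generative truth
within 3 SE, while the *integer* weights — a 0.3-wide rounding grid with
three true coefficients lying within 0.04 of a boundary — agree with the
published column for 14–17 of 19 classes depending on the seed. That
stochasticity is a property of desk-scale re-derivation, not of the
implementation; even a population-scale cohort would miss a near-boundary
class roughly one run in ten.

## Known limitations

* Exposure independence (see above) under-populates high risk classes at
  default settings.
* The category-free NRI is not numerically comparable to categorical NRI
  values computed elsewhere.
* Censoring before the horizon excludes a person from the NRI denominator
  unless IPCW is enabled; the published handling is undocumented.
* The CCI mapping covers the Deyo ICD-9-CM adaptation only; no ICD-10,
  no Elixhauser or combined scores.
* Hospital transfer chains are not merged; each admission record stands
  alone.
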