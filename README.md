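# ddci — the Drug Derived Complexity Index from prescription claims

Comorbidity indices built from hospital discharge diagnoses (such as the
Charlson Comorbidity Index) only describe people who were admitted.
Community pharmacy claims cover nearly everyone, so chronic exposure to
specific drug classes can proxy chronic disease for a whole population.
The **Drug Derived Complexity Index (DDCI)** turns a year of ATC-coded
dispensing records into 19 drug-class exposure flags and an integer score,

&nbsp;&nbsp;&nbsp;&nbsp;DDCI = Σₖ wₖ · 1{exposed to class k},&nbsp;&nbsp;
wₖ = round(βₖ / 0.3),

where βₖ is the class coefficient from a multivariate Cox
proportional-hazards model of overall mortality, rounding is to the
nearest integer with halves away from zero, and classes not significantly
associated with mortality are excluded. Scores are binned into 12 risk
classes (≤ 0 → class 0, 1–10 → themselves, ≥ 11 → class 11).

The package is aimed at pharmacoepidemiologists and health-services
researchers who want to apply, re-derive, or stress-test
prescription-based risk scores on administrative claims. It provides:

* **Claims I/O** — readers/writers and validation for persons /
  prescriptions / hospitalizations tables (`read_cohort()`,
  `derive_survival()`).
* **Exposure rules** — the 19 published drug-class rules as executable,
  configurable data, including the C07AB09 exclusion, the
  codeine/tramadol opioid exclusion, and the 45-day hypertensive-heart
  combination rule (`default_rule_table()`, `detect_exposures()`).
* **Scoring** — raw score, risk classes, and a bundled Deyo ICD-9-CM
  Charlson index for comparison (`compute_ddci()`, `assign_class()`,
  `compute_cci()`).
* **Weight derivation** — Cox fit, Wald significance filter, and the
  divide-by-0.3 rounding rule (`fit_cox()`, `derive_weights()`,
  `reproduce_table2()`).
* **Evaluation** — Kaplan–Meier curves, class-wise hazard ratios,
  Harrell's survival C-index, continuous Net Reclassification
  Improvement, and Poisson readmission rate ratios (`compare_models()`,
  `harrell_c()`, `nri()`, `readmission_irr()`).
* **Synthetic cohorts** — a claims simulator whose defaults reproduce the
  published study conditions, so the whole pipeline is testable without
  real data (`simulate_cohort()`, `make_worked_fixture()`).

## Worked example

Scoring the bundled hand-made fixture:

```r
library(ddci)
fx <- make_worked_fixture()                       # 15 persons, every rule branch
ex <- detect_exposures(fx$prescriptions, fx$persons)
sc <- compute_ddci(ex)
sc[sc$person_id %in% c("W07", "W10", "W11"), ]
#>    person_id raw_score risk_class
#> 7        W07         6          6
#> 10       W10        -3          0
#> 11       W11        14         11
```

W07 is exposed to opioids only (weight 6); W10 takes a statin and an
immunosuppressant (weights −2 and −1, the only protective classes), lands
on the minimum attainable score −3, and is folded into risk class 0; W11's
three neurological/opioid exposures sum to 14, capped into the top class.

An end-to-end run on a synthetic 20,000-person cohort — simulate, split
50/50, derive weights on the training half, score and evaluate the
validation half:

```r
run <- run_pipeline(pipeline_config(
  simulation = simulation_config(n_persons = 20000, seed = 1),
  model = "A"))
#> [  0.9s] cohort: 20000 persons, 141968 prescriptions, 18250 hospitalizations
#> [  1.2s] weights derived on training set: 8/19 match the published table
#> [  1.5s] model A: C 0.743 -> 0.761, NRI 0.332
print(run$comparison)
#> model comparison at horizon 7.00 (n=10000, events=989, excluded=340)
#>   C-index: reference 0.743 (0.728-0.759)  augmented 0.761 (0.746-0.776)  delta +0.018
#>   NRI: 0.3317 (0.2674-0.3959) = events -0.1567 + non-events 0.4884
```

Adding the score to the age–sex model raises discrimination slightly and
reclassifies strongly on the non-event side — the same signature the
published analysis reports for overall mortality. (At n = 20,000 the
re-derived integer weights are noisy — a 0.3-wide rounding grid against
coefficient standard errors up to 0.3 for the rarest classes; the
agreement count rises to 14–17/19 at n = 100,000.) Class-wise hazard
ratios rise monotonically with the risk class:

```r
head(run$class_hr, 4)
#>   class    n hazard_ratio   ci_low  ci_high      p_value
#> 1     0 4375     1.000000       NA       NA           NA
#> 2     1 2908     1.471231 1.248639 1.733506 3.967634e-06
#> 3     2 1392     2.155668 1.795067 2.588708 1.967636e-16
#> 4     3  580     2.139741 1.669426 2.742553 1.890974e-09
```

See `vignettes/ddci-methods.Rmd` for the model, the rule semantics, every
tunable parameter with its default and rationale, and known limitations.

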