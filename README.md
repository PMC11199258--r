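# pottelscore

Detecting drug-associated nephrotoxicity in extremely low birth weight
(ELBW, ≤ 1000 g) neonates from serum creatinine (Scr) is confounded by
physiology: healthy ELBW infants show a progressive Scr rise peaking around
postnatal days 3–4 followed by a slow decline, so rise-based acute kidney
injury (AKI) rules — like the neonatal modified KDIGO stage-1 criterion
(rise ≥ 0.3 mg/dL or ≥ 50% versus the previous value) — can flag normal
trajectories and need at least two measurements.

`pottelscore` implements the rescaled-creatinine alternative for
pharmacovigilance of the three nephrotoxic drugs most used in this
population (ibuprofen, amikacin, vancomycin). The core quantity is the
**Pottel score**

```
score(i, d) = Scr(i, d) / Q(d)
```

where `Q(d)` is the reference population's median (p50) Scr at postnatal
day `d`. In a reference population the score sits near 1 at every age, so a
single measurement becomes interpretable. Around it, the package provides:

* **Reference tables** — read/write/validate day-specific p50 tables, or
  estimate one from a cohort's drug-free days (`build_reference()`).
* **Exposure coding** — lag-1 binary indicators (drug given the day before
  the measurement) and consecutive-days-of-treatment categories
  (0, 1, …, 5+) from long-format administration calendars.
* **Linear mixed models** (REML via lme4) — the day-wise model
  `score ~ log(day) * exposed + (1 + log(day) | patient)` with
  exposed-vs-unexposed contrasts per day, and the cumulative model of
  consecutive treatment days; both available adjusted for the co-drug.
* **Comparator staging** — the literal mKDIGO stage-1 rule and detector
  concordance tables.
* **A seeded synthetic ELBW cohort simulator** — 201 patients / ≈ 3200
  observations by default, physiologic trajectory, realistic drug courses,
  saturating drug effects, irregular sampling and dropout, with full ground
  truth — so the entire pipeline is testable without patient data.

All user-facing functions take plain data frames (long format) and return
tibbles; fitted models support `tidy()`, `glance()`, and `autoplot()`.

## Worked example

```r
library(pottelscore)

# a fully synthetic cohort: demographics, creatinine, drug calendar + truth
cohort <- simulate_cohort(sim_params(n_patients = 201, seed = 7))

# score against the cohort's own generating reference curve
ref <- validate_reference(data.frame(
  day = cohort$ground_truth$reference$day,
  p50_scr_mg_dl = cohort$ground_truth$reference$q))
scored <- score_cohort(cohort$obs, ref, cohort$calendar)

summarize_drug_free(scored)
#> # A tibble: 1 × 5
#>       n  mean    sd skewness excess_kurtosis
#>   <int> <dbl> <dbl>    <dbl>           <dbl>
#> 1  2161 0.987 0.259    0.708           0.487

# day-wise ibuprofen effect, adjusted for antibiotics
fit <- fit_daywise_model(scored, cohort$calendar, "ibuprofen",
                         adjust_group = DRUG_GROUPS$antibiotics)
estimate_day_contrasts(fit, c(4, 5, 10))
#>   analysis drug_group day_or_category mean_exposed mean_unexposed   diff
#> 1  daywise  ibuprofen               4         1.02          0.991 0.0255
#> 2  daywise  ibuprofen               5         1.04          0.989 0.0509
#> 3  daywise  ibuprofen              10         1.11          0.984 0.1296
#>     ci_lo  ci_hi  p_value
#> 1 0.00527 0.0457 1.35e-02
#> 2 0.03418 0.0675 2.28e-09
#> 3 0.09935 0.1599 4.73e-17

# cumulative effect of consecutive treatment days, same adjustment
cm <- fit_cumulative_model(scored, cohort$calendar, "ibuprofen",
                           adjust_group = DRUG_GROUPS$antibiotics)
cm$effects[, c("day_or_category", "mean_exposed", "diff", "p_value")]
#>   day_or_category mean_exposed    diff  p_value
#> 1               0        0.985 0.00000       NA
#> 2               1        0.988 0.00323 8.07e-01
#> 3               2        1.040 0.05486 4.42e-04
#> 4               3        1.099 0.11398 8.33e-11
#> 5               4        1.042 0.05706 1.47e-02
#> 6              5+        1.109 0.12432 1.51e-11
```

The drug-free summary shows the score's null calibration: mean ≈ 1 with
SD ≈ 0.26 over the 2161 measurement days not preceded by any drug
administration. The day-wise contrasts read: on postnatal day 4, infants
exposed to ibuprofen the day before have a mean score 0.026 higher (95% CI
0.005–0.046) than unexposed infants, with the difference growing with
postnatal age — the generator injected a saturating multiplicative effect of
that order, so the model recovers it. The cumulative table shows the mean
score climbing from ≈ 0.99 at category 0 to ≈ 1.10 by day 3 of consecutive
treatment and then flattening (category estimates above 3 are noisier:
fewer infants reach long uninterrupted courses).

The mKDIGO comparator shows why rescaling matters: on a *null* cohort
(drug effects off) the physiologic rise still trips the stage-1 rule in a
large fraction of patients during days 2–4, while score-threshold flags
stay at their tail rate (`compare_detectors()`).

A thin command-line interface wraps the same functions:

```sh
Rscript inst/cli/pottel.R simulate --seed 7 --n 201 --out cohort/
Rscript inst/cli/pottel.R analyze --demographics cohort/demographics.csv \
  --obs cohort/observations.csv --exposures cohort/exposures.csv \
  --ref ref.csv --out effects.csv
```

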