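---
title: "Rescaled creatinine pharmacovigilance in ELBW neonates: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rescaled creatinine pharmacovigilance in ELBW neonates: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pottelscore)
library(dplyr)
```

## The problem

Extremely low birth weight (ELBW, ≤ 1000 g) neonates are at high risk of
drug-induced acute kidney injury (AKI), and they are routinely exposed to
nephrotoxic drugs: ibuprofen for pharmacological closure of a persistent
ductus arteriosus, and amikacin plus vancomycin for suspected late-onset
sepsis. Detecting nephrotoxicity from serum creatinine (Scr) is hard in this
population because healthy ELBW neonates show a strong *physiologic* Scr
trajectory — a progressive rise over the first days of life peaking around
postnatal days 3–4 followed by a slow decline. Rise-based AKI definitions
such as the neonatal modified KDIGO rule (stage 1: a rise of 0.3 mg/dL or
≥ 50% versus the previous value) assume a steady state, need at least two
measurements, and can flag the physiologic rise itself.

The package implements an alternative: the **Pottel score**, the measured
Scr divided by the reference population's median (p50) Scr for the same
postnatal day,

$$\mathrm{score}(i, d) \;=\; \frac{\mathrm{Scr}(i, d)}{Q(d)},$$

where $Q(d)$ is the day-$d$ p50. In a reference population the score is
distributed around 1 at every postnatal age, so a *single* measurement
becomes interpretable, and departures attributable to drug exposure can be
modelled directly.

## The analysis pipeline

1. **Cohort filtering** (`apply_exclusions()`, `restrict_window()`):
   patients are excluded for duplicated records, early neonatal death
   (before day 7), late referral (admission at or after day 15), or
   insufficient baseline creatinine data; observations are restricted to
   postnatal days 1–28. "Insufficient baseline" is operationalized as fewer
   than `min_baseline_obs` (default 1) observations on days 1–3 — a
   configurable choice, since no formal definition exists. Reasons are
   assigned in a fixed priority order (duplicate → early death → late
   referral → insufficient baseline) so each patient receives exactly one
   disposition.
2. **Scoring** (`score_cohort()`): every observation is divided by the
   reference p50 of its day. Scores are never clipped, rounded, or
   extrapolated: a day outside reference coverage is an error.
3. **Drug-free calibration** (`summarize_drug_free()`): a measurement day is
   *drug-free* when none of the three drugs was administered on the
   preceding day. Day 1, having no prior day, is drug-free by construction.
   Moments of the drug-free score distribution describe the null
   calibration; normality is reported descriptively, not tested. Whether
   same-day administration should additionally disqualify a day is an open
   question in the field; the lag-1 rule is implemented literally.
4. **Exposure coding** (`lag_indicator()`, `consecutive_days()`): treatment
   is a binary variable equal to 1 when the drug was given on the day before
   outcome evaluation (a 1-day pharmacological lag), and the cumulative
   variable is the length of the uninterrupted administration run ending on
   that previous day, categorized 0, 1, 2, 3, 4, 5+ (a gap of one day or
   more resets the run).
5. **Mixed models** (`fit_daywise_model()`, `fit_cumulative_model()`,
   `adjusted_analysis()`): see below.
6. **Comparator staging** (`mkdigo_stage1()`, `compare_detectors()`): the
   literal stage-1 rise rule against the immediately preceding measurement,
   for concordance analysis with score-threshold flagging.

## The linear mixed models

Both model families have the Pottel score as response and per-patient
random effects to respect the longitudinal structure, estimated by REML
via `lme4::lmer`.

**Day-wise model.** Fixed effects: log postnatal day, the lag-1 exposure
indicator, and their interaction; random intercept and random slope on the
same log-day scale. The log transform handles the non-linear time trend (it
gave a better AIC than spline alternatives in the motivating analysis, a
property the test suite reproduces on log-trended synthetic data). The
exposed-vs-unexposed difference at day $d$ is
$\beta_{\mathrm{exp}} + \beta_{\mathrm{int}}\log d$, with a Wald 95% CI from
the fixed-effect covariance and a two-sided p-value; α = 0.05 throughout, no
multiplicity correction. Contrasts are reported only for days on which at
least two distinct patients were exposed, and never outside the observed day
range. Putting the random slope on log-day (rather than raw day) keeps the
random and fixed time scales consistent; mixing scales would make the
variance components hard to interpret.

**Cumulative model.** Fixed effects: log day plus the consecutive-days
category (reference: category 0); same random-effects structure. Category
means are evaluated at the mean log-day of the fitted data, and each
category is contrasted against category 0. Categories with fewer than 2
observations are merged upward into the next category (the top category
merges downward) and the merges are recorded on the fit object.

**Confounding adjustment.** Because ibuprofen and antibiotic exposure
co-occur, multivariable models add the co-drug's lag indicator and its
log-day interaction. Reported means and contrasts fix the co-drug indicator
at 0 (i.e., they describe infants unexposed to the co-drug) — the estimand
was genuinely open, and this choice makes the adjusted and unadjusted
tables directly comparable. Perfectly collinear exposure indicators are
refused with an explicit error; an adjustment group with no administrations
reduces exactly to the unadjusted fit.

**Numerical behaviour.** If the correlated intercept-and-slope structure is
singular or fails to converge, the fit falls back to an uncorrelated
structure, then to intercept-only; every downgrade is recorded
(`$downgraded`, `$re_structure`). Inference is Wald/normal; small-sample
degree-of-freedom corrections (Kenward–Roger, Satterthwaite) are out of
scope, which makes the tests mildly anti-conservative at small n — the null
calibration test below quantifies this.

## The mKDIGO comparator and numeric boundaries

`mkdigo_stage1()` implements the stage-1 rule exactly as worded: a rise of
at least 0.3 mg/dL *or* at least 50% compared with the immediately
preceding measured value (not a 48-hour window, not a lowest-prior
baseline). Both-rule hits report the absolute trigger with the relative
indicator retained. Creatinine values are decimal fractions with no exact
binary representation — `0.6/0.4` evaluates to `1.4999999999999998` — so the
comparisons carry a `1e-9` slack to keep decimal-exact boundaries (a rise
of exactly 0.30, a ratio of exactly 1.5) on the flagged side. Score
flagging (`flag_scores()`) deliberately has **no default threshold**: the
1.33 upper limit established for children above 2 years is not assumed to
transfer to ELBW neonates, and a population-derived cut such as
`mean + 1.96·SD` of the cohort's own drug-free scores is the recommended
starting point.

## The synthetic cohort generator

No ELBW creatinine cohort of this kind is public, so the package ships a
fully seeded generator (`simulate_cohort()`) whose defaults encode the
study conditions the analysis assumes:

$$\mathrm{Scr}(i,d) = Q(d)\, e^{b_{0i} + b_{1i}\log d}\, C(d)\, M(i,d)\,
e^{\varepsilon},$$

with $b_{0i} \sim N(0, \sigma_b^2)$, $b_{1i} \sim N(0, \sigma_s^2)$,
$\varepsilon \sim N(0, \sigma_e^2)$, and
$C(d) = \exp\{-(\sigma_b^2 + \sigma_s^2 \log^2 d + \sigma_e^2)/2\}$ the
log-normal mean correction that makes $E[\mathrm{Scr}/Q] = 1$ exactly on
drug-free days. $M(i,d)$ multiplies in the drug effects: each drug group
contributes a multiplier determined by the consecutive-exposure run ending
on day $d-1$, from a saturating 5-entry profile.

Key defaults and why:

* `q_curve()`: $Q(d) = 0.35 + 0.60\,(d/3.5)\,e^{1-d/3.5}$ mg/dL — rises
  from 0.70 at day 1 to a 0.95 peak spanning days 3–4, then declines slowly.
  This is a **synthetic** curve with the physiologic shape only; the
  original study's p50 table is not public and these are not its values.
* `sigma_b = 0.20`, `sigma_s = 0.05`, `sigma_e = 0.12` (log scale): give a
  marginal drug-free score SD ≈ 0.25 at mid-window days, matching the
  reported calibration of ≈ 1.0 (SD ≈ 0.26) in this population.
* Ibuprofen: 61.7% of patients, course start days 2–6 (PDA treatment
  window), duration median 3 days (range 1–14); effect profile
  `(1.030, 1.058, 1.082, 1.100, 1.112)` for consecutive days 1…5+, a
  saturating shape consistent with reported cumulative score means (≈ +0.03
  after one day, ≈ +0.08 after three, ≈ +0.11 at five or more).
* Antibiotics: an episode in 81% of patients (both drugs in 87% of
  episodes), starting from day 4 (late-onset sepsis is > 72 h), amikacin
  median 6 days, vancomycin median 7; effect profile
  `(1.005, …, 1.027)` — a much smaller effect, as reported.
* Sampling: per-day observation probability `0.95·exp(-0.04(d-1))`, ≈ 16
  observations per patient over 28 days (≈ 3200 for 201 patients); late
  neonatal death in 8.5% truncates the series.
* `abx_follow_ibu_prob` (default 0) forces the antibiotic episode to start
  on the ibuprofen start day with the given probability — the knob used to
  *construct* exposure confounding in the validation suite.

Because drug effects are multiplicative on Scr (additive on the log score),
while the analysis models the score additively, the two scales agree only
approximately; at the small effect sizes involved (0.03–0.13 on a scale of
1) the discrepancy is far below the inferential noise, and the recovery
tests account for it.

**What the generator does not emulate**: correlated measurement occasions
(sampling is independent Bernoulli given survival), informative sampling or
dropout (sicker infants are measured *more* often in reality), repeat drug
courses within a patient, carry-over effects after cessation, dose or
drug-level information, and covariates such as gestational age acting on
the score. Passing the validation suite therefore shows the *statistical
machinery* is correct and calibrated under the stated generative model — it
does not validate the clinical tool on real data.

Two distributional notes. First, the per-day *median* of the
mean-one-calibrated log-normal score sits $\exp(-\sigma^2/2) \approx 3\%$
below $Q(d)$; `build_reference()`'s median estimator inherits this small
offset, which the ±5% recovery band absorbs (the recovery test averages 30
seeded replicates at n = 200 so that Monte-Carlo noise does not dominate the
comparison). Second, a log-normal with total log-SD ≈ 0.25 has skewness
≈ 0.8: the drug-free score distribution is therefore mildly right-skewed
rather than exactly normal, and a `mean + 1.96·SD` threshold captures ≈ 4%
of null observations rather than the nominal normal-tail 2.5% — the
detector-divergence test uses a band that reflects this computable
property.

## Reference table estimation

`build_reference()` estimates $Q(d)$ as the per-day median of Scr over
drug-free days only (exposure inflates creatinine and would contaminate the
reference). Days with fewer than `min_n_per_day` (default 5) eligible
values are filled by linear interpolation between directly estimated
neighbours — the simplest defensible rule; centile smoothing (GAM or
quantile regression) is deliberately out of scope. Interpolated days are
flagged in the returned table, and multiple same-day values from one
patient all count (no within-day deduplication is imposed). The default
neonatal reference is day-specific only — no sex split, since sex-specific
rescaling belongs to the method's use in older children.

## Validation design and problem sizes

The test suite validates each stage against an independent oracle or a
known ground truth, at sizes chosen to keep the full run within a routine
CI budget:

* exact scoring identities and scale equivariance (1000 randomized triples);
* exposure run-length coding and mKDIGO staging against brute-force
  re-enumeration oracles (1000 random calendars / series each);
* null calibration: 100 seeded null cohorts at n = 100, day-5 ibuprofen
  contrast, rejection rate required in 5% ± 4 pp;
* parameter recovery: constant +0.10 score-scale effect, 50 seeds at
  n = 200 — mean estimate within ±0.02, CI coverage in [88%, 100%];
* cumulative shape recovery: a profile rising over exposure days 1–3 then
  flat, 50 seeds at n = 200, monotone-then-flat category means required in
  ≥ 45/50 runs;
* confounding correction: antibiotics active and correlated with inert
  ibuprofen; adjusted ibuprofen CI must cover 0 in ≥ 90% of 50 runs while
  the unadjusted covers it in < 70%;
* detector divergence, reference-curve recovery, and byte-level seed
  determinism.

## Known limitations

* Wald/normal inference without small-sample df corrections; at n ≲ 50
  patients expect mild anti-conservatism.
* The additive-score model of a multiplicative biological effect is an
  approximation (excellent at small effects).
* The bundled reference curve is synthetic; real use requires a
  population-appropriate p50 table, and the package's `build_reference()`
  estimator needs sufficient drug-free sampling density per day.
* Prolonged post-cessation drug effects, urine-output criteria, and other
  nephrotoxic co-medications are out of scope.
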