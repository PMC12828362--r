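---
title: "Modelling cumulative oesophageal dose and high-grade toxicity in thoracic re-irradiation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cumulative oesophageal dose and high-grade toxicity in thoracic re-irradiation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reirrtox)
```

## The problem

Patients with recurrent lung or oesophageal cancer increasingly receive a
second course of thoracic radiotherapy. The oesophagus is a serial,
dose-limiting organ: grade >=3 toxicity (oesophagitis requiring
hospitalisation, stenosis, haemorrhage, perforation, tracheo-oesophageal
fistula) can be life-threatening, and evidence-based *cumulative* dose
constraints — limits on the total dose the oesophagus receives across both
courses — are scarce. Individual re-irradiation series are small, so the
practical route to a constraint is to pool study-level and patient-level
dose/toxicity information from the literature and fit a normal-tissue
complication probability (NTCP) model to the pooled data. `reirrtox`
implements that analysis as a reusable, tested workflow.

## Dose accumulation: EQD2

Fraction sizes differ wildly across re-irradiation series (conventional
2 Gy fractions through single-fraction SABR), so physical doses are not
comparable. All doses are rescaled to the equivalent dose in 2-Gy fractions
under the linear-quadratic model,

$$\mathrm{EQD2} = D\,\frac{d + \alpha/\beta}{2 + \alpha/\beta},$$

with $D$ the total dose, $d$ the dose per fraction, and $\alpha/\beta$ the
tissue sensitivity ratio: 3 Gy for late-responding tissue (events after
3 months) and 10 Gy for acute effects. `eqd2()` performs the conversion and
`cumulative_eqd2()` sums courses at a common $\alpha/\beta$; the resulting
`eqd2_dose` objects carry their $\alpha/\beta$ annotation and refuse
arithmetic across different ratios, so Gy$_3$ and Gy$_{10}$ quantities are
never silently mixed. No repopulation or inter-course recovery correction is
applied: doses add directly, and the interval between courses enters the
analysis only as a candidate regression covariate. Headline constraints are
expressed in Gy$_3$, the late-toxicity convention.

## The dose-response model

The outcome is binary: did the patient experience grade >=3 oesophageal
toxicity. The model is plain logistic regression on the cumulative
oesophageal maximal dose $CD$ (Gy EQD2) and the concurrent-chemotherapy
indicator $CC$:

$$p = \frac{1}{1 + e^{-(\beta_0 + \beta_d\,CD + \beta_c\,CC)}}.$$

The pooled literature data are *mixed granularity*: some studies report
patient-by-patient doses, others only a study median dose and an event
count. `fit_logistic()` maximises the joint likelihood in which a patient
contributes a Bernoulli term at their own covariates and a grouped study of
$n$ patients with $e$ events contributes a Binomial$(n, e)$ term at the
study's representative (median) dose and *fractional* chemotherapy rate.
The coding of study-level chemotherapy as a fraction in $[0,1]$ (rather
than dichotomised at 50%) is a genuine design choice — aggregated reports
do not say which patients received chemotherapy — and both codings are
supported (`cohort_chemo`), with fraction the default because it preserves
the study mean of the linear predictor's chemotherapy term.

The log-likelihood is reported as the kernel, without the binomial
coefficient, so that a grouped study of $n$ identical patients has
*literally* the same log-likelihood (and therefore the same fit) as the
$n$ expanded patient records; the granularity of reporting then cannot move
the estimates.

### Numerical choices

Fitting is damped Newton-Raphson on the exact likelihood: full Newton steps
with step-halving whenever a step would decrease the likelihood,
convergence when the largest score component falls below $10^{-8}$, at most
100 iterations, covariance from the inverse observed information. Complete
separation — possible in small bootstrap resamples — is detected two ways:
a coefficient escaping $|\beta| > 50$ (absurd on the per-Gy scale), or a
converged score with every fitted probability saturated within $10^{-6}$ of
0 or 1, which is how separation actually manifests numerically with
dose-scale covariates. Separated fits are flagged non-converged and never
returned as estimates; no penalisation is applied, because the analysis
reports plain maximum-likelihood estimates. Missing covariates are handled
by per-model complete-case filtering with an audited dropped-unit count —
never imputation.

## Model screening and selection

Candidate predictors (dose, chemotherapy, interval) are first examined by
median splits with $\chi^2$ or Fisher's exact tests (`median_split()`,
`contingency_test()`; Fisher is used when any expected cell is below 5, the
conventional rule), then screened univariably: predictors with a Wald
p-value below 0.2 enter the multivariable model (`screen_univariable()`).

Competing specifications are compared by leave-one-*study*-out
cross-validation (`loocv_by_cohort()`): each study in turn is held out, the
model is refitted, and the held-out study is scored by its negative
log-likelihood under that fit; fold scores are summed and the lowest total
wins. Holding out whole studies rather than patients scores generalisation
*across* studies, which is the relevant question for literature-pooled
data. Folds where any specification fails to converge are excluded
identically across specifications so totals stay comparable.

## Dose constraints and their uncertainty

The fitted curve is inverted in closed form to the iso-risk dose
$CD(p) = (\mathrm{logit}(p) - \beta_0 - \beta_c CC)/\beta_d$
(`invert_dose()`); with both dose and chemotherapy in the model the two
curves are parallel with constant horizontal offset $\beta_c/\beta_d$
(`chemo_dose_shift()`). Two interval methods are provided:

* **Delta method** (`wald_ci_dose()`): the coefficient covariance is
  propagated through the inversion gradient. The published table's
  non-bootstrap intervals do not state their method; the delta method is
  the standard inverse-prediction interval and is labelled "Wald"
  throughout.
* **Study-level block bootstrap** (`block_bootstrap_ci()`): whole studies
  are resampled with replacement (resample size = observed study count),
  the model refitted and re-inverted per resample, and the central 95%
  percentile interval taken (lowest and highest 2.5% of predictions
  excluded). Resampling clusters rather than units preserves the
  between-study heterogeneity (overdispersion) that a binomial interval
  would ignore. Separated or non-convergent replicates are dropped from
  the percentiles and counted; more than 50% failures aborts. Intervals
  are never truncated at zero — a strong chemotherapy effect can push the
  lower bound of a low-risk constraint below 0 Gy, and that is reported as
  such. The percentile method (not BCa) is used deliberately, matching the
  exclude-the-tails definition of the published procedure.

All resampling is driven by one documented seed, recorded in the output;
identical seeds give identical intervals.

## Diagnostics

`decile_calibration()` sorts complete-case units by modelled risk, cuts
them into ten equal-count bins (remainder spread over the lowest bins; ties
broken by a stable sort on predicted risk then unit id, so grouped data bin
deterministically), and correlates per-bin mean predicted with observed
rates (Pearson, t-reference on 8 degrees of freedom).
`threshold_validation()` reports observed toxicity rates strictly above
versus at-or-below a candidate constraint — "above" is strict by
documented convention. `run_pipeline()` chains every stage in the order
above and emits CSV/JSON artifacts plus a manifest (seed, unit counts,
dropped units per stage).

## The packaged dataset

`builtin_fixture()` ships a study-level transcription of 21 published
thoracic re-irradiation series: 505 patients, 49 patients with grade >=3
oesophageal toxicity from 57 itemised events (eight patients had both an
acute and a late event). Grouped per-study counts come from the itemised
event descriptions where available, otherwise from the rounded study-level
rate; the two known discrepancies are resolved in favour of the itemised
integer counts and recorded in the packaged `fixture_notes.md`, never
averaged. "Not recorded" entries are explicit missing values. A
pseudo-patient expansion (every patient at the study median dose, events
spread evenly, chemotherapy assigned to match the study fraction) is
provided for exercising patient-level code paths and is flagged
`reconstructed`: it is *not* observed individual data, and analyses on it
mirror the published unit-level results only qualitatively.

## The synthetic-data generator

`simulate_patients()` draws multi-study datasets with the structure the
analysis assumes: about 20 studies of 1-60 patients; per-study log-normal
dose locations (median 84.8 Gy, between-study log-SD 0.5, within-study
log-SD 0.35, truncated to 0-250 Gy, spanning the observed 3.7-220.6 Gy
range); per-study chemotherapy probabilities from a Beta(0.3, 0.3) —
deliberately bimodal, since real study policies are mostly all-or-none;
log-normal intervals (median 15.5 months, truncated to 1-162); and events
from the true logistic model, defaulting to coefficients
$(-7.0065, 0.0431, 2.2065)$. `design_fixture_like()` pins study sizes,
doses, chemotherapy rates and intervals to the packaged dataset.

What the generator does *not* emulate — and what passing tests therefore do
not establish about real data: publication bias, between-study differences
in toxicity grading and follow-up, dose-metric heterogeneity (D$_{max}$ vs
D1cc), volume effects, and any dose-chemotherapy confounding with disease
stage. The generator's events come from exactly the fitted model family, so
recovery and coverage results certify the estimation machinery, not the
biological truth of the logistic form.

## Verification scale and observed behaviour

The test suite verifies, at sizes chosen to make the checks sharp but
quick: closed-form and oracle equivalences (brute-force likelihood grid
search on 6-unit sets; hypergeometric enumeration of Fisher's test up to
n = 40); parameter recovery on 100 simulated datasets of 10,000 patients;
LOOCV preference for the generating dose+chemotherapy model over dose alone
on 100 simulated 21-study datasets (~2,000 patients each); and block
bootstrap coverage of the true 5% iso-risk dose on 200 simulated 21-study
datasets at 500 resamples each. Two of the measured results are worth
stating honestly. The joint "all three coefficients within 3 SE" recovery
event is a +/-3 SE criterion applied jointly to three correlated estimates,
whose theoretical rate is itself about 99%; the suite observes 98/100, with
per-coefficient z-scores unbiased and unit-variance, so this reflects the
criterion's lack of sampling slack rather than an estimation defect. And
the percentile block bootstrap *undercovers* at the study's own scale: with
only 21 resampled clusters the suite observes 87.5% coverage (175/200) for
the nominal 95% interval, with near-total replicate convergence — the known
small-cluster-count limitation of percentile cluster bootstraps, not an
implementation defect. It implies that bootstrap intervals produced this
way at this scale are, if anything, optimistically narrow.

## Known limitations

* Grouped studies enter at their median dose; if within-study dose spread
  is wide and the curve is locally convex, the binomial-at-median term is
  biased relative to the patient-level likelihood. This is inherent to
  aggregated reporting, not repairable in software.
* The reconstructed patient expansion of the packaged data cannot
  reproduce the published unit-level subset (144 patients with individual
  doses), whose membership was never printed; threshold-discrimination and
  calibration figures on the expansion are qualitative mirrors.
* Wald intervals on the inverted dose rely on asymptotic normality of a
  ratio; with 21 studies they can be wide and are not range-preserving.
* The model ignores irradiated oesophageal volume, dose-rate and technique;
  it predicts risk from cumulative point dose and chemotherapy only.
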