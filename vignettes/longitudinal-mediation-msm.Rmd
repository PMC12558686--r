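---
title: "Longitudinal causal mediation with marginal structural models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Longitudinal causal mediation with marginal structural models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

`msmmed` estimates the total and direct effects of a time-varying binary
exposure on a terminal binary (or continuous) outcome in a three-wave
cohort, with a time-varying binary mediator, time-varying confounding and
informative dropout. The motivating setting is oral-health epidemiology
in older adults: chewing disability (the hardest of six food-toughness
groups a person can chew, dichotomized) at waves 1 and 2, loneliness
(Three-Item Loneliness Scale, TILS 0–12, dichotomized at ≥ 1 or ≥ 4) as
the mediator at waves 1 and 2, and clinically significant depressive
symptoms (11-item CES-D 0–22, dichotomized at ≥ 7) at wave 3.

Standard regression fails here for a structural reason: the mediator is
affected by earlier exposure and in turn influences later exposure and
dropout (exposure–mediator feedback). Conditioning on it blocks part of
the effect and opens collider paths; ignoring it leaves confounding.
Marginal structural models (MSMs) resolve this by weighting rather than
conditioning.

## Model and estimation

Each subject contributes stabilized inverse-probability weights at each
wave:

* exposure: SW^X_t = P(X_t | X̄_{t−1}) / P(X_t | X̄_{t−1}, M̄_{t−1}, L_t),
* mediator: SW^M_t = P(M_t | X̄_t, M_{t−1}) / P(M_t | X̄_t, M_{t−1}, L_t),
* censoring: SW^C_t = P(C_t = 1 | X̄_{t−1}) / P(C_t = 1 | X̄_{t−1}, M̄_{t−1}, L_t),

fitted as main-effects logistic regressions among subjects at risk, with
L_t the time-invariant covariates plus the current wave's time-varying
covariates. The product SW_total across waves defines the
pseudo-population; by default one combined weight (exposure × mediator ×
censoring) serves both outcome models, with the exposure × censoring
variant available (`combine_weights(include_mediator = FALSE)`).

A numerator may condition **only on terms that also appear in the
weighted outcome model** (here: exposure history; for mediator weights
also mediator history). Putting the lagged mediator in the exposure- or
censoring-weight numerators looks harmless but leaves the
X_t–M_{t−1} dependence in the pseudo-population, and the total-effect
model — which marginalizes over the mediator — is then biased. Our
calibration simulations measured roughly +0.28 on a true risk ratio of
1.5 under that variant, which is why the package fixes the numerators as
above and keeps the mediator history in the denominators, where it acts
as a confounder.

The outcome models are weighted pooled modified Poisson regressions with
a log link and heteroskedasticity-robust (HC0 sandwich) standard errors,
one independent unit per subject (a single terminal outcome needs no
clustering):

* total effect: log P(Y = 1 | x̄) = β0 + β1·cum(x̄),
* direct effect: log P(Y = 1 | x̄, m̄) = β0 + β1·cum(x̄) + β2·cum(m̄),

where `cum(·)` is by default the *mean* of the two wave indicators
(0, ½, 1), so exp(β1) is the single always-vs-never relative risk; sum
coding (0, 1, 2) is available. The mediated share is decomposed on the
excess-relative-risk scale,

proportion mediated = (RR_total − RR_direct) / (RR_total − 1) × 100,

which closes to 100% with the direct share by construction and is
reported as undefined (not NaN) when RR_total ≤ 1. The mediator's own
relative risk is exp(β2) from the direct model. For continuous
analyses the same weights feed identity-link least-squares models;
mean differences convert to approximate relative risks as
exp(0.91 · MD / SD), with the unexposed group's outcome SD as the
default reference.

## Tunable parameters that matter

| parameter | default | meaning |
|---|---|---|
| `exposure_rule` | strict | group 1 only = no disability (lenient: groups 1–2) |
| `mediator_threshold` | 1 | TILS ≥ 1 = any loneliness (4 = "mostly lonely") |
| `outcome_threshold` | 7 | CES-D ≥ 7 = clinically significant symptoms |
| `truncate` | 0.95 | upper percentile capping SW_total (linear-interpolation percentile) |
| `prob_bounds` | (0.05, 0.95) | positivity alarm bounds on predicted probabilities |
| `cum_coding` | mean | cumulative exposure/mediator coding |
| `mi$m`, `mi$max_iter` | 10, 5–10 | imputations and chained sweeps |
| `bootstrap$B` | 5000 | BCa replicates for release runs |

Truncation is upper-only at the 95th percentile by default (capping is a
deliberate bias-for-variance trade; diagnostics report the 1st/5th/95th/
99th percentiles before and after, and symmetric truncation is
available). Positivity is screened by the fraction of denominator-model
predicted probabilities outside (0.05, 0.95); a zero denominator
probability is an error, never a silent clip.

## The synthetic cohort generator and its oracle

No public version of the motivating cohort exists, so the package ships
a generator whose defaults emulate its wave-1 profile: 53.5% female,
ethnicity 76.0/15.3/7.7/1.0%, 67.6% primary education or below, housing
6.7/27.1/66.2%, age 70.4 (SD 7.1), social support 30.2 (SD 12.6),
chewing disability 16.8%, loneliness 41.7%, baseline depressive
screening positivity 16.2%, wave-3 outcome prevalence 10.3%. Wave-1
intercepts are solved numerically against the realized covariate draws,
so these margins hold for any structural-coefficient setting. Retention
is 0.80 into wave 2 and 0.75 into wave 3 among those at risk — heavy,
informative attrition in the spirit of the motivating panel while
keeping analysis sets usable.

The causal graph: a scalar frailty score (fixed linear combination of
the measured covariates, so main-effects logistic weight models are
exactly correctly specified) drives exposure, mediator, retention and
outcome; exposure persists across waves and responds to the lagged
mediator (feedback); the outcome depends on cumulative exposure,
cumulative mediator and frailty. The latent CES-D is Gaussian, rounded
and clipped to 0–22, so the binary outcome (≥ 7) and the continuous
score come from one cohort; consequently the outcome coefficients are in
score points, not log-odds. TILS is hurdle-style — a logistic "any
loneliness" indicator plus a positive-part magnitude — so both the ≥ 1
and ≥ 4 thresholds are meaningful cut-points. Baseline CES-D is a
*pre-exposure* covariate (generated before wave-1 exposure): eligibility
screening then selects on a pre-treatment variable, and the oracle
applies the same restriction, so estimator and ground truth target the
same population. An earlier design in which baseline symptoms responded
to wave-1 loneliness made the screen a post-exposure collider and
produced an apparent (and spurious) bias of ~+0.3 on the risk ratio.

`true_effects()` replays the structural equations under interventions
with common random numbers and censoring removed: always exposed, never
exposed, and always exposed with the mediator held at its natural
never-exposed path (a randomized-interventional analogue of the natural
direct effect — the estimand choice is ours, since dichotomized
longitudinal mediation has no canonical nested-counterfactual label).
Default structural coefficients were calibrated once against this
oracle to a true total RR ≈ 1.49 with a genuinely mediated component
(true direct RR ≈ 1.36).

What the generator does *not* emulate: survey weights and household
sampling, interviewer effects, item-level questionnaire responses,
food-group texture semantics (the chewing group is an abstract ordinal),
direct outcome-dependent (MNAR) dropout — dropout is informative only
through measured frailty and exposure — and any misspecification of the
weight models' functional form. Passing tests therefore demonstrate
correctness of the estimation machinery under a data-generating process
the models can represent, not robustness to real-world misspecification.

## Missing data

Chained-equations imputation (m = 10 by default) runs among subjects
observed through wave 3, sweeping columns in causal order (covariates →
exposure → mediator → outcome) with logistic posterior draws for binary
columns and predictive mean matching (5 donors) for scores; every other
analysis variable, including the outcome, predicts each target. Ratio
effects pool across imputations on the log scale by Rubin's rules and
back-transform. Deterministic best/worst-case completions assign all
dropouts outcome 0 or 1, carry wave-2 exposure/mediator forward from
wave 1 for subjects lost before wave 2, and re-fit with
exposure × mediator weights only (censoring is no longer a selection
event). The bracketing behaviour of these completions is directional:
the best case scales the risk ratio by roughly the arms' retained
fractions (1−d₁)/(1−d₀), so the pair straddles the censoring-weighted
estimate when dropout is not concentrated among the exposed — the
regime our bracket simulations use — and both fall below it when it is.

## Uncertainty

The BCa bootstrap resamples subjects with replacement at the original n
and re-runs the *entire* pipeline — weight models included — inside
every replicate; resampling only the outcome stage would understate
variance. Bias correction z0 counts replicates below the point estimate
(ties as half), acceleration comes from jackknife skewness, and the
endpoints are BCa-adjusted order statistics with normal-scale
interpolation. Replicates that fail to fit are dropped and counted
(> 5% warns, > 50% errors); truncation is applied inside each replicate.
Test runs use B in the hundreds with correspondingly widened Monte-Carlo
tolerances; release runs default to B = 5000. E-values use the closed
form RR* + sqrt(RR*(RR*−1)) with RR* = max(RR, 1/RR), and the CI E-value
is 1 when the interval crosses the null.

## Numerical and design choices

* Calibration simulations (the test suite's parameter-recovery checks)
  pool replicate estimates of ratio effects on the log scale — the same
  convention used for Rubin pooling — and evaluate the untruncated
  estimator; truncation's deliberate bias is assessed separately. At the
  reference scenario (n = 5000 per cohort, analysis sets ≈ 2500) the
  pipeline recovers the oracle total RR within ±0.05 and robust-Wald
  null coverage sits near 94–97%.
* Problem sizes in the test suite (cohorts of 1.5–5k subjects, 200–500
  replicates, B = 399–2000 bootstrap replicates, m = 5–10 imputations)
  were chosen as the smallest sizes at which the Monte-Carlo error is
  comfortably inside each assertion's tolerance.
* Weight-model separation (fitted probabilities within 1e−10 of 0/1) and
  non-convergence are hard errors naming the model; imputation
  sub-models instead fall back to observed-margin draws with a warning,
  because a chained sweep should not die mid-chain.
* Degenerate inputs (constant outcomes, single-subject risk sets,
  all-censored strata, RR ≤ 1 decompositions, zero-variance bootstrap
  statistics) raise typed errors or explicit "undefined" reports rather
  than NaNs.
* Percentiles are linear-interpolation (R type 7) everywhere weights are
  truncated; BCa endpoints use the normal-scale interpolation
  conventional for bootstrap order statistics.

## Known limitations

* The direct-effect estimand is a randomized-interventional analogue;
  it is not a natural direct effect under a nested-counterfactual
  definition, and the oracle's direct contrast differs slightly from
  the direct model's coefficient even asymptotically (observed gap
  ≈ 0.03 on the RR scale at the reference scenario).
* The log-linear MSM in cum(x̄) is a two-parameter fit through three
  exposure levels; when the marginal log-risk is not exactly linear the
  exponentiated slope differs from the always-vs-never ratio by a small
  projection error (≈ +0.01 here).
* Weight models are parametric main-effects logistic regressions by
  design; no machine-learning weight estimation is provided.
* MI assumes missingness at random given the analysis variables among
  subjects observed through wave 3; the best/worst completions bound
  only the outcome's missingness, not covariate MNAR.
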