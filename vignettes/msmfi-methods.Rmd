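---
title: "Marginal structural growth models for food insecurity and memory decline: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{msmfi methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The estimation problem

`msmfi` estimates the effect of a time-varying binary exposure — food
insecurity, coded from two survey items — on the *trajectory* of a
repeatedly measured continuous outcome, a standardized memory score, in a
biennial panel of adults aged 50+. Three features make the naive regression
`memory ~ exposure * time + covariates` untrustworthy here:

1. **Exposure-confounder feedback.** Income, marital status, depressive
   symptoms and health burden both *predict* future food insecurity and
   are *affected by* past food insecurity. Adjusting for them as
   covariates removes part of the exposure's effect (the mediated share)
   and can open collider paths; leaving them out leaves confounding.
2. **Informative loss to follow-up.** Dropout is predicted by the same
   social and health variables, so complete-follow-up persons are a
   selected sample.
3. **Truncation by death.** The outcome is undefined after death; death is
   a competing terminal event, *not* censoring to be reweighted. Creating
   a pseudo-population in which nobody dies over 18 years would answer a
   question about an impossible world, so — deliberately — no
   inverse-probability-of-death weights are used, and "censoring" means
   loss to follow-up from causes other than death only.

The package implements the standard remedy: a marginal structural model
(MSM) fitted by stabilized inverse-probability-of-treatment weighting
(IPTW) combined with inverse-probability-of-censoring weighting (IPCW),
followed by an IP-weighted growth model

\[ E[Y_t \mid A_t] = \beta_0 + \beta_1 A_t + \beta_2 t + \beta_3 A_t t, \]

with time \(t\) in years since baseline. \(\beta_3\) — the
exposure-by-time coefficient — is the quantity of interest: the
difference in yearly rate of outcome change between exposed and unexposed.
The companion translation \((\beta_3 / \beta_2) \times 10\) expresses it
as *excess years of aging per decade*.

## Weights

For every wave \(t \ge 1\) four logistic models are fitted on the at-risk
set (alive, uncensored, complete model covariates):

* exposure denominator: \(P(A_t = 1 \mid A_{t-1}, L_{t-1}, V)\),
* exposure numerator: \(P(A_t = 1 \mid A_{t-1})\),
* censoring denominator: \(P(C_t = 1 \mid A_{t-1}, L_{t-1}, V)\) with the
  dead removed from the risk set,
* censoring numerator: \(P(C_t = 1 \mid A_{t-1})\).

Stabilized weights are the ratio of numerator to denominator probability
of the *observed* state (exposed/unexposed; remaining uncensored). The
final weight is the running product over waves of both ratios, truncated
at the 1st/99th percentiles of the pooled person-wave cumulative weight
distribution (type-7 linear interpolation between order statistics; the
convention is fixed because percentile definitions differ across
toolkits). Two truncation modes exist: `cap` (default) clamps weights to
the bounds; `exclude` drops person-waves outside the bounds, which is the
variant that shrinks the analytic sample and is provided because published
analyses sometimes report a post-truncation sample reduction.

**Baseline weighting.** The per-wave stabilized weights randomize exposure
*transitions* given prior exposure, but they leave the cross-sectional
confounding of the baseline exposure untouched. With a persistent exposure
and ten waves of selective attrition, that surviving baseline confounding
projects into the exposure-by-time coefficient and attenuates it
materially (set `weight_baseline = FALSE` in the parameter-recovery study
to reproduce the attenuation). The default therefore also
stabilizes the baseline exposure, with the marginal prevalence as
numerator and a logistic model in \(V\) and baseline \(L\) as denominator,
completing the sequentially randomized pseudo-population.
`weight_model_spec(weight_baseline = FALSE)` restores the
wave-0-weight-equal-one convention for comparison.

Balance diagnostics report, per wave, standardized mean differences (SMD)
between current-exposure groups for every weight-model confounder, before
and after weighting. Following the dominant balance-diagnostic convention
the SMD denominator is the *unweighted* pooled SD (binary covariates use
the pooled binomial SD), so reweighting moves only the means. Propensity
quartile summaries per exposure group provide the positivity check.

## Growth model and inference

Two estimators share the same fixed-effect structure:

* `weighted_mixed` — `lme4::lmer` with person random intercept + slope and
  the final weights as analytic weights. Weighted likelihood for mixed
  models is not cleanly defined, so on any convergence failure the fit
  downgrades (and records the downgrade) to
* `weighted_gls_independence` — weighted least squares treating persons as
  independent clusters. This is the methodologically safer pairing with
  IPW (an "independence working model") and is what the bootstrap and the
  simulation-based validation use; the two estimators agree on the point
  estimate to well within the estimand's magnitude.

Inference is by person-level bootstrap: persons (entire trajectories) are
resampled with replacement and the *whole* pipeline — all per-wave
propensity fits, weight cumulation, truncation, growth model — is re-run
inside each replicate, so the intervals carry weight-estimation
uncertainty. Intervals are percentile-based. Re-estimation inside
replicates is the default (reusing frozen weights is available as a
config option). The replicate loop has a compiled implementation (IRLS in
C++) that is bit-validated against the interpreted reference path in the
test suite; numerator models, being saturated logistic fits on one binary
covariate, use their closed form (group proportions).

## The synthetic cohort: what it emulates, and what a green test means

`simulate_cohort()` generates the *stated world* the estimator is
validated in: ten biennial waves, baseline age 67.7 (SD 10.95, truncated
at 50), ~5.2% baseline exposure prevalence rising mildly over follow-up,
outcome declining 0.045 SD/year among the unexposed with
`slope_effect_psi = -0.003` SD/year of additional decline while exposed,
substantial mortality (age-graded), ~3-4% per-wave loss to follow-up, 4%
wave nonresponse and 3% item missingness handled by last observation
carried forward. Exposure enters the outcome through the slope, so the
generator's truth *is* the exposure-by-time coefficient, making parameter
recovery the acceptance surface. A Monte-Carlo oracle
(`evaluate_true_regime_difference`) simulates both static regimes with
coupled covariate draws (outcome noise independent per regime, so its SE
is honest) and confirms the regime slope difference equals
`slope_effect_psi` up to a small mediated transient.

Three design choices deserve emphasis, because they were forced by what
the estimator can and cannot identify:

* **Frailty loads on the outcome level, and on the time-varying
  covariates only through their baseline draws.** A latent frailty raises
  chronic burden, depressive symptoms and dropout while lowering income
  and the memory level. If frailty also fed each wave's covariate
  *innovations*, the exposure (which responds to current covariates)
  would carry frailty signal that weight models conditioned on last
  wave's covariates cannot block — residual confounding by construction.
  Real panels surely contain some of this; the generator keeps it out of
  the default world so that a biased pipeline fails the tests for the
  right reason. Chronic burden, being cumulative, carries the baseline
  frailty signal across all waves, preserving cross-sectional
  confounding realism.
* **Attrition is (nearly) uninformative for the slope.** Death depends on
  age, prior exposure, health burden and income — but not directly on the
  random slope or frailty. Because death is truncation and is deliberately
  not reweighted (matching the analysis design), strongly
  slope-informative mortality would make the regime slope difference
  unrecoverable by *any* estimator conditioning on survival; the published
  analysis itself flags mortality-related attenuation as a limitation
  rather than correcting it. The generator therefore reserves informative
  selection for the outcome *level* (which IPCW partially corrects via
  observed covariates) and leaves slope heterogeneity exogenous.
* **Exposure-model magnitudes are moderate.** Inverse-probability
  estimators with a ~5% exposure are fragile under extreme propensities:
  cumulative weights compound multiplicatively over nine waves, and heavy
  weight tails produce finite-sample attenuation even with *true* weights.
  Coefficients were chosen so the post-truncation final weights have mean
  ≈ 0.98 and SD ≈ 0.3 — the behaviour reported for the real analysis —
  rather than the much heavier tails stronger coefficients would imply.

A green parameter-recovery test therefore establishes that the pipeline
removes the confounding and selection *it was designed to remove*, in a
world where the identification assumptions hold and weights are
well-behaved. It does not establish robustness to unmeasured confounding,
same-wave covariate-exposure feedback, slope-informative mortality, or
positivity violations — all of which real data may contain.

## Numerical and policy choices

* Income and wealth are equivalized by \(\sqrt{\text{household size}}\)
  and log-transformed. Wealth can be zero or negative, so the default
  transform is the signed log1p, \( \mathrm{sign}(x)\log(1+|x|) \); plain
  natural log is available for strictly positive inputs.
* Exposure coding from the two items: "no" to *enough money for food*
  → insecure; "yes" → secure; don't-know/refusal falls through to the
  *ate less* item; if that is also uninformative the value is missing
  (handled by LOCF or the recoding scenarios) rather than forced to
  secure — the published rule covers only the two informative answers.
* Eligibility exclusions are applied in a fixed order (age floor →
  missing baseline exposure → no outcome at any wave) so exclusion counts
  are reproducible.
* LOCF carries values forward only while a person is alive and under
  observation, across any number of consecutive missing waves; outcomes
  are never imputed; nothing is carried past death or loss to follow-up.
* Truncation percentile bounds are computed once from the pooled
  distribution (not per wave).
* All randomness flows from one master seed through named substreams
  (baseline, covariates, exposure, noise, censoring, death, nonresponse,
  missingness, oracle, bootstrap), so each margin is independently
  reproducible.
* The bootstrap resampling unit is the person; the published analysis
  does not state whether weights were re-estimated within replicates —
  re-estimation is the default here because intervals should reflect
  weight-estimation uncertainty.
* Baseline age appears in the weight models only, not in the outcome
  model, following the analysis description it mirrors.

## Sensitivity scenarios

Five one-change-at-a-time scenarios re-run the full pipeline: recoding
missing exposure to always-secure or always-insecure (instead of LOCF), a
complete-case analysis, freezing health covariates at baseline in the
treatment-weight models (they stay time-varying in censoring models), and
replacing parental education with a continuous childhood
socioeconomic-circumstances proxy. The proxy is generated by the
simulator as a latent variable correlated with parental education,
education and region of birth — the validated instrument the scenario
mirrors is not reconstructible from public information, so this is a
synthetic stand-in and is labelled as such.

## Known limitations

* The weighted mixed model treats analytic weights as precision weights
  (the convention of the tooling it mirrors); the GLS-independence
  estimator plus person bootstrap is the recommended inference route.
* The generator does not emulate complex survey design, proxy-based
  outcome measurement, or the construction of the composite memory score.
* With `exclude`-mode truncation the analytic sample depends on the
  weight distribution, so bootstrap replicates can differ slightly in
  size; this matches the behaviour the mode is meant to reproduce.
* Finite-sample IPW bias toward the null grows with weight variance; at
  the default desk scale (n = 5000) it is a visible fraction of the tiny
  true effect, and the validation tolerances account for it.
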