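# msmfi

Marginal structural models for the effect of time-varying **food
insecurity** on **memory decline** in ageing-cohort panels.

## The problem

Biennial panel studies of older adults measure a standardized memory score
alongside a two-item food-insecurity screen, repeatedly over ~18 years.
Estimating how food insecurity changes the *rate* of memory decline is hard
because the obvious covariates — income, wealth, marital status, depressive
symptoms, chronic disease — are simultaneously confounders of future
exposure and consequences of past exposure (*exposure-confounder
feedback*), and because follow-up ends informatively through dropout and
death. Standard covariate adjustment over-adjusts (it blocks mediated
effects and conditions on colliders); ignoring attrition leaves selection
bias.

`msmfi` implements the standard g-method remedy end to end:

1. per-wave **stabilized inverse-probability-of-treatment weights**
   (IPTW), with the baseline exposure stabilized as well,
2. per-wave **inverse-probability-of-censoring weights** (IPCW), where
   censoring means loss to follow-up *other than death* — death is a
   competing terminal event and is deliberately not reweighted,
3. cumulation across waves and percentile **truncation** (1st/99th),
4. an **IP-weighted growth model**
   `E[Y_t | A_t] = β0 + β1 A_t + β2 t + β3 A_t t` (time in years since
   baseline) fitted by weighted mixed model or weighted GLS with
   independence working correlation,
5. **person-level bootstrap** percentile confidence intervals that re-run
   the entire pipeline in each replicate,
6. the **excess-years-of-aging** translation `(β3 / β2) × 10`,
7. balance (standardized mean differences before/after weighting) and
   positivity diagnostics, Table-1-style descriptives, and the standard
   **sensitivity analyses** (exposure recoding, complete case,
   time-invariant health confounders, alternative childhood-SES covariate),
8. a **synthetic cohort generator** with known causal truth
   (exposure acts additively on the outcome slope), used to validate the
   whole pipeline by parameter recovery and bootstrap coverage.

## Worked example

```r
library(msmfi)

# a synthetic biennial cohort: 5000 persons, 10 waves, ~5.2% baseline
# exposure, true extra decline while exposed = -0.003 SD/year
params <- msmfi_sim_params(n_subjects = 5000, seed = 42)
sim    <- simulate_cohort(params)
print(sim$truth)

run <- run_msm(sim$panel, pipeline_config(
  growth_spec = growth_model_spec("weighted_gls_independence"),
  n_boot = 200, seed = 42))
print(run$result)
```

Output from this exact script:

```
True regime slope difference: -0.00338 SD/year (MC SE 0.00061, n_mc 2000)
Inverse-probability-weighted growth model (weighted_gls_independence)
  n persons 5000, person-waves 29806
  exposure                -0.01563 (95% CI -0.0812 to 0.04714)
  time_years              -0.03613 (95% CI -0.03796 to -0.0346)
  exposure:time_years     -0.00524 (95% CI -0.01108 to 0.002215)
  excess years of aging per decade: 1.45
  bootstrap replicates: 200
```

Reading it: the exposure-by-time coefficient estimates the difference in
yearly decline between the always-exposed and never-exposed regimes; here
the point estimate (−0.0052 SD/year) sits within one bootstrap standard
error of the generator's truth (−0.003; one cohort of this size cannot pin
down an effect this small, which is why the validation suite averages over
50 cohorts). The excess-aging line translates the slope difference into
extra years of memory aging per decade. The time coefficient (−0.036) is
flatter than the person-level mean slope (−0.045) because mortality removes
the fastest decliners — a real feature of truncation by death that the
method, by design, does not undo.

Other entry points: `describe_baseline()` (Table-1-style summary),
`compute_weights()` / `cumulate_and_truncate()` / `balance_report()`
(weight diagnostics), `bootstrap_cis()`, `run_scenario()` /
`collate_scenarios()` (sensitivity analyses), `write_panel()` /
`read_panel()` (tidy CSV + JSON dictionary interchange).

Command line (full artifact bundle: panel, weights, balance, results,
trajectory plot, scenario table):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/msmfi.R", package="msmfi"))')" \
  --seed 42 --n 2000 --boot 200 --estimator weighted_gls_independence \
  --scenarios complete_case,health_time_invariant --out demo_run
```

## Validation

`tests/testthat/test-acceptance.R` checks, on synthetic cohorts with known
truth: unbiased recovery of the exposure-by-time effect (and smaller bias
than covariate-adjusted regression), stabilized-weight behaviour, balance
restoration (all post-weighting SMDs < 0.25), bootstrap coverage of the
true effect in [0.90, 0.99], equivalence of all logistic fits with a
brute-force likelihood oracle, and deterministic plumbing (LOCF
idempotence, censoring monotonicity, exact eligibility accounting,
bit-reproducible runs). See `vignettes/msmfi-methods.Rmd` for the model,
its assumptions, and every numerical design choice.
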