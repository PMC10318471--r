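# Fixtures built in code: a hand-constructable person-wave panel with the
# same column layout the simulator emits.

panel_row <- function(person_id, wave, exposure = 0L, outcome = 0,
                      status = "active", responded = 1L, age0 = 70,
                      married = 1L, log_eq_income = 3, log_eq_wealth = 4.4,
                      chronic_count = 1L, depressive_sx = 1L, bmi = 26.6,
                      drinks = 0L, smokes = 0L, sex = 1L,
                      education_years = 12, race_group = 0L,
                      parental_edu_gt_hs = 0L, born_south = 0L,
                      childhood_ses = 0) {
  data.frame(person_id = person_id, wave = wave, time_years = 2 * wave,
             age0 = age0, sex = sex, education_years = education_years,
             race_group = race_group, parental_edu_gt_hs = parental_edu_gt_hs,
             born_south = born_south, childhood_ses = childhood_ses,
             married = married, log_eq_income = log_eq_income,
             log_eq_wealth = log_eq_wealth, chronic_count = chronic_count,
             depressive_sx = depressive_sx, bmi = bmi, drinks = drinks,
             smokes = smokes, exposure = exposure, outcome = outcome,
             status = status, responded = responded)
}

# panel from a compact per-person wave description:
# waves = list(list(wave=0, exposure=..., ...), ...)
mini_panel <- function(persons) {
  do.call(rbind, lapply(seq_along(persons), function(i) {
    do.call(rbind, lapply(persons[[i]], function(args) {
      do.call(panel_row, c(list(person_id = i), args))
    }))
  }))
}

# n-person fully-active panel of k waves with iid covariate noise, used by
# property-style tests needing structure but not realism
flat_panel <- function(n, k, seed = 1) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(n), function(i) {
    do.call(rbind, lapply(seq_len(k) - 1L, function(w) {
      panel_row(i, w, exposure = rbinom(1, 1, 0.3),
                outcome = rnorm(1), log_eq_income = rnorm(1, 3, 0.5),
                chronic_count = rpois(1, 1.5),
                depressive_sx = rpois(1, 1.5),
                married = rbinom(1, 1, 0.5), bmi = rnorm(1, 26, 4))
    }))
  }))
}

# Brute-force logistic maximum likelihood: direct BFGS maximization of the
# Bernoulli log-likelihood, independent of glm's IRLS and of the compiled
# solver it checks.
brute_force_logit <- function(X, y) {
  nll <- function(b) {
    eta <- as.vector(X %*% b)
    -sum(y * eta - log1p(exp(eta)))
  }
  gr <- function(b) {
    p <- stats::plogis(as.vector(X %*% b))
    -as.vector(t(X) %*% (y - p))
  }
  stats::optim(rep(0, ncol(X)), nll, gr, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))$par
}

default_gls_config <- function(n_boot = 0L, seed = 1L, ...) {
  pipeline_config(growth_spec = growth_model_spec(
    "weighted_gls_independence"), n_boot = n_boot, seed = seed, ...)
}
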