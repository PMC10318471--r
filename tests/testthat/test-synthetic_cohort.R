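test_that("parameter validation names the offending parameter", {
  expect_error(msmfi_sim_params(n_subjects = 0), "n_subjects")
  expect_error(msmfi_sim_params(n_waves = 1), "n_waves")
  expect_error(msmfi_sim_params(residual_sd = -1), "residual_sd")
  expect_error(msmfi_sim_params(item_missing_rate = 1.5),
               "item_missing_rate")
  expect_error(msmfi_sim_params(confounding_strength = c(nope = 1)),
               "nope")
  expect_error(msmfi_sim_params(death_logit_coeffs = c(intercept = -3)),
               "death_logit_coeffs")
})

test_that("same seed gives identical panels; different seed differs", {
  p <- msmfi_sim_params(n_subjects = 300, seed = 99)
  s1 <- simulate_cohort(p, truth_n_mc = 0)
  s2 <- simulate_cohort(p, truth_n_mc = 0)
  expect_identical(s1$panel, s2$panel)
  p2 <- msmfi_sim_params(n_subjects = 300, seed = 100)
  expect_false(identical(simulate_cohort(p2, truth_n_mc = 0)$panel,
                         s1$panel))
})

test_that("panel structure invariants hold", {
  sim <- simulate_cohort(msmfi_sim_params(n_subjects = 500, seed = 3),
                         truth_n_mc = 0)
  pan <- sim$panel
  expect_equal(nrow(pan), 500 * 10)
  expect_equal(pan$time_years, 2 * pan$wave)
  rank <- c(active = 0, lost = 1, dead = 1)
  for (d in split(pan, pan$person_id)) {
    d <- d[order(d$wave), ]
    expect_equal(d$wave, 0:9)                 # contiguous waves
    st <- d$status
    # once lost or dead, never active again, and the terminal state is fixed
    expect_true(all(diff(rank[st]) >= 0))
    first_gone <- match(TRUE, st != "active")
    if (!is.na(first_gone)) {
      expect_true(all(st[first_gone:length(st)] == st[first_gone]))
    }
  }
  gone <- pan$status != "active" | pan$responded == 0L
  expect_true(all(is.na(pan$outcome[gone])))
  expect_true(all(is.na(pan$exposure[gone])))
  expect_true(all(pan$age0 >= 50))
})

test_that("baseline exposure prevalence matches the generative model", {
  # independent oracle: re-draw the baseline covariate distributions from
  # their documented specification (plain R, no generator code) and
  # integrate the exposure model numerically
  set.seed(424242)
  n <- 200000
  lo <- pnorm(50, 67.7, 10.95)
  age0 <- qnorm(runif(n, lo, 1), 67.7, 10.95)
  sex <- rbinom(n, 1, 0.646)
  educ <- pmin(pmax(round(rnorm(n, 13.0, 2.98)), 0), 17)
  race <- rbinom(n, 1, 0.185)
  parent <- rbinom(n, 1, 0.113)
  south <- rbinom(n, 1, 0.375)
  frailty <- rnorm(n, 0, 0.5)
  income_t <- 3.0 + 0.08 * (educ - 13) - 0.30 * race
  income <- income_t - 0.14 * frailty + rnorm(n, 0, 0.55)
  married <- rbinom(n, 1, plogis(0.04))
  chronic <- pmin(qpois(runif(n), exp(-0.20 + 0.03 * (age0 - 68) +
                                        0.50 * frailty)), 8)
  depr <- pmin(qpois(runif(n), exp(0.30 + 0.30 * frailty -
                                     0.10 * (income - 3))), 8)
  eta <- -3.59 +
    (-0.35) * (married - 0.5) + (-0.55) * (income - 3.0) +
    0.12 * (chronic - 1.5) + 0.18 * (depr - 1.5) +
    (-0.02) * (age0 - 68) + 0.35 * sex + (-0.06) * (educ - 13) +
    0.90 * race + (-0.25) * parent + 0.40 * south
  implied <- mean(plogis(eta))

  sim <- simulate_cohort(msmfi_sim_params(n_subjects = 50000, seed = 77),
                         truth_n_mc = 0)
  emp <- mean(sim$panel$exposure[sim$panel$wave == 0])
  mc_err <- 3 * sqrt(implied * (1 - implied) / 50000)
  expect_lt(abs(emp - implied), mc_err + 0.002)
  # and the implied value sits at the calibrated ~5.2%
  expect_lt(abs(implied - 0.052), 0.004)
})

test_that("regime oracle recovers the slope effect and scales correctly", {
  # null effect
  p0 <- msmfi_sim_params(n_subjects = 100, slope_effect_psi = 0, seed = 1)
  tr0 <- evaluate_true_regime_difference(p0, n_mc = 2000)
  expect_lt(abs(tr0$true_slope_difference), 2 * tr0$mc_se)

  # psi = -0.003, additive-on-slope: pooled over 10 seeds
  est <- se2 <- numeric(10)
  for (s in 1:10) {
    p <- msmfi_sim_params(n_subjects = 100, seed = s)
    tr <- evaluate_true_regime_difference(p, n_mc = 2000)
    est[s] <- tr$true_slope_difference
    se2[s] <- tr$mc_se^2
  }
  pooled_se <- sqrt(mean(se2) / 10)
  expect_lt(abs(mean(est) - (-0.003)), 2 * pooled_se + 5e-4)

  # Monte-Carlo scaling: doubling n_mc shrinks the SE by ~1/sqrt(2)
  pa <- msmfi_sim_params(n_subjects = 100, seed = 5)
  a <- evaluate_true_regime_difference(pa, n_mc = 4000)
  b <- evaluate_true_regime_difference(pa, n_mc = 8000)
  expect_gt(a$mc_se / b$mc_se, 1.15)
  expect_lt(a$mc_se / b$mc_se, 1.75)
  expect_error(evaluate_true_regime_difference(pa, n_mc = 10), "n_mc")
})

test_that("item missingness injection hits the stated rate and targets", {
  sim <- simulate_cohort(msmfi_sim_params(n_subjects = 2000, seed = 6,
                                          item_missing_rate = 0,
                                          nonresponse_rate = 0),
                         truth_n_mc = 0)
  pan <- sim$panel
  expect_identical(inject_item_missingness(pan, 0, 1), pan)

  full <- inject_item_missingness(pan, 1, 1)
  post <- full$wave > 0 & full$status == "active" & full$responded == 1
  expect_true(all(is.na(full$exposure[post])))
  expect_true(all(!is.na(full$exposure[full$wave == 0])))  # baseline kept
  expect_identical(full$outcome, pan$outcome)              # outcomes kept

  some <- inject_item_missingness(pan, 0.1, 2)
  frac <- mean(is.na(some$exposure[post]))
  expect_lt(abs(frac - 0.1), 3 * sqrt(0.1 * 0.9 / sum(post)))
})

test_that("with all confounding and attrition off, the naive slope contrast
           recovers the true effect", {
  off <- c(intercept = -20, a_prev = 0, age = 0, chronic_count = 0,
           depressive_sx = 0, log_eq_income = 0, frailty = 0)
  p <- msmfi_sim_params(
    n_subjects = 20000, seed = 13,
    confounding_strength = c(married = 0, log_eq_income = 0,
                             chronic_count = 0, depressive_sx = 0),
    feedback_strength = 0, censoring_logit_coeffs = off,
    death_logit_coeffs = off, item_missing_rate = 0, nonresponse_rate = 0)
  sim <- simulate_cohort(p, truth_n_mc = 0)
  pan <- sim$panel
  fit <- stats::lm(outcome ~ exposure * time_years, data = pan)
  co <- summary(fit)$coefficients
  est <- co["exposure:time_years", "Estimate"]
  se <- co["exposure:time_years", "Std. Error"]
  expect_lt(abs(est - (-0.003)), 2.5 * se)
})
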