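small_run <- function(n = 800, seed = 30, ...) {
  p <- msmfi_sim_params(n_subjects = n, seed = seed, ...)
  sim <- simulate_cohort(p, truth_n_mc = 0)
  prepare_panel(sim$panel)$panel
}

test_that("unit-weight GLS equals the closed-form least-squares oracle", {
  pan <- small_run()
  fwu <- data.frame(person_id = pan$person_id, wave = pan$wave,
                    w_cum = 1, w_final = 1)
  res <- fit_weighted_growth_model(
    pan, fwu, growth_model_spec("weighted_gls_independence"))
  rows <- pan$status == "active" & !is.na(pan$outcome) &
    !is.na(pan$exposure)
  X <- cbind(1, pan$exposure[rows], pan$time_years[rows],
             pan$exposure[rows] * pan$time_years[rows])
  beta <- solve(crossprod(X), crossprod(X, pan$outcome[rows]))
  expect_equal(res$beta_exposure, beta[2], tolerance = 1e-8)
  expect_equal(res$beta_time, beta[3], tolerance = 1e-8)
  expect_equal(res$beta_interaction, beta[4], tolerance = 1e-8)
})

test_that("mixed and GLS point estimates agree in expectation", {
  # On any single cohort the two estimators differ by sampling-order noise
  # (they whiten the data differently under informative dropout), so the
  # asymptotic point-target agreement is checked as absence of systematic
  # difference in the paired mean across cohorts.
  d <- vapply(1:6, function(i) {
    pan <- small_run(n = 5000, seed = 410 + i)
    ww <- compute_weights(pan, engine = "irls", keep_fits = FALSE)
    fw <- cumulate_and_truncate(ww)
    gls <- fit_weighted_growth_model(
      pan, fw, growth_model_spec("weighted_gls_independence"))
    mix <- fit_weighted_growth_model(pan, fw, growth_model_spec())
    expect_identical(mix$estimator_used, "weighted_mixed")
    mix$beta_interaction - gls$beta_interaction
  }, 0)
  expect_lt(abs(mean(d)), 2 * stats::sd(d) / sqrt(length(d)) + 5e-4)
})

test_that("excess aging per decade is the stated ratio-times-ten", {
  expect_equal(round(excess_aging_per_decade(-0.0030, -0.045), 2), 0.67)
  expect_equal(excess_aging_per_decade(0, -0.02), 0)
  expect_equal(excess_aging_per_decade(-0.01, -0.01), 10)
  expect_error(excess_aging_per_decade(-0.003, 0), "undefined")
  # pure function, scale-invariant
  for (k in c(0.5, 2, 100)) {
    expect_equal(excess_aging_per_decade(-0.0030 * k, -0.045 * k),
                 excess_aging_per_decade(-0.0030, -0.045))
  }
})

test_that("regime trajectories follow the fitted linear model", {
  res <- structure(list(intercept = 0.9, beta_exposure = 0.017,
                        beta_time = -0.045, beta_interaction = -0.0030),
                   class = "msmfi_result")
  tr <- predict_regime_trajectories(res, horizon_years = 18)
  gap <- tr$always_exposed - tr$never_exposed
  expect_equal(gap[tr$time_years == 0], 0.017)
  expect_equal(gap[tr$time_years == 18], 0.017 + 18 * (-0.0030))
  # no interaction -> parallel lines
  res$beta_interaction <- 0
  tr0 <- predict_regime_trajectories(res)
  expect_equal(diff(range(tr0$always_exposed - tr0$never_exposed)), 0)
})

test_that("bootstrap is deterministic, brackets the point, rejects n=1", {
  pan <- small_run(n = 500, seed = 33)
  b1 <- bootstrap_cis(pan, n_boot = 25, seed = 7)
  b2 <- bootstrap_cis(pan, n_boot = 25, seed = 7)
  expect_identical(b1$ci, b2$ci)
  b3 <- bootstrap_cis(pan, n_boot = 25, seed = 8)
  expect_false(identical(b3$ci, b1$ci))

  pan2 <- small_run(n = 600, seed = 34)
  bb <- bootstrap_cis(pan2, n_boot = 200, seed = 11)
  for (nm in c("exposure", "time_years", "exposure:time_years")) {
    pt <- switch(nm, exposure = bb$beta_exposure,
                 time_years = bb$beta_time, bb$beta_interaction)
    expect_lte(bb$ci[nm, "lower"], pt)
    expect_gte(bb$ci[nm, "upper"], pt)
  }

  one <- pan[pan$person_id == pan$person_id[1], ]
  expect_error(bootstrap_cis(one, n_boot = 5, seed = 1), "two persons")
})

test_that("a quadratic time term is not supported by linear-truth data", {
  pan <- small_run(n = 4000, seed = 35)
  ww <- compute_weights(pan, keep_fits = FALSE)
  fw <- cumulate_and_truncate(ww)
  tab <- msmfi:::.analysis_table(pan)
  sel <- msmfi:::.outcome_rows(tab, fw)
  d <- data.frame(y = tab$outcome[sel$rows], a = tab$exposure[sel$rows],
                  t = tab$time_years[sel$rows], w = sel$w)
  fit <- stats::lm(y ~ a * t + I(t^2), data = d, weights = w)
  z <- summary(fit)$coefficients["I(t^2)", ]
  expect_lt(abs(z["Estimate"] / z["Std. Error"]), 2)
})

test_that("naive covariate-adjusted fit runs and reports the design size", {
  pan <- small_run(n = 500, seed = 36)
  nv <- naive_adjusted_fit(pan)
  expect_true(is.finite(nv$beta_interaction))
  expect_gt(nv$n_obs, 0)
})
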