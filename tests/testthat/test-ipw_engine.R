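prepared_cohort <- function(n = 2000, seed = 5, ...) {
  p <- msmfi_sim_params(n_subjects = n, seed = seed, ...)
  sim <- simulate_cohort(p, truth_n_mc = 0)
  prepare_panel(sim$panel)$panel
}

test_that("logistic fits agree with glm and a brute-force oracle", {
  # 8-row instance, single covariate, checked to 1e-6 against direct
  # likelihood maximization
  X <- cbind(1, c(-1.2, -0.8, -0.3, -0.1, 0.2, 0.6, 1.1, 1.5))
  y <- c(0, 0, 1, 0, 0, 1, 1, 1)
  ref <- brute_force_logit(X, y)
  glm_fit <- suppressWarnings(stats::glm.fit(X, y,
                                             family = stats::binomial()))
  irls <- msmfi:::.irls_logit(X, y)
  expect_equal(unname(glm_fit$coefficients), ref, tolerance = 1e-6)
  expect_equal(as.vector(irls$coefficients), ref, tolerance = 1e-6)

  # larger random instances: compiled IRLS == glm
  for (s in 1:3) {
    set.seed(s)
    X <- cbind(1, matrix(rnorm(150 * 3), 150))
    y <- rbinom(150, 1, stats::plogis(X %*% c(-0.5, 1, -1, 0.3)))
    g <- suppressWarnings(stats::glm.fit(X, y, family = stats::binomial()))
    f <- msmfi:::.irls_logit(X, y)
    expect_equal(as.vector(f$coefficients), unname(g$coefficients),
                 tolerance = 1e-8)
    expect_true(f$converged)
  }
})

test_that("propensity fit: null confounding gives null covariate effects", {
  pan <- prepared_cohort(
    n = 20000, seed = 21,
    confounding_strength = c(married = 0, log_eq_income = 0,
                             chronic_count = 0, depressive_sx = 0),
    feedback_strength = 0, item_missing_rate = 0, nonresponse_rate = 0)
  fit <- fit_propensity(pan, weight_model_spec(), wave = 2, "exposure",
                        "denominator")
  expect_true(fit$converged)
  expect_true(all(fit$fitted_probabilities > 0 &
                    fit$fitted_probabilities < 1))
  # independent glm refit for standard errors
  tab <- msmfi:::.analysis_table(pan, weight_model_spec())
  cols <- msmfi:::.den_columns(weight_model_spec()$denominator)
  sub <- tab[tab$wave == 2 & tab$active == 1 & tab$active_lag == 1 &
               !is.na(tab$exposure), c("exposure", cols)]
  sub <- sub[stats::complete.cases(sub), ]
  g <- stats::glm(exposure ~ ., data = sub, family = stats::binomial())
  se <- summary(g)$coefficients[, 2]
  z <- fit$coefficients[paste0(msmfi:::.L_COLS, "_lag")] /
    se[paste0(msmfi:::.L_COLS, "_lag")]
  expect_true(all(abs(z) < 2.6))  # each within ~2.6 SE of zero
})

test_that("separation is flagged, empty risk sets error", {
  pan <- prepared_cohort(n = 300, seed = 8)
  pan$exposure[pan$status == "active"] <- 1L  # everyone at risk exposed
  fit <- fit_propensity(pan, wave = 1, target = "exposure")
  expect_false(fit$converged)
  pan2 <- prepared_cohort(n = 50, seed = 9)
  expect_error(fit_propensity(pan2, wave = 40, target = "exposure"),
               "empty")
})

test_that("stabilized weight arithmetic matches the ratio definition", {
  pan <- prepared_cohort(n = 400, seed = 10)
  den <- fit_propensity(pan, wave = 1, target = "exposure",
                        role = "denominator")
  num <- fit_propensity(pan, wave = 1, target = "exposure",
                        role = "numerator")
  # p_num = p_den everywhere -> all weights 1
  same <- den
  same$fitted_probabilities <- den$fitted_probabilities
  sw <- stabilized_weights(pan, same, den)
  expect_true(all(abs(sw$sw - 1) < 1e-12))

  # hand-constructed probabilities: exposed 0.05/0.20, unexposed ratio
  ids <- den$person_id[1:2]
  tab <- msmfi:::.analysis_table(pan)
  a <- tab$exposure[match(paste(ids, 1), paste(tab$person_id, tab$wave))]
  fake <- function(p) structure(list(wave = 1, target = "exposure",
                                     fitted_probabilities = stats::setNames(
                                       rep(p, 2), ids),
                                     person_id = ids),
                                class = "msmfi_propensity")
  sw2 <- stabilized_weights(pan, fake(0.05), fake(0.20))
  expect_equal(sw2$sw, ifelse(a == 1, 0.25, 0.95 / 0.80))

  # exact 0/1 denominator probability is a positivity violation
  expect_error(stabilized_weights(pan, fake(0.05), fake(0)),
               "positivity violation.*wave 1")
})

test_that("stabilized treatment weights average to ~1 on a large wave", {
  pan <- prepared_cohort(n = 10000, seed = 12)
  ww <- compute_weights(pan, keep_fits = FALSE)
  m <- tapply(ww$sw_treat, ww$wave, mean)
  expect_true(all(m > 0.9 & m < 1.1))
})

test_that("cumulation and truncation follow the stated percentile rule", {
  # all weights 1 -> cumulative and final weights all 1
  ww <- data.frame(person_id = rep(1:40, each = 3),
                   wave = rep(0:2, 40), sw_treat = 1, sw_cens = 1)
  fw <- cumulate_and_truncate(ww)
  expect_true(all(fw$w_cum == 1) && all(fw$w_final == 1))

  # pooled weights 1..100: cap-mode min/max equal type-7 percentiles
  ww2 <- data.frame(person_id = 1:100, wave = 0L,
                    sw_treat = 1:100, sw_cens = 1)
  ww2$sw_treat <- 1  # wave-0 convention: replace below via two waves
  ww2 <- rbind(ww2,
               data.frame(person_id = 1:100, wave = 1L,
                          sw_treat = 1:100, sw_cens = 1))
  fw2 <- cumulate_and_truncate(ww2, mode = "cap")
  w1 <- fw2$w_cum[fw2$wave == 1]
  expect_equal(sort(w1), 1:100)
  b <- stats::quantile(fw2$w_cum, c(0.01, 0.99), type = 7, names = FALSE)
  expect_equal(unname(attr(fw2, "bounds")), b)
  expect_equal(max(fw2$w_final), b[2])
  expect_equal(min(fw2$w_final[fw2$wave == 1][order(w1)][1]), b[1])

  # exclude mode drops out-of-bounds person-waves and reports analytic n
  fw3 <- cumulate_and_truncate(ww2, mode = "exclude")
  expect_lt(attr(fw3, "n_person_waves"), nrow(ww2))
  expect_true(all(fw3$w_final >= b[1] & fw3$w_final <= b[2]))

  expect_warning(cumulate_and_truncate(ww2[1:50, ]), "unreliable")
})

test_that("balance report: zero SMD for identical groups, weight invariance", {
  pan <- prepared_cohort(n = 3000, seed = 14)
  ww <- compute_weights(pan, keep_fits = FALSE)
  fw <- cumulate_and_truncate(ww)
  bal <- balance_report(pan, fw, wave = 2)
  expect_true(all(is.finite(bal$smd_unweighted)))

  # post-truncation final weights behave like the published distribution:
  # mean near 1, SD a fraction of the mean
  expect_gt(mean(fw$w_final), 0.9)
  expect_lt(mean(fw$w_final), 1.05)
  expect_lt(stats::sd(fw$w_final), 0.6 * mean(fw$w_final))

  # equal weights reproduce the unweighted SMDs exactly
  fw_unit <- fw
  fw_unit$w_final <- rep(1, nrow(fw_unit))
  bal_u <- balance_report(pan, fw_unit, wave = 2)
  expect_equal(bal_u$smd_weighted, bal_u$smd_unweighted)

  # identical covariate distributions across groups -> SMD 0: persons come
  # in pairs with identical covariate trajectories, one exposed per pair
  pan2 <- flat_panel(60, 3, seed = 3)
  odd <- pan2$person_id %% 2 == 1
  for (cl in c("married", "log_eq_income", "chronic_count")) {
    pan2[[cl]][!odd] <- pan2[[cl]][odd]
  }
  pan2$exposure <- as.integer(pan2$person_id %% 2)
  pan2 <- build_censoring_indicators(pan2)
  fwu <- data.frame(person_id = pan2$person_id, wave = pan2$wave,
                    w_cum = 1, w_final = 1)
  b2 <- balance_report(pan2, fwu, weight_model_spec(
    denominator_covariates = c("married", "log_eq_income",
                               "chronic_count")), wave = 2)
  expect_equal(b2$smd_unweighted, rep(0, 3))
})

test_that("censoring risk sets exclude the dead and reconcile with status", {
  pan <- prepared_cohort(n = 2000, seed = 15)
  tab <- msmfi:::.analysis_table(pan)
  for (w in c(2, 5)) {
    fit_c <- fit_propensity(pan, wave = w, target = "censoring")
    dead_ids <- pan$person_id[pan$wave == w & pan$status == "dead"]
    expect_length(intersect(fit_c$person_id, dead_ids), 0)
    # risk set = persons active at w-1 minus those dead at w (with
    # complete covariates); exposure risk set additionally requires
    # being under observation at w
    n_prev <- sum(tab$wave == w & tab$active_lag == 1)
    n_dead <- sum(tab$wave == w & tab$active_lag == 1 & is.na(tab$C))
    expect_lte(fit_c$n_used, n_prev - n_dead)
    fit_a <- fit_propensity(pan, wave = w, target = "exposure")
    expect_lte(fit_a$n_used, fit_c$n_used)
  }
})
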