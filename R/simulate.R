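#' Parameters for the synthetic biennial cohort generator
#'
#' Bundles and validates every knob of the generative model: cohort size and
#' length, the exposure (food insecurity) process, the time-varying covariate
#' process with exposure-confounder feedback, the memory-score outcome model,
#' and the loss-to-follow-up and mortality hazards.
#'
#' Defaults emulate a national ageing-cohort panel: ten biennial waves,
#' baseline age 67.7 (10.95) years truncated at 50, ~5% baseline exposure
#' prevalence, outcome declining 0.045 SD/year among the unexposed, and an
#' additional true decline of 0.003 SD/year while exposed (the exposure acts
#' on the slope, so the generator's truth is exactly the exposure-by-time
#' coefficient the weighted growth model targets).
#'
#' @param n_subjects number of persons.
#' @param n_waves number of biennial waves; time in years is `2 * wave`.
#' @param baseline_age_mean,baseline_age_sd baseline age distribution
#'   (normal, truncated below at 50 years).
#' @param exposure_baseline_logit intercept of the logistic exposure model;
#'   the default gives ~5.2% marginal prevalence at baseline.
#' @param exposure_persistence log-odds carried by prior-wave exposure.
#' @param confounding_strength named coefficients of the (centred)
#'   time-varying confounders in the exposure model; names must be a subset
#'   of the time-varying covariate set.
#' @param feedback_strength scales every effect of prior exposure on current
#'   time-varying covariates (income loss, depressive symptoms, partnership
#'   dissolution, smoking). 0 switches exposure-confounder feedback off.
#' @param v_effect_scale scales the effects of the baseline covariates V on
#'   the exposure logit; 0 (with `confounding_strength = 0`) makes exposure
#'   depend on prior exposure only.
#' @param outcome_intercept_mean,outcome_intercept_sd person-level intercept
#'   of the memory score, SD units.
#' @param slope_mean mean yearly memory change among the unexposed, SD/year.
#' @param slope_effect_psi true additional yearly change while exposed,
#'   SD/year (the marginal structural estimand).
#' @param random_slope_sd SD of the person-level slope deviation, SD/year.
#' @param residual_sd occasion-level measurement noise, SD units.
#' @param frailty_sd SD of a latent person frailty that raises chronic
#'   disease, depressive symptoms, mortality and dropout while lowering the
#'   memory level and steepening its slope; this is what inverse-probability
#'   of censoring weighting has to correct for.
#' @param censoring_logit_coeffs,death_logit_coeffs named vectors
#'   (`intercept`, `a_prev`, `age`, `chronic_count`, `depressive_sx`,
#'   `log_eq_income`, `frailty`) for the biennial loss-to-follow-up and death
#'   hazards, logistic in prior exposure, prior covariates, age and frailty.
#' @param nonresponse_rate probability an active person skips a post-baseline
#'   interview (remaining under observation).
#' @param item_missing_rate probability any one exposure/covariate item is
#'   missing at a responded post-baseline wave.
#' @param seed master seed; all randomness flows from it via named
#'   substreams.
#' @return an object of class `msmfi_sim_params` (a validated list).
#' @export
msmfi_sim_params <- function(n_subjects = 5000L,
                             n_waves = 10L,
                             baseline_age_mean = 67.7,
                             baseline_age_sd = 10.95,
                             exposure_baseline_logit = -3.33,
                             exposure_persistence = 1.9,
                             confounding_strength = c(
                               married = -0.25, log_eq_income = -0.40,
                               chronic_count = 0.10, depressive_sx = 0.15),
                             feedback_strength = 0.25,
                             v_effect_scale = 1,
                             outcome_intercept_mean = 0.94,
                             outcome_intercept_sd = 0.50,
                             slope_mean = -0.045,
                             slope_effect_psi = -0.003,
                             random_slope_sd = 0.02,
                             residual_sd = 0.35,
                             frailty_sd = 0.5,
                             censoring_logit_coeffs = c(
                               intercept = -3.3, a_prev = 0.3, age = 0.02,
                               chronic_count = 0.10, depressive_sx = 0.08,
                               log_eq_income = -0.15, frailty = 0.25),
                             death_logit_coeffs = c(
                               intercept = -3.4, a_prev = 0.4, age = 0.09,
                               chronic_count = 0.10, depressive_sx = 0.05,
                               log_eq_income = -0.10, frailty = 0),
                             nonresponse_rate = 0.04,
                             item_missing_rate = 0.03,
                             seed = 1L) {
  p <- list(
    n_subjects = .check_count(n_subjects, "n_subjects", 1L),
    n_waves = .check_count(n_waves, "n_waves", 2L),
    baseline_age_mean = baseline_age_mean,
    baseline_age_sd = .check_nonneg(baseline_age_sd, "baseline_age_sd"),
    exposure_baseline_logit = exposure_baseline_logit,
    exposure_persistence = exposure_persistence,
    confounding_strength = confounding_strength,
    feedback_strength = feedback_strength,
    v_effect_scale = v_effect_scale,
    outcome_intercept_mean = outcome_intercept_mean,
    outcome_intercept_sd = .check_nonneg(outcome_intercept_sd,
                                         "outcome_intercept_sd"),
    slope_mean = slope_mean,
    slope_effect_psi = slope_effect_psi,
    random_slope_sd = .check_nonneg(random_slope_sd, "random_slope_sd"),
    residual_sd = .check_nonneg(residual_sd, "residual_sd"),
    frailty_sd = .check_nonneg(frailty_sd, "frailty_sd"),
    censoring_logit_coeffs = censoring_logit_coeffs,
    death_logit_coeffs = death_logit_coeffs,
    nonresponse_rate = .check_prob(nonresponse_rate, "nonresponse_rate"),
    item_missing_rate = .check_prob(item_missing_rate, "item_missing_rate"),
    seed = .check_count(seed, "seed", 0L)
  )
  bad <- setdiff(names(p$confounding_strength), .L_COLS)
  .stop_if(length(bad) > 0,
           "confounding_strength names not time-varying covariates: ",
           paste(bad, collapse = ", "))
  hz <- c("intercept", "a_prev", "age", "chronic_count", "depressive_sx",
          "log_eq_income", "frailty")
  for (nm in c("censoring_logit_coeffs", "death_logit_coeffs")) {
    .stop_if(!all(hz %in% names(p[[nm]])),
             sprintf("'%s' must carry names: %s", nm,
                     paste(hz, collapse = ", ")))
  }
  class(p) <- "msmfi_sim_params"
  p
}

# Fixed structural constants of the generative model (not user knobs; see the
# methods vignette for the rationale behind each magnitude).
.GEN <- list(
  # effect of baseline covariates V on the exposure logit; magnitudes are
  # moderate so that the cumulative stabilized weights stay as tame as the
  # published weight distribution (mean ~0.98, SD ~0.3)
  v_exposure = c(age0 = -0.015, sex = 0.25, education_years = -0.05,
                 race_group = 0.60, parental_edu_gt_hs = -0.20,
                 born_south = 0.30),
  # centring constants for time-varying covariates in logit models
  l_center = c(married = 0.5, log_eq_income = 3.0, log_eq_wealth = 4.4,
               chronic_count = 1.5, depressive_sx = 1.5, bmi = 26.6,
               drinks = 0.45, smokes = 0.17),
  # effect of (centred) time-varying covariates on the outcome level
  # kept deliberately small for the fed-back covariates so the mediated
  # pathway contributes little to the regime slope difference (see vignette)
  gamma_y = c(married = 0.004, log_eq_income = 0.005, log_eq_wealth = 0.002,
              chronic_count = -0.020, depressive_sx = -0.003,
              bmi = -0.002, drinks = 0.000, smokes = -0.005),
  income_rho = 0.8, income_shock_sd = 0.4,
  wealth_rho = 0.8, wealth_shock_sd = 0.5,
  bmi_rho = 0.95, bmi_shock_sd = 1.0,
  # frailty loads heavily on the outcome level and only weakly on its slope:
  # death is truncation (never reweighted), so slope-informative mortality
  # would bias any estimator that conditions on survival (see vignette)
  frailty_intercept = -0.20, frailty_slope = -0.002
)

.rbern <- function(u, p) as.integer(u < p)

# Core latent-process engine. regime = NULL draws exposure from its logistic
# model; regime = 0/1 forces the static never/always-exposed regime.
# attrition = FALSE disables censoring, death and nonresponse (used by the
# counterfactual oracle). Returns per-wave matrices in a list.
.sim_engine <- function(p, regime = NULL, attrition = TRUE,
                        noise_seed = NULL) {
  n <- p$n_subjects
  K <- p$n_waves
  G <- .GEN

  # -- baseline substream: V, frailty, person effects ------------------------
  set.seed(sub_seed(p$seed, "baseline"))
  lo <- stats::pnorm(50, p$baseline_age_mean, p$baseline_age_sd)
  age0 <- stats::qnorm(stats::runif(n, lo, 1),
                       p$baseline_age_mean, p$baseline_age_sd)
  sex <- stats::rbinom(n, 1L, 0.646)            # 1 = female
  educ <- pmin(pmax(round(stats::rnorm(n, 13.0, 2.98)), 0), 17)
  race <- stats::rbinom(n, 1L, 0.185)           # 1 = minoritized group
  parent <- stats::rbinom(n, 1L, 0.113)
  south <- stats::rbinom(n, 1L, 0.375)
  frailty <- stats::rnorm(n, 0, p$frailty_sd)
  childhood_ses <- 0.5 * parent + 0.10 * (educ - 13) - 0.2 * south +
    stats::rnorm(n, 0, 0.7)
  b0 <- stats::rnorm(n, 0, p$outcome_intercept_sd)
  b1 <- stats::rnorm(n, 0, p$random_slope_sd)
  intercept_i <- p$outcome_intercept_mean + b0 + 0.04 * (educ - 13) -
    0.20 * race - 0.022 * (age0 - 68) + G$frailty_intercept * frailty
  # slope heterogeneity is (nearly) exogenous to the attrition process:
  # death is truncation, so strongly slope-informative mortality would make
  # the regime slope difference unrecoverable by design (see vignette)
  slope_i <- p$slope_mean + b1 + G$frailty_slope * frailty

  # -- pre-drawn shocks, one named substream per margin ----------------------
  set.seed(sub_seed(p$seed, "covariates"))
  u_married <- matrix(stats::runif(n * K), n, K)
  e_income <- matrix(stats::rnorm(n * K, 0, G$income_shock_sd), n, K)
  e_wealth <- matrix(stats::rnorm(n * K, 0, G$wealth_shock_sd), n, K)
  u_chronic <- matrix(stats::runif(n * K), n, K)
  u_depr <- matrix(stats::runif(n * K), n, K)
  e_bmi <- matrix(stats::rnorm(n * K, 0, G$bmi_shock_sd), n, K)
  u_drinks <- matrix(stats::runif(n * K), n, K)
  u_smokes <- matrix(stats::runif(n * K), n, K)
  set.seed(sub_seed(p$seed, "exposure"))
  u_expo <- matrix(stats::runif(n * K), n, K)
  set.seed(if (is.null(noise_seed)) sub_seed(p$seed, "noise") else noise_seed)
  eps <- matrix(stats::rnorm(n * K, 0, p$residual_sd), n, K)
  set.seed(sub_seed(p$seed, "censoring"))
  u_cens <- matrix(stats::runif(n * K), n, K)
  set.seed(sub_seed(p$seed, "death"))
  u_death <- matrix(stats::runif(n * K), n, K)
  set.seed(sub_seed(p$seed, "nonresponse"))
  u_nonresp <- matrix(stats::runif(n * K), n, K)

  # frailty loads on the time-varying covariates only through their baseline
  # draws: transitions are frailty-free so that, given last wave's
  # covariates, the exposure carries no residual frailty signal (the lag-1
  # weight models can then block all measured confounding; see vignette)
  income_target <- 3.0 + 0.08 * (educ - 13) - 0.30 * race
  wealth_target <- 4.4 + 1.2 * (income_target - 3.0)

  L <- vector("list", K)
  A <- matrix(NA_integer_, n, K)
  Y <- matrix(NA_real_, n, K)
  status <- matrix("active", n, K)
  responded <- matrix(1L, n, K)

  v_logit <- p$v_effect_scale * as.vector(
    .GEN$v_exposure["age0"] * (age0 - 68) +
      .GEN$v_exposure["sex"] * sex +
      .GEN$v_exposure["education_years"] * (educ - 13) +
      .GEN$v_exposure["race_group"] * race +
      .GEN$v_exposure["parental_edu_gt_hs"] * parent +
      .GEN$v_exposure["born_south"] * south)

  conf_logit <- function(Lw) {
    cs <- p$confounding_strength
    out <- numeric(nrow(Lw))
    for (nm in names(cs)) out <- out + cs[[nm]] * (Lw[, nm] - G$l_center[[nm]])
    out
  }

  hazard_logit <- function(cf, Lprev, Aprev, t) {
    cf[["intercept"]] + cf[["a_prev"]] * Aprev +
      cf[["age"]] * (age0 + 2 * t - 68) +
      cf[["chronic_count"]] * (Lprev[, "chronic_count"] - 1.5) +
      cf[["depressive_sx"]] * (Lprev[, "depressive_sx"] - 1.5) +
      cf[["log_eq_income"]] * (Lprev[, "log_eq_income"] - 3.0) +
      cf[["frailty"]] * frailty
  }

  fb <- p$feedback_strength
  alive <- rep(TRUE, n)      # not dead
  observed <- rep(TRUE, n)   # not lost to follow-up

  for (t in seq_len(K) - 1L) {
    j <- t + 1L
    if (t == 0L) {
      married <- .rbern(u_married[, j], stats::plogis(0.04))
      # baseline levels reuse the shock substreams, rescaled to marginal SDs
      income <- income_target - 0.14 * frailty + e_income[, j] * 1.375
      wealth <- wealth_target - 0.20 * frailty + e_wealth[, j] * 1.6
      chronic <- pmin(stats::qpois(u_chronic[, j],
                                   exp(-0.20 + 0.03 * (age0 - 68) +
                                         0.50 * frailty)), 8)
      depr <- pmin(stats::qpois(u_depr[, j],
                                exp(0.30 + 0.30 * frailty -
                                      0.10 * (income - 3))), 8)
      bmi <- pmin(pmax(26.6 - 0.05 * (age0 - 68) + e_bmi[, j] * 5.2, 15), 60)
      drinks <- .rbern(u_drinks[, j], stats::plogis(-0.15))
      smokes <- .rbern(u_smokes[, j], stats::plogis(-1.60))
      Aprev <- rep(0L, n)
    } else {
      Lp <- L[[j - 1L]]
      Aprev <- A[, j - 1L]
      Aprev[is.na(Aprev)] <- 0L

      if (attrition) {
        # death first (terminal), then loss to follow-up among survivors;
        # both states are absorbing (the lost stay "lost" even if they
        # later die, since their vital status is no longer observed)
        ph_d <- stats::plogis(hazard_logit(p$death_logit_coeffs, Lp, Aprev, t))
        dies <- alive & observed & (u_death[, j] < ph_d)
        alive <- alive & !dies
        ph_c <- stats::plogis(hazard_logit(p$censoring_logit_coeffs, Lp,
                                           Aprev, t))
        lost_now <- alive & observed & (u_cens[, j] < ph_c)
        observed <- observed & !lost_now
      }

      # latent covariate/exposure process continues for everyone alive
      married_prev <- Lp[, "married"]
      pm <- stats::plogis(-2.5 + 5.0 * married_prev - fb * 0.5 * Aprev)
      married <- .rbern(u_married[, j], pm)
      income <- income_target +
        G$income_rho * (Lp[, "log_eq_income"] - income_target) -
        fb * 0.25 * Aprev + e_income[, j]
      wealth <- wealth_target +
        G$wealth_rho * (Lp[, "log_eq_wealth"] - wealth_target) -
        fb * 0.30 * Aprev + e_wealth[, j]
      # chronic burden accumulates at an exogenous rate; its cross-sectional
      # frailty/age loading comes from the baseline draw
      chronic <- pmin(Lp[, "chronic_count"] +
                        .rbern(u_chronic[, j], stats::plogis(-2.2)), 8)
      lam_d <- exp(-0.05 + 0.50 * log1p(Lp[, "depressive_sx"]) +
                     fb * 0.50 * Aprev - 0.10 * (income - 3))
      depr <- pmin(stats::qpois(u_depr[, j], lam_d), 8)
      bmi <- pmin(pmax(26.6 + G$bmi_rho * (Lp[, "bmi"] - 26.6) + e_bmi[, j],
                       15), 60)
      drinks <- .rbern(u_drinks[, j],
                       stats::plogis(-1.8 + 3.4 * Lp[, "drinks"] -
                                       fb * 0.3 * Aprev))
      smokes <- .rbern(u_smokes[, j],
                       stats::plogis(-3.0 + 4.5 * Lp[, "smokes"] +
                                       fb * 0.2 * Aprev))
    }

    Lw <- cbind(married = married, log_eq_income = income,
                log_eq_wealth = wealth, chronic_count = chronic,
                depressive_sx = depr, bmi = bmi, drinks = drinks,
                smokes = smokes)
    L[[j]] <- Lw

    if (is.null(regime)) {
      eta <- p$exposure_baseline_logit + p$exposure_persistence * Aprev +
        conf_logit(Lw) + v_logit
      a <- .rbern(u_expo[, j], stats::plogis(eta))
    } else {
      a <- rep(as.integer(regime), n)
    }
    A[, j] <- a

    gy <- numeric(n)
    for (nm in names(G$gamma_y)) {
      gy <- gy + G$gamma_y[[nm]] * (Lw[, nm] - G$l_center[[nm]])
    }
    Y[, j] <- intercept_i + gy +
      (slope_i + p$slope_effect_psi * a) * (2 * t) + eps[, j]

    if (attrition) {
      status[, j] <- ifelse(!observed, "lost",
                            ifelse(alive, "active", "dead"))
      if (t > 0L) {
        nonresp <- alive & observed & (u_nonresp[, j] < p$nonresponse_rate)
        responded[, j] <- as.integer(alive & observed & !nonresp)
      } else {
        responded[, j] <- as.integer(alive & observed)
      }
    }
  }

  list(age0 = age0, sex = sex, educ = educ, race = race, parent = parent,
       south = south, childhood_ses = childhood_ses, frailty = frailty,
       intercept_i = intercept_i, slope_i = slope_i,
       L = L, A = A, Y = Y, status = status, responded = responded)
}

# Flatten the engine state into the tidy person-wave panel, blanking
# everything that is unobserved (after death, after loss, at nonresponse).
.assemble_panel <- function(st, p) {
  n <- p$n_subjects
  K <- p$n_waves
  waves <- rep(seq_len(K) - 1L, each = n)
  obs_active <- as.vector(st$status == "active")
  obs_resp <- as.vector(st$responded == 1L) & obs_active

  Lmat <- do.call(rbind, st$L)
  panel <- data.frame(
    person_id = rep(seq_len(n), times = K),
    wave = waves,
    time_years = 2 * waves,
    age0 = rep(st$age0, K), sex = rep(st$sex, K),
    education_years = rep(st$educ, K), race_group = rep(st$race, K),
    parental_edu_gt_hs = rep(st$parent, K), born_south = rep(st$south, K),
    childhood_ses = rep(st$childhood_ses, K),
    Lmat,
    exposure = as.vector(st$A),
    outcome = as.vector(st$Y),
    status = as.vector(st$status),
    responded = as.integer(obs_resp)
  )
  blank <- !obs_resp
  panel[blank, c(.L_COLS, "exposure", "outcome")] <- NA
  panel <- panel[order(panel$person_id, panel$wave), ]
  rownames(panel) <- NULL
  panel
}

#' Simulate a longitudinal cohort with known causal truth
#'
#' Generates a biennial person-wave panel in which time-varying covariates
#' both confound the exposure and are affected by prior exposure
#' (exposure-confounder feedback), loss to follow-up and death are
#' informative through a latent frailty, and the exposure's true causal
#' effect enters the outcome slope additively, so the exposure-by-time
#' coefficient of a correctly weighted growth model has a known target.
#'
#' @param params an [msmfi_sim_params()] object.
#' @param truth_n_mc Monte-Carlo size for the counterfactual regime oracle
#'   attached to the result; 0 skips the oracle (`truth` is `NULL`).
#' @return a list of class `msmfi_sim` with elements `panel` (the tidy
#'   person-wave data frame) and `truth` (see
#'   [evaluate_true_regime_difference()]).
#' @export
simulate_cohort <- function(params, truth_n_mc = 2000L) {
  .stop_if(!inherits(params, "msmfi_sim_params"),
           "'params' must come from msmfi_sim_params()")
  st <- .sim_engine(params, regime = NULL, attrition = TRUE)
  panel <- .assemble_panel(st, params)
  if (params$item_missing_rate > 0) {
    panel <- inject_item_missingness(panel, params$item_missing_rate,
                                     sub_seed(params$seed, "missingness"))
  }
  truth <- NULL
  if (truth_n_mc > 0) {
    truth <- evaluate_true_regime_difference(params, n_mc = truth_n_mc)
  }
  structure(list(panel = panel, truth = truth, params = params),
            class = "msmfi_sim")
}

#' Monte-Carlo oracle for the true regime slope difference
#'
#' Simulates counterfactual outcome trajectories under the two static
#' regimes (always exposed, never exposed) with censoring, death and
#' nonresponse switched off. Baseline and covariate-shock draws are shared
#' between the regimes (counterfactual coupling), while occasion-level
#' outcome noise is drawn independently per regime so the Monte-Carlo
#' standard error honestly reflects outcome-level sampling variability. The
#' contrast is the mean difference in per-person least-squares slopes.
#'
#' @param params an [msmfi_sim_params()] object.
#' @param n_mc number of Monte-Carlo persons (>= 1000).
#' @return a list of class `msmfi_truth`: `params`, `true_slope_difference`
#'   (SD units/year), and `mc_se`.
#' @export
evaluate_true_regime_difference <- function(params, n_mc = 10000L) {
  .stop_if(!inherits(params, "msmfi_sim_params"),
           "'params' must come from msmfi_sim_params()")
  n_mc <- .check_count(n_mc, "n_mc", 1000L)
  p <- params
  p$n_subjects <- n_mc
  p$seed <- sub_seed(params$seed, "oracle")

  tt <- 2 * (seq_len(p$n_waves) - 1L)
  tc <- tt - mean(tt)
  slope_of <- function(Y) as.vector(Y %*% tc) / sum(tc^2)

  ns <- sub_seed(p$seed, "noise")
  st1 <- .sim_engine(p, regime = 1L, attrition = FALSE, noise_seed = ns + 1L)
  st0 <- .sim_engine(p, regime = 0L, attrition = FALSE, noise_seed = ns)
  d <- slope_of(st1$Y) - slope_of(st0$Y)

  structure(list(params = params,
                 true_slope_difference = mean(d),
                 mc_se = stats::sd(d) / sqrt(n_mc),
                 n_mc = n_mc),
            class = "msmfi_truth")
}

#' Blank exposure/covariate items at random post-baseline person-waves
#'
#' Emulates item nonresponse among persons who are alive and under
#' observation. Wave-0 exposure is never blanked (baseline exposure
#' completeness is an eligibility criterion), and outcomes are never
#' touched.
#'
#' @param panel a person-wave panel data frame.
#' @param rate per-item missingness probability in `[0, 1]`.
#' @param seed integer seed.
#' @return the panel with injected `NA`s.
#' @export
inject_item_missingness <- function(panel, rate, seed) {
  .check_prob(rate, "rate")
  if (rate == 0) return(panel)
  set.seed(seed)
  items <- c("exposure", .L_COLS)
  idx <- which(panel$status == "active" & panel$responded == 1L &
                 panel$wave > 0L)
  for (it in items) {
    hit <- if (rate >= 1) idx else idx[stats::runif(length(idx)) < rate]
    panel[[it]][hit] <- NA
  }
  panel
}

#' @export
print.msmfi_truth <- function(x, ...) {
  cat(sprintf(
    "True regime slope difference: %.5f SD/year (MC SE %.2g, n_mc %d)\n",
    x$true_slope_difference, x$mc_se, x$n_mc))
  invisible(x)
}

#' @export
print.msmfi_sim <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d persons x %d waves (%d person-wave rows)\n",
              x$params$n_subjects, x$params$n_waves, nrow(x$panel)))
  if (!is.null(x$truth)) print(x$truth)
  invisible(x)
}
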