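#' Growth-model specification
#'
#' Fixed effects are always intercept, exposure, time (years since
#' baseline, linear) and exposure-by-time; the exposure-by-time coefficient
#' is the coefficient of interest (difference in yearly outcome change
#' between exposed and unexposed). `weighted_mixed` adds person random
#' effects and fits by weighted REML; `weighted_gls_independence` is
#' weighted least squares with persons treated as independent clusters —
#' the standard marginal-structural pairing of IPW with an independence
#' working model, whose inference comes from the person-level bootstrap.
#'
#' @param estimator `"weighted_mixed"` (default) or
#'   `"weighted_gls_independence"`.
#' @param random_effects `"intercept_slope"` (default) or `"intercept"`;
#'   ignored by the GLS estimator.
#' @return a list of class `msmfi_growth_spec`.
#' @export
growth_model_spec <- function(estimator = c("weighted_mixed",
                                            "weighted_gls_independence"),
                              random_effects = c("intercept_slope",
                                                 "intercept")) {
  structure(list(estimator = match.arg(estimator),
                 random_effects = match.arg(random_effects)),
            class = "msmfi_growth_spec")
}

# Closed-form weighted least squares on the MSM design; shared by the GLS
# estimator, the mixed-model fallback and the bootstrap hot loop.
.wls_msm <- function(a, t, y, w) {
  X <- cbind(1, a, t, a * t)
  XtW <- t(X * w)
  beta <- solve(XtW %*% X, XtW %*% y)
  stats::setNames(as.vector(beta),
                  c("(Intercept)", "exposure", "time_years",
                    "exposure:time_years"))
}

# Rows of the analysis table that enter the outcome model, with weights.
.outcome_rows <- function(tab, weights) {
  rows <- which(tab$active == 1L & !is.na(tab$outcome) &
                  !is.na(tab$exposure))
  w <- weights$w_final[match(paste(tab$person_id[rows], tab$wave[rows]),
                             paste(weights$person_id, weights$wave))]
  ok <- !is.na(w)
  list(rows = rows[ok], w = w[ok])
}

#' Fit the inverse-probability-weighted growth model
#'
#' Fits `outcome ~ exposure * time + person random effects` with the final
#' person-wave weights as analytic weights. Under correct weighting the
#' exposure-by-time coefficient estimates the difference in yearly outcome
#' change between the always-exposed and never-exposed regimes. If the
#' mixed model fails to converge the fit silently downgrades to the
#' GLS-independence estimator and records the downgrade.
#'
#' @param panel analysis-ready panel (or analysis table).
#' @param weights a `msmfi_final_weights` table.
#' @param spec a [growth_model_spec()].
#' @return object of class `msmfi_result` with elements `beta_exposure`,
#'   `beta_time`, `beta_interaction`, `intercept`,
#'   `excess_years_per_decade`, `estimator`, `estimator_used`, `n_persons`,
#'   `n_obs`, `converged`; confidence intervals are `NA` until
#'   [bootstrap_cis()] fills them.
#' @export
fit_weighted_growth_model <- function(panel, weights,
                                      spec = growth_model_spec()) {
  tab <- if (inherits(panel, "msmfi_analysis_table")) panel else
    structure(.analysis_table(panel),
              class = c("msmfi_analysis_table", "data.frame"))
  sel <- .outcome_rows(tab, weights)
  d <- data.frame(y = tab$outcome[sel$rows],
                  a = tab$exposure[sel$rows],
                  t = tab$time_years[sel$rows],
                  id = tab$person_id[sel$rows],
                  w = sel$w)
  .stop_if(nrow(d) == 0, "no person-waves with outcome, exposure and weight")
  .stop_if(stats::var(d$a) == 0 || stats::var(d$t) == 0,
           "rank-deficient design: exposure or time is constant")

  used <- spec$estimator
  converged <- TRUE
  if (spec$estimator == "weighted_mixed") {
    re <- if (spec$random_effects == "intercept_slope") {
      "(1 + t | id)"
    } else {
      "(1 | id)"
    }
    fml <- stats::as.formula(paste("y ~ a * t +", re))
    fit <- tryCatch(
      suppressMessages(suppressWarnings(
        lme4::lmer(fml, data = d, weights = w, REML = TRUE))),
      error = function(e) NULL)
    if (is.null(fit)) {
      used <- "weighted_gls_independence"
      converged <- FALSE
      beta <- .wls_msm(d$a, d$t, d$y, d$w)
    } else {
      fe <- lme4::fixef(fit)
      beta <- stats::setNames(as.vector(fe[c("(Intercept)", "a", "t",
                                             "a:t")]),
                              c("(Intercept)", "exposure", "time_years",
                                "exposure:time_years"))
    }
  } else {
    beta <- .wls_msm(d$a, d$t, d$y, d$w)
  }

  structure(list(
    intercept = beta[["(Intercept)"]],
    beta_exposure = beta[["exposure"]],
    beta_time = beta[["time_years"]],
    beta_interaction = beta[["exposure:time_years"]],
    excess_years_per_decade = excess_aging_per_decade(
      beta[["exposure:time_years"]], beta[["time_years"]]),
    ci = NULL, n_boot = 0L,
    estimator = spec$estimator, estimator_used = used,
    n_persons = length(unique(d$id)), n_obs = nrow(d),
    converged = converged), class = "msmfi_result")
}

#' Unweighted regression adjusting for the time-varying confounders
#'
#' The conventional comparator the weighting approach is designed to
#' improve on: ordinary least squares of the outcome on exposure, time,
#' their interaction, the baseline covariates and the *current-wave*
#' time-varying covariates. With exposure-confounder feedback this
#' over-adjusts (blocks mediated pathways and conditions on colliders), so
#' its exposure-by-time coefficient is biased for the regime contrast.
#'
#' @param panel analysis-ready panel.
#' @param covariates adjustment covariates (default V and current L).
#' @return list with the four MSM-aligned coefficients.
#' @export
naive_adjusted_fit <- function(panel, covariates = c(.V_COLS, .L_COLS)) {
  tab <- if (inherits(panel, "msmfi_analysis_table")) panel else
    structure(.analysis_table(panel),
              class = c("msmfi_analysis_table", "data.frame"))
  rows <- tab$active == 1L & !is.na(tab$outcome) & !is.na(tab$exposure)
  sub <- tab[rows, , drop = FALSE]
  Z <- as.matrix(sub[, covariates, drop = FALSE])
  ok <- stats::complete.cases(Z)
  sub <- sub[ok, , drop = FALSE]
  Z <- Z[ok, , drop = FALSE]
  X <- cbind(1, sub$exposure, sub$time_years, sub$exposure * sub$time_years,
             Z)
  beta <- solve(crossprod(X), crossprod(X, sub$outcome))
  list(intercept = beta[1], beta_exposure = beta[2], beta_time = beta[3],
       beta_interaction = beta[4], n_obs = nrow(sub))
}

#' Excess years of outcome aging per decade
#'
#' Divides the difference in yearly rates of decline between exposed and
#' unexposed (the exposure-by-time coefficient) by the yearly rate of
#' decline of the unexposed (the time coefficient, taken to represent
#' baseline aging) and multiplies by 10. Positive values mean excess aging
#' for the exposed. Scale-invariant: rescaling both coefficients by the
#' same constant leaves it unchanged.
#'
#' @param beta_interaction exposure-by-time coefficient, SD units/year.
#' @param beta_time time coefficient among the unexposed, SD units/year
#'   (non-zero).
#' @return excess years of aging per 10-year period.
#' @export
excess_aging_per_decade <- function(beta_interaction, beta_time) {
  .stop_if(any(beta_time == 0),
           "excess aging is undefined when the reference slope is 0")
  (beta_interaction / beta_time) * 10
}

#' Predicted mean trajectories under the two static regimes
#'
#' @param result a `msmfi_result`.
#' @param horizon_years prediction horizon (default 18, i.e. ten biennial
#'   waves).
#' @param step_years spacing of prediction points.
#' @return data frame: `time_years`, `never_exposed`, `always_exposed`.
#' @export
predict_regime_trajectories <- function(result, horizon_years = 18,
                                        step_years = 2) {
  t <- seq(0, horizon_years, by = step_years)
  data.frame(
    time_years = t,
    never_exposed = result$intercept + result$beta_time * t,
    always_exposed = result$intercept + result$beta_exposure +
      (result$beta_time + result$beta_interaction) * t)
}

#' @export
print.msmfi_result <- function(x, ...) {
  cat("Inverse-probability-weighted growth model (", x$estimator_used,
      ")\n", sep = "")
  cat(sprintf("  n persons %d, person-waves %d\n", x$n_persons, x$n_obs))
  fmt <- function(nm, b) {
    ci <- if (!is.null(x$ci) && nm %in% rownames(x$ci)) {
      sprintf(" (95%% CI %.4g to %.4g)", x$ci[nm, 1], x$ci[nm, 2])
    } else ""
    cat(sprintf("  %-22s %9.5f%s\n", nm, b, ci))
  }
  fmt("exposure", x$beta_exposure)
  fmt("time_years", x$beta_time)
  fmt("exposure:time_years", x$beta_interaction)
  cat(sprintf("  excess years of aging per decade: %.2f\n",
              x$excess_years_per_decade))
  if (x$n_boot > 0) cat(sprintf("  bootstrap replicates: %d\n", x$n_boot))
  invisible(x)
}
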