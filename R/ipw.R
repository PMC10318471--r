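#' Specification of the per-wave weight models
#'
#' The denominator model for the exposure at wave `t` is logistic in the
#' time-invariant baseline covariates V, the time-varying covariates L
#' measured at `t - 1`, and the exposure at `t - 1`; the stabilizing
#' numerator conditions on prior exposure only. Censoring models reuse the
#' same covariate sets, positing that the major predictors of attrition
#' overlap with the predictors of exposure.
#'
#' @param denominator_covariates covariate names: baseline covariates are
#'   taken at face value, time-varying ones are lagged one wave.
#' @param numerator_covariates covariates of the stabilizing numerator
#'   (default: prior exposure only; must be a subset of the denominator
#'   set plus `exposure_lag`).
#' @param censoring_denominator_covariates covariates of the censoring
#'   denominator models; defaults to the exposure set. (Sensitivity
#'   analyses may freeze health covariates at baseline in the treatment
#'   models while keeping them time-varying here.)
#' @param per_wave fit one model per wave (default); `FALSE` pools waves
#'   with wave indicators, for small samples.
#' @param weight_baseline also stabilize the baseline exposure
#'   (numerator: marginal prevalence; denominator: logistic in V and
#'   baseline L). Without this, the cross-sectional confounding of
#'   baseline exposure survives in the weighted pseudo-population — the
#'   per-wave weights only randomize *transitions* — and, combined with
#'   selective attrition, biases the exposure-by-time coefficient. On by
#'   default.
#' @return a list of class `msmfi_weight_spec`.
#' @export
weight_model_spec <- function(denominator_covariates = c(.V_COLS, .L_COLS),
                              numerator_covariates = character(0),
                              censoring_denominator_covariates =
                                denominator_covariates,
                              per_wave = TRUE, weight_baseline = TRUE) {
  den <- unique(c(denominator_covariates, "exposure_lag"))
  cden <- unique(c(censoring_denominator_covariates, "exposure_lag"))
  num <- unique(c(numerator_covariates, "exposure_lag"))
  .stop_if(!all(num %in% den),
           "numerator covariates must be a subset of denominator covariates")
  structure(list(denominator = den, cens_denominator = cden, numerator = num,
                 per_wave = isTRUE(per_wave),
                 weight_baseline = isTRUE(weight_baseline)),
            class = "msmfi_weight_spec")
}

# One flat person-wave table carrying everything the weight and outcome
# models need: current exposure/outcome/censoring status plus baseline
# covariates and one-wave-lagged time-varying covariates. Built once per
# dataset; the bootstrap resamples its rows by person.
.analysis_table <- function(panel, spec = weight_model_spec()) {
  .stop_if(!"C" %in% names(panel),
           "panel lacks censoring indicators; run build_censoring_indicators()")
  panel <- panel[order(panel$person_id, panel$wave), ]
  key_prev <- match(paste(panel$person_id, panel$wave - 1L),
                    paste(panel$person_id, panel$wave))
  lag_cols <- intersect(.L_COLS, names(panel))
  tab <- data.frame(person_id = panel$person_id,
                    wave = panel$wave,
                    time_years = panel$time_years,
                    outcome = panel$outcome,
                    exposure = panel$exposure,
                    C = panel$C,
                    active = as.integer(panel$status == "active"),
                    active_lag = as.integer(
                      panel$status[key_prev] == "active"),
                    exposure_lag = panel$exposure[key_prev])
  for (v in intersect(c(.V_COLS, "childhood_ses"), names(panel))) {
    tab[[v]] <- panel[[v]]
  }
  for (v in lag_cols) {
    tab[[paste0(v, "_lag")]] <- panel[[v]][key_prev]
    tab[[v]] <- panel[[v]]
  }
  # baseline-frozen health covariates, for the time-invariant-health
  # sensitivity scenario
  key_base <- match(panel$person_id, panel$person_id[panel$wave == 0L])
  for (v in intersect(c("chronic_count", "depressive_sx", "bmi", "drinks",
                        "smokes"), names(panel))) {
    tab[[paste0(v, "_base")]] <- panel[[v]][panel$wave == 0L][key_base]
  }
  tab$active_lag[is.na(tab$active_lag)] <- 0L
  tab
}

# Resolve a spec covariate name to the analysis-table column: time-varying
# covariates are used lagged, baseline covariates as-is.
.den_columns <- function(spec_cov) {
  ifelse(spec_cov %in% .L_COLS, paste0(spec_cov, "_lag"), spec_cov)
}

# Risk-set rows of the analysis table for one wave and target. At wave 0
# (baseline exposure model) there is no lag: time-varying covariates enter
# at their current values and prior exposure drops out.
.risk_set <- function(tab, wave, target, covars) {
  if (wave == 0) {
    rows <- tab$wave == 0L & tab$active == 1L & !is.na(tab$exposure)
    cols <- setdiff(covars, "exposure_lag")
  } else {
    rows <- tab$wave == wave & tab$active_lag == 1L
    if (target == "exposure") {
      rows <- rows & tab$active == 1L & !is.na(tab$exposure)
    } else {
      rows <- rows & !is.na(tab$C)   # dead at t have C = NA: not at risk
    }
    cols <- .den_columns(covars)
  }
  X <- as.matrix(tab[rows, cols, drop = FALSE])
  ok <- stats::complete.cases(X)
  X <- X[ok, , drop = FALSE]
  list(rows = which(rows)[ok],
       X = cbind(`(Intercept)` = rep(1, nrow(X)), X))
}

.logit_fit <- function(X, y, engine) {
  if (engine == "irls") {
    f <- .irls_logit(X, y)
    list(coef = stats::setNames(as.vector(f$coefficients), colnames(X)),
         fitted = as.vector(f$fitted), converged = f$converged)
  } else {
    f <- withCallingHandlers(
      stats::glm.fit(X, y, family = stats::binomial()),
      warning = function(w) invokeRestart("muffleWarning"))
    sep <- any(f$fitted.values > 1 - 1e-8 | f$fitted.values < 1e-8) &&
      max(abs(f$coefficients), na.rm = TRUE) > 15
    list(coef = stats::setNames(f$coefficients, colnames(X)),
         fitted = f$fitted.values,
         converged = isTRUE(f$converged) && !sep)
  }
}

#' Fit a per-wave propensity model for exposure or censoring
#'
#' Maximum-likelihood logistic regression on the wave's at-risk set: persons
#' alive and under observation at `t - 1` with complete model covariates;
#' for the exposure target additionally under observation at `t` with
#' observed exposure, for the censoring target not dead at `t` (death is a
#' competing event, so the dead are removed from censoring risk sets rather
#' than treated as censored).
#'
#' @param panel analysis-ready panel (censoring indicators present).
#' @param spec a [weight_model_spec()].
#' @param wave wave index >= 1.
#' @param target `"exposure"` or `"censoring"`.
#' @param role `"denominator"` (full covariate set) or `"numerator"`
#'   (stabilizing set).
#' @param engine `"glm"` (reference) or `"irls"` (compiled fast path; both
#'   maximize the same Bernoulli likelihood).
#' @return an object of class `msmfi_propensity`: coefficients, fitted
#'   probabilities (named by person id), `n_used`, `converged`, wave,
#'   target, role.
#' @export
fit_propensity <- function(panel, spec = weight_model_spec(), wave,
                           target = c("exposure", "censoring"),
                           role = c("denominator", "numerator"),
                           engine = c("glm", "irls")) {
  target <- match.arg(target)
  role <- match.arg(role)
  engine <- match.arg(engine)
  .stop_if(wave < 0, "wave must be >= 0")
  .stop_if(wave == 0 && target == "censoring",
           "there is no censoring transition into baseline")
  tab <- if (inherits(panel, "msmfi_analysis_table")) panel else
    structure(.analysis_table(panel, spec), class = c("msmfi_analysis_table",
                                                      "data.frame"))
  covars <- if (role == "numerator") spec$numerator
    else if (target == "censoring") spec$cens_denominator
    else spec$denominator
  rs <- .risk_set(tab, wave, target, covars)
  .stop_if(nrow(rs$X) == 0, sprintf("empty %s risk set at wave %d", target,
                                    wave))
  y <- if (target == "exposure") tab$exposure[rs$rows] else tab$C[rs$rows]
  f <- .logit_fit(rs$X, y, engine)
  structure(list(wave = wave, target = target, role = role,
                 coefficients = f$coef,
                 fitted_probabilities = stats::setNames(
                   pmin(pmax(f$fitted, 1e-12), 1 - 1e-12),
                   tab$person_id[rs$rows]),
                 person_id = tab$person_id[rs$rows],
                 n_used = length(y), converged = f$converged),
            class = "msmfi_propensity")
}

#' Stabilized inverse-probability weights for one wave
#'
#' For the exposure target, exposed person-waves get
#' `p_num / p_den` and unexposed ones `(1 - p_num) / (1 - p_den)`. For the
#' censoring target both numerator and denominator use the probability of
#' remaining uncensored, and only uncensored person-waves receive a weight.
#'
#' @param panel analysis-ready panel (or prebuilt analysis table).
#' @param num_fit,den_fit [fit_propensity()] results for the same wave and
#'   target, roles numerator and denominator.
#' @return data frame: `person_id`, `wave`, `sw` (> 0, finite).
#' @export
stabilized_weights <- function(panel, num_fit, den_fit) {
  .stop_if(num_fit$wave != den_fit$wave || num_fit$target != den_fit$target,
           "numerator and denominator fits must share wave and target")
  tab <- if (inherits(panel, "msmfi_analysis_table")) panel else
    .analysis_table(panel)
  ids <- intersect(den_fit$person_id, num_fit$person_id)
  pd <- den_fit$fitted_probabilities[match(ids, den_fit$person_id)]
  pn <- num_fit$fitted_probabilities[match(ids, num_fit$person_id)]
  .stop_if(any(pd <= 0 | pd >= 1),
           sprintf("positivity violation in %s model at wave %d",
                   den_fit$target, den_fit$wave))
  rows <- match(paste(ids, den_fit$wave),
                paste(tab$person_id, tab$wave))
  if (den_fit$target == "exposure") {
    a <- tab$exposure[rows]
    sw <- ifelse(a == 1L, pn / pd, (1 - pn) / (1 - pd))
  } else {
    c_t <- tab$C[rows]
    keep <- !is.na(c_t) & c_t == 0L
    ids <- ids[keep]
    sw <- (1 - pn[keep]) / (1 - pd[keep])
  }
  data.frame(person_id = ids, wave = den_fit$wave, sw = as.vector(sw))
}

# Fit all four models at one wave and return merged stabilized weights for
# person-waves observed at that wave (active, uncensored).
.wave_weights <- function(tab, spec, wave, engine) {
  den_a <- fit_propensity(tab, spec, wave, "exposure", "denominator", engine)
  num_a <- fit_propensity(tab, spec, wave, "exposure", "numerator", engine)
  den_c <- fit_propensity(tab, spec, wave, "censoring", "denominator", engine)
  num_c <- fit_propensity(tab, spec, wave, "censoring", "numerator", engine)
  swt <- stabilized_weights(tab, num_a, den_a)
  swc <- stabilized_weights(tab, num_c, den_c)
  m <- merge(stats::setNames(swt, c("person_id", "wave", "sw_treat")),
             stats::setNames(swc, c("person_id", "wave", "sw_cens")),
             by = c("person_id", "wave"))
  attr(m, "fits") <- list(exposure_den = den_a, exposure_num = num_a,
                          censoring_den = den_c, censoring_num = num_c)
  m
}

#' Compute stabilized treatment and censoring weights at every wave
#'
#' Runs the four per-wave logistic fits (exposure and censoring, numerator
#' and denominator) for each wave `t >= 1` and returns the long table of
#' per-person-wave stabilized weights. Wave 0 carries weight 1 by
#' convention.
#'
#' @inheritParams fit_propensity
#' @param keep_fits retain the underlying `msmfi_propensity` objects (for
#'   diagnostics; off in the bootstrap).
#' @return object of class `msmfi_wave_weights`: data frame `person_id`,
#'   `wave`, `sw_treat`, `sw_cens`, with the fits in `attr(, "fits")`.
#' @export
compute_weights <- function(panel, spec = weight_model_spec(),
                            engine = c("glm", "irls"), keep_fits = TRUE) {
  engine <- match.arg(engine)
  tab <- if (inherits(panel, "msmfi_analysis_table")) panel else
    structure(.analysis_table(panel, spec),
              class = c("msmfi_analysis_table", "data.frame"))
  waves <- sort(unique(tab$wave))
  waves <- waves[waves >= 1]
  fits <- list()
  if (spec$weight_baseline) {
    den0 <- fit_propensity(tab, spec, 0L, "exposure", "denominator", engine)
    num0 <- fit_propensity(tab, spec, 0L, "exposure", "numerator", engine)
    sw0 <- stabilized_weights(tab, num0, den0)
    if (keep_fits) fits[["0"]] <- list(exposure_den = den0,
                                       exposure_num = num0)
    base <- data.frame(person_id = sw0$person_id, wave = 0L,
                       sw_treat = sw0$sw, sw_cens = 1)
  } else {
    base_ids <- unique(tab$person_id[tab$wave == 0 & tab$active == 1L])
    base <- data.frame(person_id = base_ids, wave = 0L,
                       sw_treat = 1, sw_cens = 1)
  }
  out <- list(base)
  for (w in waves) {
    ww <- .wave_weights(tab, spec, w, engine)
    if (keep_fits) fits[[as.character(w)]] <- attr(ww, "fits")
    attr(ww, "fits") <- NULL
    out[[length(out) + 1L]] <- ww
  }
  res <- do.call(rbind, out)
  res <- res[order(res$person_id, res$wave), ]
  rownames(res) <- NULL
  structure(res, fits = if (keep_fits) fits,
            class = c("msmfi_wave_weights", "data.frame"))
}

#' Cumulate per-wave weights and truncate the pooled distribution
#'
#' The final weight at wave `t` is the running product over waves `s <= t`
#' of the stabilized treatment and censoring weights. Truncation bounds are
#' the chosen percentiles (default 1st and 99th) of the pooled person-wave
#' cumulative weight distribution, computed once with linear interpolation
#' between order statistics (`stats::quantile` type 7). `"cap"` clamps
#' weights to the bounds; `"exclude"` drops person-waves outside them.
#'
#' @param wave_weights a `msmfi_wave_weights` table (or any data frame with
#'   `person_id`, `wave`, `sw_treat`, `sw_cens`).
#' @param percentiles lower/upper truncation probabilities.
#' @param mode `"cap"` (default) or `"exclude"`.
#' @return object of class `msmfi_final_weights`: data frame `person_id`,
#'   `wave`, `w_cum`, `w_final`, with attributes `bounds`, `mode`,
#'   `n_person_waves`, `n_persons`.
#' @export
cumulate_and_truncate <- function(wave_weights,
                                  percentiles = c(0.01, 0.99),
                                  mode = c("cap", "exclude")) {
  mode <- match.arg(mode)
  ww <- wave_weights[order(wave_weights$person_id, wave_weights$wave), ]
  sw <- ww$sw_treat * ww$sw_cens
  # per-person running product (waves are contiguous per person)
  pid <- ww$person_id
  new_person <- c(TRUE, pid[-1] != pid[-length(pid)])
  lw <- cumsum(log(sw))
  base <- cumsum(ifelse(new_person, 1, 0))
  offset <- lw[new_person][base] - log(sw[new_person])[base]
  w_cum <- exp(lw - offset)
  if (length(w_cum) < 100) {
    warning("fewer than 100 person-waves: percentile bounds are unreliable")
  }
  bounds <- stats::quantile(w_cum, percentiles, type = 7, names = FALSE)
  if (mode == "cap") {
    w_final <- pmin(pmax(w_cum, bounds[1]), bounds[2])
    keep <- rep(TRUE, length(w_cum))
  } else {
    keep <- w_cum >= bounds[1] & w_cum <= bounds[2]
    w_final <- w_cum
  }
  out <- data.frame(person_id = pid[keep], wave = ww$wave[keep],
                    w_cum = w_cum[keep], w_final = w_final[keep])
  structure(out, bounds = bounds, mode = mode,
            n_person_waves = nrow(out),
            n_persons = length(unique(out$person_id)),
            class = c("msmfi_final_weights", "data.frame"))
}

#' Covariate balance and positivity diagnostics at one wave
#'
#' Standardized mean differences between current-exposure groups for each
#' weight-model confounder (lagged time-varying covariates and baseline
#' covariates), before weighting and with the final weights as analytic
#' weights. Following common balance-diagnostic practice the denominator is
#' the unweighted pooled standard deviation in both cases (for binary
#' covariates the pooled binomial SD), so weighting moves only the means.
#' Also returns quartile summaries of the fitted exposure propensity by
#' group as a positivity check.
#'
#' @param panel analysis-ready panel.
#' @param weights a `msmfi_final_weights` table.
#' @param spec a [weight_model_spec()].
#' @param wave wave index >= 1.
#' @param engine logistic engine for the positivity densities.
#' @return object of class `msmfi_balance`: data frame with columns
#'   `covariate`, `smd_unweighted`, `smd_weighted`, plus attribute
#'   `propensity_summary`.
#' @export
balance_report <- function(panel, weights, spec = weight_model_spec(), wave,
                           engine = c("glm", "irls")) {
  engine <- match.arg(engine)
  tab <- if (inherits(panel, "msmfi_analysis_table")) panel else
    structure(.analysis_table(panel, spec),
              class = c("msmfi_analysis_table", "data.frame"))
  covars <- setdiff(spec$denominator, "exposure_lag")
  cols <- .den_columns(covars)
  rows <- tab$wave == wave & tab$active == 1L & !is.na(tab$exposure)
  sub <- tab[rows, , drop = FALSE]
  w <- weights$w_final[match(paste(sub$person_id, wave),
                             paste(weights$person_id, weights$wave))]
  ok <- !is.na(w) & stats::complete.cases(sub[, cols, drop = FALSE])
  sub <- sub[ok, , drop = FALSE]
  w <- w[ok]
  a <- sub$exposure
  .stop_if(length(unique(a)) < 2,
           sprintf("only one exposure group at wave %d: SMD undefined", wave))

  smd_one <- function(x, wts) {
    m1 <- .wmean(x[a == 1], wts[a == 1])
    m0 <- .wmean(x[a == 0], wts[a == 0])
    binary <- all(x %in% c(0, 1))
    if (binary) {
      p1 <- mean(x[a == 1]); p0 <- mean(x[a == 0])
      s <- sqrt((p1 * (1 - p1) + p0 * (1 - p0)) / 2)
    } else {
      s <- sqrt((stats::var(x[a == 1]) + stats::var(x[a == 0])) / 2)
    }
    if (s == 0) return(0)
    (m1 - m0) / s
  }
  unw <- rep(1, nrow(sub))
  res <- data.frame(
    covariate = covars,
    smd_unweighted = vapply(cols, function(cl) smd_one(sub[[cl]], unw), 0),
    smd_weighted = vapply(cols, function(cl) smd_one(sub[[cl]], w), 0),
    row.names = NULL)

  den_fit <- fit_propensity(tab, spec, wave, "exposure", "denominator",
                            engine)
  ps <- den_fit$fitted_probabilities
  pa <- tab$exposure[match(paste(den_fit$person_id, wave),
                           paste(tab$person_id, tab$wave))]
  qs <- function(v) stats::quantile(v, c(0.05, 0.25, 0.5, 0.75, 0.95),
                                    names = FALSE)
  psum <- rbind(exposed = qs(ps[pa == 1]), unexposed = qs(ps[pa == 0]))
  colnames(psum) <- c("q05", "q25", "q50", "q75", "q95")
  structure(res, wave = wave, propensity_summary = psum,
            class = c("msmfi_balance", "data.frame"))
}
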