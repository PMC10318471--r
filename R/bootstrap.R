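# Fast pipeline internals: everything the bootstrap must redo per replicate
# (per-wave propensity fits -> stabilized weights -> cumulation ->
# truncation -> weighted growth model) operating on plain numeric vectors
# and a prebuilt design matrix, so one replicate costs milliseconds.

.pipeline_context <- function(panel, spec = weight_model_spec()) {
  tab <- if (inherits(panel, "msmfi_analysis_table")) panel else
    .analysis_table(panel, spec)
  Xden <- cbind(`(Intercept)` = 1,
                as.matrix(tab[, .den_columns(spec$denominator),
                              drop = FALSE]))
  Xcen <- cbind(`(Intercept)` = 1,
                as.matrix(tab[, .den_columns(spec$cens_denominator),
                              drop = FALSE]))
  Xbase <- cbind(`(Intercept)` = 1,
                 as.matrix(tab[, setdiff(spec$denominator, "exposure_lag"),
                               drop = FALSE]))
  list(person_id = tab$person_id, wave = tab$wave,
       weight_baseline = spec$weight_baseline,
       Xbase = Xbase,
       cc_base = stats::complete.cases(Xbase),
       time_years = tab$time_years, outcome = tab$outcome,
       exposure = tab$exposure, exposure_lag = tab$exposure_lag,
       C = tab$C, active = tab$active, active_lag = tab$active_lag,
       Xden = Xden, Xcen = Xcen,
       cc_den = stats::complete.cases(Xden) & stats::complete.cases(Xcen),
       waves = sort(unique(tab$wave[tab$wave >= 1])),
       person_rows = split(seq_len(nrow(tab)), tab$person_id))
}

# Saturated logistic MLE for a binary covariate: fitted probabilities are
# the group proportions (identical to the numerator glm, in closed form).
.binary_numerator <- function(x, y) {
  n1 <- sum(x)
  p1 <- if (n1 > 0) sum(y[x == 1]) / n1 else sum(y) / length(y)
  n0 <- length(x) - n1
  p0 <- if (n0 > 0) sum(y[x == 0]) / n0 else sum(y) / length(y)
  pmin(pmax(p1 * x + p0 * (1 - x), 1e-12), 1 - 1e-12)
}

# rows: index vector into the context (persons contiguous);
# new_person: logical marking each person's first row;
# warm: optional per-wave starting coefficients (from the original-data
# fits) to cut IRLS iterations inside bootstrap replicates.
.fast_pipeline <- function(ctx, rows, new_person,
                           percentiles = c(0.01, 0.99),
                           mode = "cap", estimator = "gls",
                           frozen_w = NULL, warm = NULL) {
  wv <- ctx$wave[rows]
  act <- ctx$active[rows]
  act_lag <- ctx$active_lag[rows]
  expo <- ctx$exposure[rows]
  expo_lag <- ctx$exposure_lag[rows]
  C <- ctx$C[rows]
  cc <- ctx$cc_den[rows]
  n <- length(rows)
  if (!is.null(frozen_w)) {
    w_final <- frozen_w[rows]
    bounds <- c(NA_real_, NA_real_)
    grp <- cumsum(new_person)
  } else {
  sw <- rep(NA_real_, n)            # combined treat x cens weight per row
  if (ctx$weight_baseline) {
    b0 <- which(wv == 0 & act == 1L & !is.na(expo) & ctx$cc_base[rows])
    y0 <- expo[b0]
    f0 <- .irls_logit(ctx$Xbase[rows[b0], , drop = FALSE], y0,
                      start = warm$base)
    pn0 <- min(max(mean(y0), 1e-12), 1 - 1e-12)
    sw[b0] <- (pn0 / f0$fitted) * y0 +
      ((1 - pn0) / (1 - f0$fitted)) * (1 - y0)
    warm_base <- as.vector(f0$coefficients)
  } else {
    sw[wv == 0 & act == 1L] <- 1
    warm_base <- NULL
  }

  warm_out <- vector("list", length(ctx$waves))
  names(warm_out) <- as.character(ctx$waves)
  at_risk <- act_lag == 1L & cc
  widx <- split(seq_len(n), wv)
  for (t in ctx$waves) {
    key <- as.character(t)
    iw <- widx[[key]]
    iw <- iw[at_risk[iw]]
    er <- iw[act[iw] == 1L & !is.na(expo[iw])]
    cr <- iw[!is.na(C[iw])]
    if (length(er) == 0 || length(cr) == 0) next
    ye <- expo[er]
    fd <- .irls_logit(ctx$Xden[rows[er], , drop = FALSE], ye,
                      start = warm$expo[[key]])
    pd <- fd$fitted
    pn <- .binary_numerator(expo_lag[er], ye)
    swt <- (pn / pd) * ye + ((1 - pn) / (1 - pd)) * (1 - ye)

    yc <- C[cr]
    gd <- .irls_logit(ctx$Xcen[rows[cr], , drop = FALSE], yc,
                      start = warm$cens[[key]])
    qd <- 1 - gd$fitted
    qn <- 1 - .binary_numerator(expo_lag[cr], yc)
    swc_all <- rep(NA_real_, n)
    swc_all[cr] <- qn / qd
    sw[er] <- swt * swc_all[er]
    warm_out[[key]] <- list(e = as.vector(fd$coefficients),
                            c = as.vector(gd$coefficients))
  }

  # per-person cumulative product (rows are person-contiguous, wave-ordered)
  lw <- log(sw)
  cs <- cumsum(ifelse(is.na(lw), 0, lw))
  na_cs <- cumsum(is.na(lw))
  start <- which(new_person)
  grp <- cumsum(new_person)
  base_cs <- (c(0, cs)[start])[grp]
  base_na <- (c(0, na_cs)[start])[grp]
  w_cum <- exp(cs - base_cs)
  w_cum[(na_cs - base_na) > 0] <- NA   # NA weight poisons later waves
  w_cum[is.na(sw) & (na_cs - base_na) == 0] <- NA

  pool <- w_cum[!is.na(w_cum)]
  bounds <- stats::quantile(pool, percentiles, type = 7, names = FALSE)
  if (mode == "cap") {
    w_final <- pmin(pmax(w_cum, bounds[1]), bounds[2])
  } else {
    w_final <- ifelse(w_cum >= bounds[1] & w_cum <= bounds[2], w_cum, NA)
  }
  }

  keep <- act == 1L & !is.na(ctx$outcome[rows]) & !is.na(expo) &
    !is.na(w_final)
  y <- ctx$outcome[rows][keep]
  a <- expo[keep]
  tt <- ctx$time_years[rows][keep]
  w <- w_final[keep]
  beta <- if (estimator == "mixed") {
    d <- data.frame(y = y, a = a, t = tt, w = w,
                    id = cumsum(new_person)[keep])
    fit <- suppressMessages(suppressWarnings(
      lme4::lmer(y ~ a * t + (1 + t | id), data = d, weights = w,
                 REML = TRUE)))
    fe <- lme4::fixef(fit)
    stats::setNames(as.vector(fe[c("(Intercept)", "a", "t", "a:t")]),
                    c("(Intercept)", "exposure", "time_years",
                      "exposure:time_years"))
  } else {
    .wls_msm(a, tt, y, w)
  }
  list(beta = beta,
       warm = if (is.null(frozen_w)) {
         list(expo = lapply(warm_out, `[[`, "e"),
              cens = lapply(warm_out, `[[`, "c"),
              base = warm_base)
       },
       w_final = w_final,
       w_mean = mean(w_final, na.rm = TRUE),
       w_sd = stats::sd(w_final, na.rm = TRUE),
       bounds = bounds,
       n_obs = sum(keep),
       n_persons = length(unique(grp[keep])))
}

#' Person-level bootstrap confidence intervals for the weighted growth model
#'
#' Resamples persons (whole trajectories) with replacement and, inside each
#' replicate, re-runs the full estimation pipeline: per-wave propensity and
#' censoring fits, stabilized weights, cumulation, truncation and the
#' weighted growth model — so the intervals reflect weight-estimation
#' uncertainty. Percentile intervals; deterministic given `seed`.
#'
#' @param panel analysis-ready panel (censoring indicators present, LOCF
#'   applied as configured).
#' @param weight_spec a [weight_model_spec()].
#' @param growth_spec a [growth_model_spec()]; the same estimator is used
#'   for the point fit and inside every replicate (the GLS-independence
#'   estimator is strongly recommended here for speed).
#' @param n_boot number of bootstrap replicates (>= 2; 1000 in a
#'   full-scale analysis).
#' @param seed integer seed.
#' @param percentiles,mode weight-truncation settings, as in
#'   [cumulate_and_truncate()].
#' @param reestimate_weights re-fit the weight models inside each replicate
#'   (default) or reuse the original person-wave weights.
#' @param level confidence level for the percentile intervals.
#' @param use_compiled use the compiled replicate loop for the
#'   GLS-independence estimator (default; the interpreted path is retained
#'   as a reference implementation and for the mixed estimator).
#' @return a `msmfi_result` whose `ci` element is a matrix with rows
#'   `exposure`, `time_years`, `exposure:time_years`,
#'   `excess_years_per_decade`.
#' @export
bootstrap_cis <- function(panel, weight_spec = weight_model_spec(),
                          growth_spec = growth_model_spec(
                            "weighted_gls_independence"),
                          n_boot = 1000L, seed = 1L,
                          percentiles = c(0.01, 0.99), mode = "cap",
                          reestimate_weights = TRUE, level = 0.95,
                          use_compiled = TRUE) {
  n_boot <- .check_count(n_boot, "n_boot", 2L)
  ctx <- .pipeline_context(panel, weight_spec)
  persons <- names(ctx$person_rows)
  .stop_if(length(persons) < 2,
           "bootstrap requires at least two persons to resample")
  est <- if (growth_spec$estimator == "weighted_mixed") "mixed" else "gls"

  all_rows <- unlist(ctx$person_rows, use.names = FALSE)
  np_all <- rep(FALSE, length(all_rows))
  np_all[cumsum(c(1, lengths(ctx$person_rows)))[seq_along(persons)]] <- TRUE
  point <- .fast_pipeline(ctx, all_rows, np_all, percentiles, mode, est)

  frozen <- NULL
  if (!reestimate_weights) {
    # freeze the original final weights; replicates refit the outcome only
    frozen <- rep(NA_real_, length(ctx$wave))
    frozen[all_rows] <- point$w_final
  }

  set.seed(sub_seed(seed, "bootstrap"))
  lens <- lengths(ctx$person_rows)
  draws <- matrix(sample.int(length(persons), length(persons) * n_boot,
                             replace = TRUE), ncol = n_boot)
  res <- matrix(NA_real_, n_boot, 4,
                dimnames = list(NULL, c("exposure", "time_years",
                                        "exposure:time_years",
                                        "excess_years_per_decade")))
  if (use_compiled && est == "gls" && reestimate_weights) {
    er_ok <- as.integer(ctx$active == 1L & ctx$active_lag == 1L &
                          !is.na(ctx$exposure) & ctx$cc_den)
    cr_ok <- as.integer(ctx$active_lag == 1L & !is.na(ctx$C) & ctx$cc_den)
    b_ok <- as.integer(ctx$active == 1L & !is.na(ctx$exposure) &
                         ctx$cc_base)
    Xd <- ctx$Xden; Xd[is.na(Xd)] <- 0  # rows with NAs are masked by *_ok
    Xc <- ctx$Xcen; Xc[is.na(Xc)] <- 0
    Xb <- ctx$Xbase; Xb[is.na(Xb)] <- 0
    pstart <- cumsum(c(0L, lens))[seq_along(lens)]
    bb <- .boot_pipeline_cpp(
      Xd, Xc, Xb, as.integer(ctx$wave),
      ifelse(is.na(ctx$exposure), -1, ctx$exposure),
      ifelse(is.na(ctx$exposure_lag), -1, ctx$exposure_lag),
      ifelse(is.na(ctx$C), -1, ctx$C),
      ctx$outcome, ctx$time_years, er_ok, cr_ok, b_ok,
      as.integer(pstart), as.integer(lens), draws - 1L,
      max(ctx$waves), percentiles[1], percentiles[2], mode == "cap",
      ctx$weight_baseline)
    res[, 1:3] <- bb
    ok_t <- !is.na(bb[, 2]) & bb[, 2] != 0
    res[ok_t, 4] <- 10 * bb[ok_t, 3] / bb[ok_t, 2]
  } else {
    for (b in seq_len(n_boot)) {
      ids <- draws[, b]
      rows <- unlist(ctx$person_rows[ids], use.names = FALSE)
      nl <- lens[ids]
      np <- rep(FALSE, length(rows))
      np[cumsum(c(1, nl))[seq_along(ids)]] <- TRUE
      r <- tryCatch(
        .fast_pipeline(ctx, rows, np, percentiles, mode, est, frozen,
                       warm = point$warm),
        error = function(e) NULL)
      if (!is.null(r)) {
        res[b, 1:3] <- r$beta[c("exposure", "time_years",
                                "exposure:time_years")]
        if (r$beta[["time_years"]] != 0) {
          res[b, 4] <- 10 * r$beta[["exposure:time_years"]] /
            r$beta[["time_years"]]
        }
      }
    }
  }
  fail <- sum(is.na(res[, 1]))
  .stop_if(fail > 0.10 * n_boot,
           sprintf("%d of %d bootstrap replicates failed", fail, n_boot))

  alpha <- (1 - level) / 2
  ci <- t(apply(res, 2, stats::quantile, probs = c(alpha, 1 - alpha),
                na.rm = TRUE, type = 7, names = FALSE))
  colnames(ci) <- c("lower", "upper")

  structure(list(
    intercept = point$beta[["(Intercept)"]],
    beta_exposure = point$beta[["exposure"]],
    beta_time = point$beta[["time_years"]],
    beta_interaction = point$beta[["exposure:time_years"]],
    excess_years_per_decade = excess_aging_per_decade(
      point$beta[["exposure:time_years"]], point$beta[["time_years"]]),
    ci = ci, n_boot = n_boot, n_failed = fail,
    estimator = growth_spec$estimator, estimator_used = growth_spec$estimator,
    n_persons = point$n_persons, n_obs = point$n_obs,
    weight_mean = point$w_mean, weight_sd = point$w_sd,
    converged = TRUE), class = "msmfi_result")
}
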