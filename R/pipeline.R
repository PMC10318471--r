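#' Full pipeline configuration
#'
#' Bundles the per-stage settings of one reproducible run: preparation,
#' weight models, truncation, growth model, bootstrap, and the policy for
#' missing exposure data.
#'
#' @param prep a [prep_config()].
#' @param weight_spec a [weight_model_spec()].
#' @param growth_spec a [growth_model_spec()].
#' @param truncation_percentiles,truncation_mode see
#'   [cumulate_and_truncate()].
#' @param exposure_missing how missing exposure at observed waves is
#'   handled: carried forward (`"locf"`, default), recoded to secure
#'   (`"recode_secure"`) or to insecure (`"recode_insecure"`); under
#'   `prep$complete_case` nothing is imputed.
#' @param n_boot bootstrap replicates (0 disables bootstrap CIs).
#' @param seed integer seed for the bootstrap.
#' @param engine logistic engine for the weight models: `"glm"`
#'   (reference) or `"irls"` (compiled; equal to glm within solver
#'   tolerance, used by large simulation studies).
#' @return a list of class `msmfi_config`.
#' @export
pipeline_config <- function(prep = prep_config(),
                            weight_spec = weight_model_spec(),
                            growth_spec = growth_model_spec(),
                            truncation_percentiles = c(0.01, 0.99),
                            truncation_mode = c("cap", "exclude"),
                            exposure_missing = c("locf", "recode_secure",
                                                 "recode_insecure"),
                            n_boot = 0L, seed = 1L,
                            engine = c("glm", "irls")) {
  structure(list(prep = prep, weight_spec = weight_spec,
                 growth_spec = growth_spec,
                 truncation_percentiles = truncation_percentiles,
                 truncation_mode = match.arg(truncation_mode),
                 exposure_missing = match.arg(exposure_missing),
                 n_boot = as.integer(n_boot), seed = as.integer(seed),
                 engine = match.arg(engine)),
            class = "msmfi_config")
}

# Preparation honoring the missing-exposure policy of the config.
.prepare_with_policy <- function(panel, config) {
  el <- apply_eligibility(panel, config$prep)
  out <- build_censoring_indicators(el$panel)
  if (config$exposure_missing != "locf" && !config$prep$complete_case) {
    fillval <- if (config$exposure_missing == "recode_secure") 0L else 1L
    sel <- out$status == "active" & is.na(out$exposure) & out$wave > 0L
    out$exposure[sel] <- fillval
    if (config$prep$locf_enabled) out <- locf_impute(out, columns = .L_COLS)
  } else if (config$prep$locf_enabled && !config$prep$complete_case) {
    out <- locf_impute(out)
  }
  list(panel = out, exclusion_log = el$exclusion_log)
}

#' Run the estimation pipeline on a raw panel
#'
#' Eligibility and preparation, per-wave stabilized treatment and censoring
#' weights, cumulation and truncation, the weighted growth model, and
#' (optionally) person-level bootstrap confidence intervals.
#'
#' @param panel raw person-wave panel (e.g. from [simulate_cohort()] or
#'   [read_panel()]).
#' @param config a [pipeline_config()].
#' @return list of class `msmfi_run`: `result` (a `msmfi_result`),
#'   `weights` (`msmfi_final_weights`), `exclusion_log`, `panel`
#'   (analysis-ready), `config`.
#' @export
run_msm <- function(panel, config = pipeline_config()) {
  pr <- .prepare_with_policy(panel, config)
  tab <- structure(.analysis_table(pr$panel, config$weight_spec),
                   class = c("msmfi_analysis_table", "data.frame"))
  ww <- compute_weights(tab, config$weight_spec, engine = config$engine,
                        keep_fits = FALSE)
  fw <- cumulate_and_truncate(ww, config$truncation_percentiles,
                              config$truncation_mode)
  if (config$n_boot > 0) {
    res <- bootstrap_cis(tab, config$weight_spec, config$growth_spec,
                         n_boot = config$n_boot, seed = config$seed,
                         percentiles = config$truncation_percentiles,
                         mode = config$truncation_mode)
    if (config$growth_spec$estimator == "weighted_mixed") {
      # point estimates from the mixed fit, intervals from the bootstrap
      pt <- fit_weighted_growth_model(tab, fw, config$growth_spec)
      for (f in c("intercept", "beta_exposure", "beta_time",
                  "beta_interaction", "excess_years_per_decade",
                  "estimator_used", "converged")) res[[f]] <- pt[[f]]
    }
  } else {
    res <- fit_weighted_growth_model(tab, fw, config$growth_spec)
  }
  res$weight_mean <- mean(fw$w_final)
  res$weight_sd <- stats::sd(fw$w_final)
  structure(list(result = res, weights = fw, exclusion_log = pr$exclusion_log,
                 panel = pr$panel, config = config),
            class = "msmfi_run")
}
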