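#' Sensitivity-analysis scenarios
#'
#' Each scenario changes exactly one behaviour of the base pipeline:
#' \describe{
#'   \item{recode_missing_secure}{missing exposure at observed waves is
#'     recoded to food secure instead of carried forward.}
#'   \item{recode_missing_insecure}{missing exposure recoded to food
#'     insecure.}
#'   \item{complete_case}{no imputation; person-waves with missing exposure
#'     or covariates drop out of risk sets and the outcome model.}
#'   \item{health_time_invariant}{health covariates (chronic conditions,
#'     depressive symptoms, BMI, drinking, smoking) enter the treatment
#'     weight models at their baseline values, remaining time-varying in
#'     the censoring models.}
#'   \item{alt_childhood_ses}{parental education is replaced by a
#'     continuous childhood socioeconomic-circumstances proxy
#'     (`childhood_ses`) in all weight models.}
#' }
#'
#' @param name one of the five scenario names.
#' @return a list of class `msmfi_scenario`.
#' @export
scenario <- function(name = c("recode_missing_secure",
                              "recode_missing_insecure", "complete_case",
                              "health_time_invariant",
                              "alt_childhood_ses")) {
  structure(list(name = match.arg(name)), class = "msmfi_scenario")
}

#' Patch a base configuration for a scenario
#'
#' @param scn a [scenario()].
#' @param base_config the base [pipeline_config()].
#' @return the patched `msmfi_config`.
#' @export
scenario_config <- function(scn, base_config = pipeline_config()) {
  .stop_if(!inherits(scn, "msmfi_scenario"), "'scn' must come from scenario()")
  cfg <- base_config
  health <- c("chronic_count", "depressive_sx", "bmi", "drinks", "smokes")
  switch(scn$name,
    recode_missing_secure = {
      .stop_if(cfg$prep$complete_case,
               "exposure recoding conflicts with complete-case preparation")
      cfg$exposure_missing <- "recode_secure"
    },
    recode_missing_insecure = {
      .stop_if(cfg$prep$complete_case,
               "exposure recoding conflicts with complete-case preparation")
      cfg$exposure_missing <- "recode_insecure"
    },
    complete_case = {
      cfg$prep$complete_case <- TRUE
      cfg$prep$locf_enabled <- FALSE
    },
    health_time_invariant = {
      den <- cfg$weight_spec$denominator
      hit <- den %in% health
      den[hit] <- paste0(den[hit], "_base")
      cfg$weight_spec$denominator <- den
    },
    alt_childhood_ses = {
      swap <- function(v) {
        v[v == "parental_edu_gt_hs"] <- "childhood_ses"
        v
      }
      cfg$weight_spec$denominator <- swap(cfg$weight_spec$denominator)
      cfg$weight_spec$cens_denominator <-
        swap(cfg$weight_spec$cens_denominator)
    })
  cfg
}

#' Run one sensitivity scenario
#'
#' Applies the scenario's single configuration change and re-runs the full
#' pipeline (preparation, weights, truncation, growth model, bootstrap if
#' configured).
#'
#' @param panel raw person-wave panel.
#' @param scn a [scenario()] (or scenario name).
#' @param base_config the base [pipeline_config()].
#' @return a `msmfi_result` tagged with the scenario name.
#' @export
run_scenario <- function(panel, scn, base_config = pipeline_config()) {
  if (is.character(scn)) scn <- scenario(scn)
  cfg <- scenario_config(scn, base_config)
  run <- run_msm(panel, cfg)
  run$result$scenario <- scn$name
  run$result
}

#' Collate base and scenario results into a comparison table
#'
#' @param results list of `msmfi_result` objects; the untagged one (no
#'   scenario) is flagged as the base analysis.
#' @return data frame: `scenario`, `beta_interaction`, `ci_lower`,
#'   `ci_upper`, `excess_years_per_decade`, `n_persons`, `n_obs`, `base`.
#' @export
collate_scenarios <- function(results) {
  .stop_if(length(results) < 1, "need at least one result")
  rows <- lapply(results, function(r) {
    ci <- if (!is.null(r$ci)) r$ci["exposure:time_years", ] else c(NA, NA)
    data.frame(scenario = if (is.null(r$scenario)) "base" else r$scenario,
               beta_interaction = r$beta_interaction,
               ci_lower = ci[[1]], ci_upper = ci[[2]],
               excess_years_per_decade = r$excess_years_per_decade,
               n_persons = r$n_persons, n_obs = r$n_obs)
  })
  out <- do.call(rbind, rows)
  out$base <- out$scenario == "base"
  rownames(out) <- NULL
  out
}
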