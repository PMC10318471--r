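#' Write a person-wave panel as tidy CSV with a JSON column dictionary
#'
#' One row per person-wave, missing values as empty fields; a `.dict.json`
#' sidecar documents each column.
#'
#' @param panel person-wave panel.
#' @param path CSV path; the dictionary goes to `sub(".csv", ".dict.json")`.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  utils::write.csv(panel, path, row.names = FALSE, na = "")
  dict <- list(
    person_id = "person identifier",
    wave = "0-based biennial wave index",
    time_years = "years since baseline (2 x wave)",
    age0 = "baseline age, years", sex = "1 = female",
    education_years = "completed education, years",
    race_group = "1 = minoritized race/ethnicity group",
    parental_edu_gt_hs = "1 = parental education beyond high school",
    born_south = "1 = born in a southern state",
    childhood_ses = "childhood socioeconomic circumstances proxy (z-like)",
    married = "1 = married/partnered",
    log_eq_income = "log equivalized household income ($1000)",
    log_eq_wealth = "log equivalized household wealth ($1000)",
    chronic_count = "number of chronic conditions (0-8)",
    depressive_sx = "depressive symptoms (0-8)",
    bmi = "body mass index", drinks = "1 = current drinker",
    smokes = "1 = current smoker",
    exposure = "food insecurity (1 = insecure), empty = missing",
    outcome = "standardized memory score, empty = missing",
    status = "active / lost / dead",
    responded = "1 = interviewed at this wave",
    C = "censoring indicator (1 at first lost wave, empty once dead/lost)")
  dict <- dict[names(dict) %in% names(panel)]
  jsonlite::write_json(dict, sub("\\.csv$", ".dict.json", path),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a person-wave panel written by [write_panel()]
#'
#' @param path CSV path.
#' @return person-wave data frame.
#' @export
read_panel <- function(path) {
  p <- utils::read.csv(path, na.strings = "", stringsAsFactors = FALSE)
  int_cols <- intersect(c("person_id", "wave", "sex", "race_group",
                          "parental_edu_gt_hs", "born_south", "married",
                          "chronic_count", "depressive_sx", "drinks",
                          "smokes", "exposure", "responded", "C"), names(p))
  for (cl in int_cols) p[[cl]] <- as.integer(p[[cl]])
  p
}

#' Serialize a fitted result as a coefficient table (CSV/JSON)
#'
#' @param result a `msmfi_result`.
#' @param path_csv,path_json optional output paths.
#' @return the coefficient table, invisibly if written.
#' @export
result_table <- function(result, path_csv = NULL, path_json = NULL) {
  ci <- result$ci
  get_ci <- function(nm, i) if (!is.null(ci) && nm %in% rownames(ci))
    ci[nm, i] else NA_real_
  tab <- data.frame(
    term = c("exposure", "time_years", "exposure:time_years"),
    estimate = c(result$beta_exposure, result$beta_time,
                 result$beta_interaction),
    ci_lower = vapply(c("exposure", "time_years", "exposure:time_years"),
                      get_ci, 0, i = 1L),
    ci_upper = vapply(c("exposure", "time_years", "exposure:time_years"),
                      get_ci, 0, i = 2L),
    excess_years_per_decade = c(NA, NA, result$excess_years_per_decade))
  if (!is.null(path_csv)) utils::write.csv(tab, path_csv, row.names = FALSE)
  if (!is.null(path_json)) {
    jsonlite::write_json(list(coefficients = tab,
                              n_persons = result$n_persons,
                              n_obs = result$n_obs,
                              n_boot = result$n_boot,
                              estimator = result$estimator_used),
                         path_json, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
  }
  if (is.null(path_csv) && is.null(path_json)) tab else invisible(tab)
}
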