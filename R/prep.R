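#' Code food insecurity from the two survey items
#'
#' Item 1 asks whether the household has always had enough money to buy the
#' food it needs (yes / no / dont_know / refused); item 2, asked only of
#' those not answering yes to item 1, asks whether the respondent ever ate
#' less than they felt they should for lack of money (yes / no). A "no" to
#' item 1 or a "yes" to item 2 codes as food insecure (1); a "yes" to item 1
#' codes as food secure (0); a non-informative item 1 (dont_know/refused)
#' falls through to item 2, and codes as missing if item 2 is also missing.
#'
#' @param q1_enough_money character vector in
#'   `c("yes","no","dont_know","refused","missing")`.
#' @param q2_ate_less character vector in `c("yes","no","missing")`; may
#'   only be populated when item 1 was not answered "yes".
#' @return integer vector: 1 (insecure), 0 (secure) or `NA`.
#' @export
code_food_insecurity <- function(q1_enough_money, q2_ate_less) {
  q1 <- match.arg(q1_enough_money,
                  c("yes", "no", "dont_know", "refused", "missing"),
                  several.ok = TRUE)
  q2 <- match.arg(q2_ate_less, c("yes", "no", "missing"), several.ok = TRUE)
  .stop_if(length(q1) != length(q2),
           "q1_enough_money and q2_ate_less must have equal length")
  .stop_if(any(q1 == "yes" & q2 != "missing"),
           "invalid response pattern: item 2 populated although item 1 = yes")
  out <- rep(NA_integer_, length(q1))
  out[q1 == "no"] <- 1L
  out[q1 == "yes"] <- 0L
  fall <- q1 %in% c("dont_know", "refused", "missing")
  out[fall & q2 == "yes"] <- 1L
  out[fall & q2 == "no"] <- 0L
  out
}

#' Preparation configuration
#'
#' @param baseline_wave index of the baseline wave (default 0).
#' @param min_baseline_age eligibility age floor in years (default 50).
#' @param locf_enabled carry last observations forward for exposure and
#'   covariates among persons alive and under observation.
#' @param log_policy `"signed_log1p"` (total, monotone, handles zero and
#'   negative wealth) or `"ln"` (plain natural log, positive amounts only).
#' @param complete_case drop person-waves with any missing exposure or
#'   covariate instead of imputing.
#' @return a list of class `msmfi_prep_config`.
#' @export
prep_config <- function(baseline_wave = 0L, min_baseline_age = 50,
                        locf_enabled = TRUE,
                        log_policy = c("signed_log1p", "ln"),
                        complete_case = FALSE) {
  .check_nonneg(min_baseline_age, "min_baseline_age")
  structure(list(baseline_wave = as.integer(baseline_wave),
                 min_baseline_age = min_baseline_age,
                 locf_enabled = isTRUE(locf_enabled),
                 log_policy = match.arg(log_policy),
                 complete_case = isTRUE(complete_case)),
            class = "msmfi_prep_config")
}

#' Apply eligibility filters
#'
#' Drops, in fixed order: (1) persons below the baseline age floor,
#' (2) persons with missing baseline exposure, (3) persons with no
#' non-missing outcome at any wave. The order is fixed so exclusion counts
#' are reproducible.
#'
#' @param panel person-wave panel with wave-0 rows for every person.
#' @param cfg a [prep_config()].
#' @return list with `panel` (eligible persons) and `exclusion_log`
#'   (named counts: `age`, `exposure`, `outcome`).
#' @export
apply_eligibility <- function(panel, cfg = prep_config()) {
  base <- panel[panel$wave == cfg$baseline_wave, ]
  .stop_if(any(duplicated(base$person_id)), "duplicated baseline rows")
  miss_base <- setdiff(unique(panel$person_id), base$person_id)
  .stop_if(length(miss_base) > 0, "persons lack a baseline-wave row")

  drop_age <- base$person_id[base$age0 < cfg$min_baseline_age]
  base2 <- base[!base$person_id %in% drop_age, ]
  drop_expo <- base2$person_id[is.na(base2$exposure)]
  keep <- setdiff(base2$person_id, drop_expo)
  has_y <- tapply(!is.na(panel$outcome[panel$person_id %in% keep]),
                  panel$person_id[panel$person_id %in% keep], any)
  drop_y <- as.vector(names(has_y)[!has_y])
  keep <- setdiff(keep, drop_y)
  .stop_if(length(keep) == 0, "no persons remain after eligibility filtering")

  out <- panel[panel$person_id %in% keep, ]
  rownames(out) <- NULL
  list(panel = out,
       exclusion_log = c(age = length(drop_age),
                         exposure = length(drop_expo),
                         outcome = length(drop_y)))
}

#' Last observation carried forward for exposure and covariates
#'
#' For each person, missing exposure and time-varying covariate values at
#' waves where the person is alive and under observation (`status ==
#' "active"`) are replaced by the most recent non-missing value. Outcomes
#' are never imputed, nothing is carried into waves after death or loss to
#' follow-up, and values missing before any observation stay missing.
#' Idempotent by construction.
#'
#' @param panel person-wave panel, ordered or orderable by person and wave.
#' @param columns columns to fill; defaults to exposure plus the
#'   time-varying covariates.
#' @return the imputed panel.
#' @export
locf_impute <- function(panel, columns = c("exposure", .L_COLS)) {
  ord <- order(panel$person_id, panel$wave)
  panel <- panel[ord, ]
  columns <- intersect(columns, names(panel))
  active <- panel$status == "active"
  pid <- panel$person_id
  new_person <- c(TRUE, pid[-1] != pid[-length(pid)])
  ix <- seq_len(nrow(panel))
  person_start <- ix[new_person][cumsum(new_person)]
  for (cl in columns) {
    x <- panel[[cl]]
    last_valid <- cummax(ifelse(!is.na(x), ix, 0L))
    fill <- active & is.na(x) & last_valid >= person_start
    x[fill] <- x[last_valid[fill]]
    panel[[cl]] <- x
  }
  rownames(panel) <- NULL
  panel
}

#' Equivalize a household amount and log-transform it
#'
#' Divides by the square root of household size (to account for household
#' size and composition) and applies the configured log policy:
#' `"signed_log1p"` is `sign(x) * log(1 + |x|)` (total and monotone, so zero
#' and negative wealth are handled), `"ln"` is the plain natural log and
#' requires a strictly positive equivalized amount.
#'
#' @param amount currency amount (vectorized).
#' @param household_size integer >= 1 (vectorized).
#' @param policy `"signed_log1p"` (default) or `"ln"`.
#' @return transformed numeric vector, monotone in `amount`.
#' @export
equivalize_and_log <- function(amount, household_size,
                               policy = c("signed_log1p", "ln")) {
  policy <- match.arg(policy)
  .stop_if(any(household_size < 1, na.rm = TRUE), "household_size must be >= 1")
  x <- amount / sqrt(household_size)
  if (policy == "ln") {
    .stop_if(any(x <= 0, na.rm = TRUE),
             "plain log requires strictly positive equivalized amounts")
    log(x)
  } else {
    sign(x) * log1p(abs(x))
  }
}

#' Build per-wave censoring indicators
#'
#' Censoring means loss to follow-up from causes other than death: `C = 0`
#' while under observation, `C = 1` at the first wave a living person fails
#' to be under observation, and `NA` (undefined) thereafter and at or after
#' death — the dead contribute no censoring risk sets, since death is a
#' competing terminal event rather than censoring.
#'
#' @param panel person-wave panel with a monotone `status` column.
#' @return the panel with an integer `C` column appended.
#' @export
build_censoring_indicators <- function(panel) {
  ord <- order(panel$person_id, panel$wave)
  panel <- panel[ord, ]
  code <- c(active = 0L, lost = 1L, dead = 2L)[panel$status]
  .stop_if(any(is.na(code)), "status must be active/lost/dead")
  pid <- panel$person_id
  new_person <- c(TRUE, pid[-1] != pid[-length(pid)])
  # monotonicity: within person, coded status may change value but never
  # back to active, and dead is absorbing
  prev <- c(0L, code[-length(code)])
  prev[new_person] <- 0L
  .stop_if(any(prev > 0L & code != prev & !(prev == 1L & code == 1L) &
                 !(prev == 2L & code == 2L)),
           "non-monotone status: person returns from lost/dead")
  C <- rep(NA_integer_, nrow(panel))
  C[code == 0L] <- 0L
  first_lost <- code == 1L & prev == 0L
  C[first_lost] <- 1L
  panel$C <- C
  rownames(panel) <- NULL
  panel
}

#' Run the full preparation stage
#'
#' Eligibility filtering, censoring-indicator construction, and (unless
#' `complete_case`) LOCF imputation of exposure and covariates.
#'
#' @param panel raw person-wave panel.
#' @param cfg a [prep_config()].
#' @return list: `panel` (analysis-ready), `exclusion_log`.
#' @export
prepare_panel <- function(panel, cfg = prep_config()) {
  el <- apply_eligibility(panel, cfg)
  out <- build_censoring_indicators(el$panel)
  if (cfg$locf_enabled && !cfg$complete_case) out <- locf_impute(out)
  list(panel = out, exclusion_log = el$exclusion_log)
}
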