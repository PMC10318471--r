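#' Baseline descriptive table, overall and by baseline exposure
#'
#' Mean (SD) for symmetric continuous variables, n (%) for binaries, and
#' median (IQR) for skewed ones (income, wealth, chronic conditions,
#' depressive symptoms). Income and wealth are reported on the original
#' (unlogged, equivalized, $1000) scale when the panel carries log values.
#'
#' @param panel analysis-ready panel.
#' @param baseline_wave baseline wave index.
#' @return data frame of class `msmfi_table1`: `variable`, `statistic`,
#'   `overall`, `exposed`, `unexposed`, plus numeric columns
#'   `overall_value` (and group values) for machine checks.
#' @export
describe_baseline <- function(panel, baseline_wave = 0L) {
  b <- panel[panel$wave == baseline_wave, ]
  groups <- list(overall = rep(TRUE, nrow(b)),
                 unexposed = !is.na(b$exposure) & b$exposure == 0,
                 exposed = !is.na(b$exposure) & b$exposure == 1)

  mean_sd <- function(x, g) {
    x <- x[g & !is.na(x)]
    c(sprintf("%.2f (%.2f)", mean(x), stats::sd(x)), mean(x))
  }
  n_pct <- function(x, g) {
    x <- x[g & !is.na(x)]
    c(sprintf("%d (%.2f)", sum(x == 1), 100 * mean(x == 1)),
      100 * mean(x == 1))
  }
  med_iqr <- function(x, g) {
    x <- x[g & !is.na(x)]
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    c(sprintf("%.2f (%.2f-%.2f)", q[2], q[1], q[3]), q[2])
  }

  vars <- list(
    list("n", function(x, g) c(sprintf("%d", sum(g)), sum(g)),
         quote(rep(1, nrow(b)))),
    list("Age, mean (SD), y", mean_sd, quote(b$age0)),
    list("Female, No. (%)", n_pct, quote(b$sex)),
    list("Education, mean (SD), y", mean_sd, quote(b$education_years)),
    list("Married, No. (%)", n_pct, quote(b$married)),
    list("Parental education >HS, No. (%)", n_pct,
         quote(b$parental_edu_gt_hs)),
    list("Born in South, No. (%)", n_pct, quote(b$born_south)),
    list("Income (per $1000), median (IQR)", med_iqr,
         quote(exp(b$log_eq_income))),
    list("Wealth (per $1000), median (IQR)", med_iqr,
         quote(exp(b$log_eq_wealth))),
    list("Chronic conditions, median (IQR)", med_iqr,
         quote(b$chronic_count)),
    list("Depressive symptoms, median (IQR)", med_iqr,
         quote(b$depressive_sx)),
    list("BMI, mean (SD)", mean_sd, quote(b$bmi)),
    list("Current drinking, No. (%)", n_pct, quote(b$drinks)),
    list("Current smoker, No. (%)", n_pct, quote(b$smokes)),
    list("Outcome, mean (SD)", mean_sd, quote(b$outcome)))

  out <- do.call(rbind, lapply(vars, function(v) {
    x <- eval(v[[3]])
    vals <- lapply(groups, function(g) v[[2]](x, g))
    data.frame(variable = v[[1]],
               overall = vals$overall[1], exposed = vals$exposed[1],
               unexposed = vals$unexposed[1],
               overall_value = as.numeric(vals$overall[2]),
               exposed_value = as.numeric(vals$exposed[2]),
               unexposed_value = as.numeric(vals$unexposed[2]))
  }))
  rownames(out) <- NULL
  class(out) <- c("msmfi_table1", "data.frame")
  out
}

#' Baseline exposure prevalence
#'
#' @param n_exposed count exposed at baseline.
#' @param n_total total analytic sample size.
#' @param digits rounding for the percentage (default 1).
#' @return prevalence in percent.
#' @export
baseline_prevalence_pct <- function(n_exposed, n_total, digits = 1) {
  .stop_if(n_total <= 0, "n_total must be positive")
  round(100 * n_exposed / n_total, digits)
}

#' Attrition summary over follow-up
#'
#' Per-wave counts and proportions of persons active, lost to follow-up and
#' dead, overall or stratified by baseline exposure.
#'
#' @param panel person-wave panel with `status`.
#' @param by_baseline_exposure stratify by wave-0 exposure.
#' @return data frame with one row per wave (and stratum).
#' @export
attrition_summary <- function(panel, by_baseline_exposure = FALSE) {
  b <- panel[panel$wave == 0L, c("person_id", "exposure")]
  names(b)[2] <- "baseline_exposure"
  p <- merge(panel, b, by = "person_id")
  strat <- if (by_baseline_exposure) {
    split(p, p$baseline_exposure)
  } else {
    list(all = p)
  }
  out <- do.call(rbind, lapply(names(strat), function(s) {
    pp <- strat[[s]]
    agg <- do.call(rbind, lapply(split(pp, pp$wave), function(d) {
      data.frame(stratum = s, wave = d$wave[1], n = nrow(d),
                 active = mean(d$status == "active"),
                 lost = mean(d$status == "lost"),
                 dead = mean(d$status == "dead"))
    }))
    agg
  }))
  rownames(out) <- NULL
  out
}
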