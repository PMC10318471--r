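# Internal helpers shared across modules.

# Deterministic substream seeds: every margin of randomness (exposure draws,
# covariate shocks, censoring, ...) gets its own seed derived from the master
# seed, so regenerating one margin never perturbs another.
.SUBSTREAMS <- c(
  baseline = 1L, covariates = 2L, exposure = 3L, noise = 4L,
  censoring = 5L, death = 6L, nonresponse = 7L, missingness = 8L,
  oracle = 9L, bootstrap = 10L
)

sub_seed <- function(seed, stream) {
  k <- .SUBSTREAMS[[stream]]
  s <- (abs(as.double(seed)) * 48271 + k * 104729) %% 2147483399
  as.integer(s) + 1L
}

.stop_if <- function(cond, ...) if (isTRUE(cond)) stop(..., call. = FALSE)

.check_prob <- function(x, name) {
  .stop_if(!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1,
           sprintf("'%s' must be a probability in [0, 1]", name))
  x
}

.check_count <- function(x, name, min = 1L) {
  .stop_if(!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
             x != floor(x),
           sprintf("'%s' must be an integer >= %d", name, min))
  as.integer(x)
}

.check_nonneg <- function(x, name) {
  .stop_if(!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0,
           sprintf("'%s' must be a non-negative number", name))
  x
}

# Weighted mean/variance with frequency-style analytic weights.
.wmean <- function(x, w) sum(w * x) / sum(w)
.wvar <- function(x, w) {
  m <- .wmean(x, w)
  sum(w * (x - m)^2) / sum(w)
}

# Baseline covariate column names (V) and time-varying ones (L).
.V_COLS <- c("age0", "sex", "education_years", "race_group",
             "parental_edu_gt_hs", "born_south")
.L_COLS <- c("married", "log_eq_income", "log_eq_wealth", "chronic_count",
             "depressive_sx", "bmi", "drinks", "smokes")
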