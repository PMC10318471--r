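test_that("food-insecurity coding implements the two-item rule", {
  # (q1, q2) -> coded value, including the fall-through via item 2
  expect_identical(code_food_insecurity("yes", "missing"), 0L)
  expect_identical(code_food_insecurity("no", "missing"), 1L)
  expect_identical(code_food_insecurity("dont_know", "yes"), 1L)
  expect_identical(code_food_insecurity("refused", "missing"), NA_integer_)
  expect_identical(
    code_food_insecurity(c("yes", "no", "dont_know", "refused", "missing"),
                         c("missing", "missing", "no", "yes", "missing")),
    c(0L, 1L, 0L, 1L, NA))
  expect_error(code_food_insecurity("yes", "no"), "item 1 = yes")
})

test_that("every coded value is reachable from some raw response pattern", {
  combos <- expand.grid(
    q1 = c("yes", "no", "dont_know", "refused", "missing"),
    q2 = c("yes", "no", "missing"), stringsAsFactors = FALSE)
  combos <- combos[!(combos$q1 == "yes" & combos$q2 != "missing"), ]
  coded <- mapply(code_food_insecurity, combos$q1, combos$q2)
  expect_setequal(unique(coded), c(0L, 1L, NA_integer_))
})

test_that("eligibility drops in fixed order with exact counts", {
  # 100 persons: 10 under-age; 5 of the rest missing baseline exposure;
  # 2 of the rest with no outcome anywhere
  persons <- lapply(1:100, function(i) {
    age <- if (i <= 10) 45 else 70
    ex <- if (i > 10 && i <= 15) NA else 0L
    out <- if (i > 15 && i <= 17) NA else 0.5
    list(list(wave = 0, age0 = age, exposure = ex, outcome = out),
         list(wave = 1, age0 = age, exposure = 0L, outcome = out))
  })
  pan <- mini_panel(persons)
  el <- apply_eligibility(pan, prep_config())
  expect_identical(el$exclusion_log, c(age = 10L, exposure = 5L,
                                       outcome = 2L))
  expect_equal(length(unique(el$panel$person_id)), 83)

  ok <- apply_eligibility(el$panel, prep_config())
  expect_identical(ok$exclusion_log, c(age = 0L, exposure = 0L,
                                       outcome = 0L))
  expect_identical(ok$panel, el$panel)

  all_young <- mini_panel(lapply(1:3, function(i)
    list(list(wave = 0, age0 = 40))))
  expect_error(apply_eligibility(all_young), "no persons remain")
})

test_that("LOCF fills forward only, never into dead/lost waves, idempotent", {
  pan <- mini_panel(list(
    # exposure (1, NA, NA, 0) while active -> (1, 1, 1, 0)
    list(list(wave = 0, exposure = 1L), list(wave = 1, exposure = NA),
         list(wave = 2, exposure = NA), list(wave = 3, exposure = 0L)),
    # covariate missing at wave 0, observed at wave 1: wave 0 stays NA
    list(list(wave = 0, married = NA), list(wave = 1, married = 1L)),
    # dies at wave 3; wave-4 row present but must stay empty
    list(list(wave = 0, exposure = 1L), list(wave = 1, exposure = 1L),
         list(wave = 2, exposure = NA),
         list(wave = 3, exposure = NA, outcome = NA, status = "dead",
              responded = 0L),
         list(wave = 4, exposure = NA, outcome = NA, status = "dead",
              responded = 0L))))
  out <- locf_impute(pan)
  expect_identical(out$exposure[out$person_id == 1], c(1L, 1L, 1L, 0L))
  expect_identical(out$married[out$person_id == 2], c(NA, 1L))
  expect_identical(out$exposure[out$person_id == 3],
                   c(1L, 1L, 1L, NA, NA))
  # idempotence and non-destruction
  expect_identical(locf_impute(out), out)
  keep <- !is.na(pan$exposure)
  expect_identical(out$exposure[keep], pan$exposure[keep])
})

test_that("LOCF idempotence holds on random ragged panels", {
  for (s in 1:5) {
    pan <- flat_panel(20, 6, seed = s)
    set.seed(s + 100)
    for (cl in c("exposure", "married", "log_eq_income")) {
      pan[[cl]][sample(nrow(pan), 40)] <- NA
    }
    pan$status[pan$wave >= 4 & pan$person_id <= 5] <- "lost"
    once <- locf_impute(pan)
    expect_identical(locf_impute(once), once)
    nonmiss <- !is.na(pan$log_eq_income)
    expect_identical(once$log_eq_income[nonmiss],
                     pan$log_eq_income[nonmiss])
  }
})

test_that("equivalization and log policies evaluate the stated transforms", {
  expect_equal(equivalize_and_log(2 * exp(1), 4, "ln"), 1.0)
  expect_equal(equivalize_and_log(0, 3, "signed_log1p"), 0)
  expect_equal(equivalize_and_log(-5000, 1, "signed_log1p"), -log1p(5000))
  expect_error(equivalize_and_log(10, 0), ">= 1")
  expect_error(equivalize_and_log(-1, 1, "ln"), "positive")
  x <- seq(-100, 100, by = 7)
  expect_true(all(diff(equivalize_and_log(x, 2, "signed_log1p")) > 0))
})

test_that("censoring indicators mark first lost wave, undefined after death", {
  pan <- mini_panel(list(
    list(list(wave = 0), list(wave = 1), list(wave = 2), list(wave = 3),
         list(wave = 4),
         list(wave = 5, status = "lost", responded = 0L, outcome = NA,
              exposure = NA)),
    list(list(wave = 0), list(wave = 1), list(wave = 2),
         list(wave = 3, status = "dead", responded = 0L, outcome = NA,
              exposure = NA),
         list(wave = 4, status = "dead", responded = 0L, outcome = NA,
              exposure = NA)),
    list(list(wave = 0), list(wave = 1), list(wave = 2))))
  out <- build_censoring_indicators(pan)
  expect_identical(out$C[out$person_id == 1], c(0L, 0L, 0L, 0L, 0L, 1L))
  expect_identical(out$C[out$person_id == 2], c(0L, 0L, 0L, NA, NA))
  expect_identical(out$C[out$person_id == 3], c(0L, 0L, 0L))

  bad <- mini_panel(list(list(
    list(wave = 0), list(wave = 1, status = "lost", responded = 0L),
    list(wave = 2))))
  expect_error(build_censoring_indicators(bad), "non-monotone")
})
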