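# Cohort construction: eligibility, analysis window, baseline capture,
# adherence, comorbidity flags.

test_that("index_and_end follows first-HbA1c / last-any rule", {
  d <- as.Date("2013-01-01")
  w <- index_and_end(d + c(0, 400), d + 500)
  expect_equal(w$index_date, d)
  expect_equal(w$end_date, d + 500)
  w2 <- index_and_end(d + 10, d + c(100, 300))
  expect_equal(w2$index_date, d + 10)
  expect_equal(w2$end_date, d + 300)
  w3 <- index_and_end(d + c(0, 700), d + 500)   # last HbA1c after last SCr
  expect_equal(w3$end_date, d + 700)
  expect_error(index_and_end(as.Date(character(0))), "no index")
})

test_that("baseline_nearest picks nearest-in-window, ties to earlier", {
  d <- as.Date("2013-06-01")
  b <- baseline_nearest(d + c(-10, 200), c(1.1, 1.2), d)
  expect_equal(b$value, 1.1)
  expect_null(baseline_nearest(d - 45, 1.0, d))          # outside -30
  b2 <- baseline_nearest(d + c(100, -20), c(1.3, 1.4), d)
  expect_equal(b2$value, 1.4)
  b3 <- baseline_nearest(d + c(20, -20), c(1.5, 1.6), d) # tie -> earlier
  expect_equal(b3$value, 1.6)
})

test_that("adherence is visits per follow-up year", {
  d <- as.Date("2012-01-01")
  expect_equal(adherence(d + round(seq(0, 5 * 365.25, length.out = 10)),
                         d, d + round(5 * 365.25)),
               10 / (round(5 * 365.25) / 365.25))
  expect_equal(adherence(d + c(0, 90, 180, 270, 365), d, d + 365),
               5 / (365 / 365.25))
  expect_error(adherence(d, d, d), "zero follow-up")
})

test_that("comorbidity flags normalise case and dots", {
  f <- flag_comorbidity("I10")
  expect_true(f$hypertension)
  expect_false(f$ascvd)
  f2 <- flag_comorbidity("E11.9")
  expect_false(f2$hypertension || f2$ascvd)
  f3 <- flag_comorbidity("i25.1")
  expect_true(f3$ascvd)
  f4 <- flag_comorbidity(c("I13.2", "I70"))
  expect_true(f4$hypertension)
  expect_true(f4$ascvd)
  expect_error(flag_comorbidity("I10", hypertension_prefixes = character(0)),
               "nonempty")
})

test_that("eligibility on the hand fixture gives the expected decisions", {
  raw <- fixture_raw_10()
  el <- apply_eligibility(raw)
  expect_setequal(el$included, c("S01", "S09", "S10"))
  got <- setNames(el$exclusions$reason, el$exclusions$id)
  want <- fixture_expected_reasons[!is.na(fixture_expected_reasons)]
  expect_mapequal(as.list(got), as.list(want))
  # every subject appears exactly once in included + exclusion log
  expect_setequal(c(el$included, el$exclusions$id), raw$subjects$id)
  expect_equal(length(c(el$included, el$exclusions$id)),
               nrow(raw$subjects))
})

test_that("eligibility is idempotent on the included set", {
  cfg <- sim_config(n_subjects = 80, seed = 3L)
  raw <- simulate_cohort(cfg)
  el <- apply_eligibility(raw)
  keep <- function(tb) tb[tb$id %in% el$included, , drop = FALSE]
  raw2 <- raw
  raw2$subjects <- keep(raw$subjects)
  raw2$visits <- keep(raw$visits)
  raw2$labs <- keep(raw$labs)
  raw2$meds <- keep(raw$meds)
  raw2$diagnoses <- keep(raw$diagnoses)
  el2 <- apply_eligibility(raw2)
  expect_setequal(el2$included, el$included)
  expect_equal(nrow(el2$exclusions), 0)
})

test_that("build_cohort derives the fixture's hand-worked values", {
  raw <- fixture_raw_10()
  co <- build_cohort(raw)
  expect_setequal(co$subject_id, c("S01", "S09", "S10"))
  r <- function(id) co[co$subject_id == id, ]

  s1 <- r("S01")
  expect_equal(s1$hvs, 50)
  expect_equal(s1$hvs_category, 3L)
  expect_equal(s1$baseline_egfr, 90, tolerance = 1e-9)
  expect_equal(s1$mean_slope, -5, tolerance = 1e-9)
  expect_true(s1$rapid_decliner)   # boundary -5 inclusive
  expect_true(s1$hypertension)
  expect_false(s1$ascvd)
  expect_true(s1$ever_insulin && s1$ever_statin)
  expect_false(s1$ever_arb_acei)
  expect_equal(s1$twa_hba1c, 5684.5 / 730, tolerance = 1e-12)
  expect_equal(s1$adherence, 5 / (730 / 365.25), tolerance = 1e-12)
  expect_equal(s1$n_scr, 3L)

  s9 <- r("S09")
  expect_equal(s9$hvs, 0)
  expect_equal(s9$hvs_category, 1L)
  expect_equal(s9$baseline_egfr, 83.94524298425736, tolerance = 1e-9)
  expect_equal(s9$mean_slope, 1, tolerance = 1e-9)
  expect_false(s9$rapid_decliner)
  expect_true(s9$ascvd)            # lower-case dotted code

  s10 <- r("S10")
  expect_equal(s10$hvs, 100)
  expect_equal(s10$hvs_category, 5L)
  expect_equal(s10$mean_slope, -12.3, tolerance = 1e-9)  # umol/L converted
  expect_true(s10$rapid_decliner)
  expect_equal(s10$last_measure_gap_days, 100)
  expect_true(s10$ever_sglt2i_glp1ra)
})

test_that("cohort rows satisfy their invariants on simulated data", {
  cfg <- sim_config(n_subjects = 150, seed = 21L)
  co <- build_cohort(simulate_cohort(cfg))
  expect_true(all(co$follow_up_years > 0))
  expect_true(all(co$hvs >= 0 & co$hvs <= 100))
  expect_true(all(co$adherence > 0))
  expect_true(all(co$baseline_egfr >= 15))
  expect_true(all(co$end_date >= co$index_date + 365))
  expect_true(all(co$age_at_index >= 18))
  expect_true(all(co$n_hba1c >= 2 & co$n_scr >= 3))
  expect_equal(co$hvs_category, hvs_category(co$hvs))
  expect_equal(co$rapid_decliner, co$mean_slope <= -5)
})
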