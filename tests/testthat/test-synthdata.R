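# Synthetic EMR generator: determinism, series contracts, truth recovery.

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("sim_config validates fields and names the offender", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(n_subjects = 0), "n_subjects")
  expect_error(sim_config(category_probs = c(0.5, 0.5, 0, 0, 0.1)),
               "category_probs")
  expect_error(sim_config(jump_prob_by_category = c(0.1, 0.2, 0.3, 0.4, 1.2)),
               "jump_prob_by_category")
  expect_error(sim_config(visit_rate = 0), "visit_rate")
  expect_error(sim_config(egfr_noise_sd = -1), "egfr_noise_sd")
  expect_error(sim_config(p_miss_scr = 1.5), "p_miss_scr")
})

test_that("simulate_cohort is byte-identical under the same seed", {
  cfg <- sim_config(n_subjects = 40, seed = 99L)
  r1 <- simulate_cohort(cfg)
  r2 <- simulate_cohort(cfg)
  expect_identical(r1, r2)
  r3 <- simulate_cohort(sim_config(n_subjects = 40, seed = 100L))
  expect_false(identical(r1$labs, r3$labs))
})

test_that("simulate_cohort emits consistent tables and handles n=1", {
  raw <- simulate_cohort(sim_config(n_subjects = 1, seed = 5L))
  expect_equal(nrow(raw$subjects), 1)
  for (tb in c("visits", "labs", "diagnoses")) {
    expect_true(all(raw[[tb]]$id %in% raw$subjects$id))
  }
  expect_true(all(raw$labs$value > 0))
  raw2 <- simulate_cohort(sim_config(n_subjects = 30, seed = 6L))
  for (tb in c("visits", "labs", "meds", "diagnoses")) {
    expect_true(all(raw2[[tb]]$id %in% raw2$subjects$id))
    expect_false(any(is.na(raw2[[tb]]$date %||% raw2[[tb]]$visit_date)))
  }
})

test_that("degenerate config: single band, no jumps -> all realised HVS 0", {
  cfg <- sim_config(n_subjects = 25, seed = 17L,
                    category_probs = c(1, 0, 0, 0, 0),
                    jump_prob_by_category = c(0, 0.3, 0.5, 0.7, 0.9),
                    p_miss_hba1c = 0)
  raw <- simulate_cohort(cfg)
  labs <- raw$labs[raw$labs$analyte == "HBA1C", ]
  for (id in unique(labs$id)) {
    v <- labs$value[labs$id == id]
    if (length(v) >= 2) expect_equal(hvs(v), 0)
  }
})

test_that("simulate_hba1c_series honours the jump probability exactly at 0/1", {
  set.seed(31)
  s0 <- simulate_hba1c_series(7.5, 0, 20)
  expect_equal(hvs(s0$value), 0)
  s1 <- simulate_hba1c_series(7.5, 1, 20)
  expect_equal(hvs(s1$value), 100)
  expect_error(simulate_hba1c_series(7, 0.5, 1), "n_visits")
  expect_true(all(s1$value >= 4 & s1$value <= 15))
})

test_that("realised HVS is binomial with mean jump_prob", {
  # analytic oracle: HVS/100 is Binomial(n-1, p)/(n-1); with p = 0.5,
  # n = 81, 2000 replicates the Monte-Carlo mean is 50 +/- ~0.25
  set.seed(37)
  h <- replicate(2000, hvs(simulate_hba1c_series(7.5, 0.5, 81)$value))
  expect_lt(abs(mean(h) - 50), 1)
  expect_lt(abs(sd(h) - 100 * sqrt(0.25 / 80)), 1)
})

test_that("creatinine series round-trips the planted eGFR trajectory", {
  times <- seq(0, 5, by = 0.5)
  scr <- simulate_creatinine_series(90, -3, times, 0, 55, "M")
  g <- egfr_ckdepi(scr$creatinine, 55 + times, "M")
  expect_equal(g, 90 - 3 * times, tolerance = 1e-9)
  expect_equal(egfr_slope(times, g, min_points = 2L)$slope, -3,
               tolerance = 1e-9)
  # zero slope, zero noise: latent eGFR constant, attained age advances
  scr2 <- simulate_creatinine_series(80, 0, times, 0, 60, "F")
  g2 <- egfr_ckdepi(scr2$creatinine, 60 + times, "F")
  expect_equal(g2, rep(80, length(times)), tolerance = 1e-9)
  expect_warning(simulate_creatinine_series(3, -2, times, 0, 50, "F",
                                            id = "X1"),
                 "floored")
})

test_that("realised band occupancy matches category_probs (chi-square GOF)", {
  # dense-lab config so every band is realisable for every subject
  cfg <- sim_config(n_subjects = 5000, seed = 2024L, visit_rate = 4,
                    visit_rate_logsd = 0, p_miss_hba1c = 0, p_miss_scr = 0,
                    p_unparallel = 0)
  raw <- simulate_cohort(cfg)
  co <- build_cohort(raw)
  expect_gt(nrow(co), 4900)
  tab <- table(factor(co$hvs_category, 1:5))
  p <- suppressWarnings(stats::chisq.test(tab, p = cfg$category_probs))$p.value
  expect_gt(p, 0.01)
})

test_that("noise-free cohort recovers every subject's true slope exactly", {
  cfg <- sim_config(n_subjects = 30, seed = 55L, egfr_noise_sd = 0,
                    p_miss_scr = 0, p_unparallel = 0)
  raw <- simulate_cohort(cfg)
  co <- build_cohort(raw)
  truth <- attr(raw, "truth")
  planted <- truth$true_slope[match(co$subject_id, truth$id)]
  expect_equal(co$mean_slope, planted, tolerance = 1e-9)
})

test_that("raw tables round-trip through delimited text", {
  cfg <- sim_config(n_subjects = 12, seed = 77L)
  raw <- simulate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_raw_tables(raw, dir, config = cfg)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- read_raw_tables(dir)
  for (tb in c("subjects", "visits", "meds", "diagnoses")) {
    expect_equal(back[[tb]], raw[[tb]], ignore_attr = TRUE)
  }
  expect_equal(back$labs$value, raw$labs$value)
  expect_equal(back$labs$date, raw$labs$date)
  m <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(m$seed, 77L)
})

test_that("subject-level simulator plants outcomes and slopes as configured", {
  set.seed(61)
  sim <- simulate_analysis_cohort(12000, rapid_ref_prob = 0.10,
                                  rapid_log_or = c(0, 0, 0, 0, log(3)),
                                  longitudinal = TRUE, confounded = FALSE)
  co <- sim$cohort
  p1 <- mean(co$rapid_decliner[co$hvs_category == 1])
  p5 <- mean(co$rapid_decliner[co$hvs_category == 5])
  expect_lt(abs(p1 - 0.10), 0.03)
  odds <- function(p) p / (1 - p)
  # ~1000 cat-5 subjects: SD of the raw odds ratio is about 0.3
  expect_lt(abs(odds(p5) / odds(p1) - 3), 1)
  # per-subject OLS slopes centre on the planted values; short sparse
  # series make individual slopes heavy-tailed, hence the loose band
  for (k in c(1, 5)) {
    ix <- co$hvs_category == k
    expect_lt(abs(mean(co$mean_slope[ix]) - mean(co$true_slope[ix])), 0.2)
  }
  # confounded gradients present by default, absent when disabled
  set.seed(62)
  simc <- simulate_analysis_cohort(4000)
  ins <- tapply(simc$cohort$ever_insulin, simc$cohort$hvs_category, mean)
  expect_gt(ins[[5]], ins[[1]] + 0.2)
  insu <- tapply(co$ever_insulin, co$hvs_category, mean)
  expect_lt(abs(insu[[5]] - insu[[1]]), 0.1)
})
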