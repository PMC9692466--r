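# Derived biomarkers: CKD-EPI, HVS, TWA HbA1c, slopes, rapid decline.

test_that("egfr_ckdepi matches the independent closed-form oracle", {
  # frozen values from an external evaluation of the 2009 equation
  expect_equal(egfr_ckdepi(0.7, 50, "F"), 101.0251061463907, tolerance = 1e-12)
  expect_equal(egfr_ckdepi(1.4, 65, "M"), 52.35168489372829, tolerance = 1e-12)
})

test_that("egfr_ckdepi is continuous at Scr = kappa and monotone", {
  for (sex in c("F", "M")) {
    kappa <- if (sex == "F") 0.7 else 0.9
    eps <- 1e-9
    expect_equal(egfr_ckdepi(kappa - eps, 60, sex),
                 egfr_ckdepi(kappa + eps, 60, sex), tolerance = 1e-6)
  }
  scr <- seq(0.3, 5, by = 0.05)
  g <- egfr_ckdepi(scr, 55, "M")
  expect_true(all(diff(g) < 0))
  ages <- seq(18, 90, by = 1)
  expect_true(all(diff(egfr_ckdepi(1, ages, "F")) < 0))
  # female adjustment at identical kappa-normalised creatinine
  expect_equal(egfr_ckdepi(0.7, 50, "F") / egfr_ckdepi(0.9, 50, "M"), 1.018,
               tolerance = 1e-12)
})

test_that("creatinine_for_egfr round-trips and agrees with root-finding", {
  set.seed(101)
  for (i in 1:1000) {
    g <- runif(1, 15, 120)
    age <- runif(1, 18, 90)
    sex <- sample(c("F", "M"), 1)
    scr <- creatinine_for_egfr(g, age, sex)
    expect_lt(abs(egfr_ckdepi(scr, age, sex) - g), 1e-6)
  }
  # independent oracle: monotone root-finding on the closed form
  for (g in c(20, 45, 90, 115)) {
    root <- uniroot(function(s) egfr_ckdepi(s, 60, "F") - g,
                    c(0.05, 20), tol = 1e-12)$root
    expect_equal(creatinine_for_egfr(g, 60, "F"), root, tolerance = 1e-8)
  }
  expect_error(creatinine_for_egfr(-1, 50, "F"), "positive")
})

test_that("scr unit conversion handles umol/L", {
  expect_equal(scr_to_mgdl(88.4, "umol/L"), 1)
  expect_equal(scr_to_mgdl(1.2, "mg/dL"), 1.2)
  expect_equal(scr_to_mgdl(c(88.4, 1), c("umol/L", "mg/dL")), c(1, 1))
  expect_error(scr_to_mgdl(1, "mol"), "unit")
})

test_that("hvs counts successive changes >= 0.5% inclusively", {
  expect_equal(hvs(c(7.0, 7.6, 7.5, 8.2, 8.1)), 50)
  expect_equal(hvs(rep(6.5, 6)), 0)
  expect_equal(hvs(c(7.0, 7.5)), 100)    # |delta| exactly 0.50 counts
  expect_equal(hvs(c(7.2, 7.7, 7.75)), 50)
  expect_error(hvs(7.0), "undefined")
})

test_that("hvs is shift-invariant and time-free", {
  set.seed(7)
  for (i in 1:20) {
    v <- round(runif(10, 6, 10), 1)
    expect_equal(hvs(v), hvs(v + 2.3))
  }
})

test_that("hvs_category uses [0,20] then left-open 20%-bands", {
  expect_equal(hvs_category(c(0, 20, 20.01, 40, 60, 80, 80.01, 100)),
               c(1L, 1L, 2L, 2L, 3L, 4L, 5L, 5L))
  expect_error(hvs_category(101), "\\[0, 100\\]")
  expect_error(hvs_category(-0.5), "\\[0, 100\\]")
})

test_that("twa_hba1c integrates the piecewise-linear interpolant", {
  expect_equal(twa_hba1c(c(0, 1, 2), c(7, 7, 7)), 7)
  expect_equal(twa_hba1c(c(0, 1), c(6, 8)), 7)
  expect_equal(twa_hba1c(c(0, 2, 3), c(6, 6, 9)), 6.5)
  expect_equal(twa_hba1c(0, 7.3), 7.3)  # single measure
  # oracle: numeric quadrature of the interpolant
  set.seed(13)
  for (i in 1:10) {
    t <- sort(runif(6, 0, 5))
    v <- runif(6, 6, 10)
    f <- approxfun(t, v)
    num <- integrate(f, t[1], t[6], rel.tol = 1e-10)$value / (t[6] - t[1])
    expect_equal(twa_hba1c(t, v), num, tolerance = 1e-7)
    expect_gte(twa_hba1c(t, v), min(v))
    expect_lte(twa_hba1c(t, v), max(v))
  }
})

test_that("hba1c percent to mmol/mol conversion matches published pairs", {
  expect_equal(round(hba1c_pct_to_mmolmol(7.3)), 56)
  expect_equal(round(hba1c_pct_to_mmolmol(6.8)), 51)
  # a 0.5% change is about 5.5 mmol/mol
  expect_equal(hba1c_pct_to_mmolmol(8.0) - hba1c_pct_to_mmolmol(7.5),
               0.5 * 10.929)
  expect_error(hba1c_pct_to_mmolmol(2.0), "2.15")
})

test_that("egfr_slope equals the closed-form OLS solution", {
  s <- egfr_slope(c(0, 1, 2), c(90, 85, 80))
  expect_equal(s$slope, -5)
  expect_equal(s$intercept, 90)
  set.seed(23)
  for (i in 1:10) {
    t <- sort(runif(10, 0, 6))
    y <- 90 - 3 * t + rnorm(10, 0, 4)
    s <- egfr_slope(t, y)
    oracle <- sum((t - mean(t)) * (y - mean(y))) / sum((t - mean(t))^2)
    expect_equal(s$slope, oracle, tolerance = 1e-12)
    # equivariance: adding c*t raises the slope by exactly c
    expect_equal(egfr_slope(t, y + 2.5 * t)$slope, s$slope + 2.5,
                 tolerance = 1e-9)
  }
})

test_that("egfr_slope windows and minimum-point rules", {
  t <- c(0, 0.5, 1, 3, 5)
  y <- 90 - 2 * t
  expect_equal(egfr_slope(t, y, window_years = 1)$n_points, 3L)
  expect_null(egfr_slope(t, y, window_years = 0.6))     # 2 points < 3
  expect_equal(egfr_slope(t, y, window_years = 0.6, min_points = 2L)$slope,
               -2)
  expect_equal(egfr_slope(t, y, window_years = 10)$slope,
               egfr_slope(t, y)$slope)
})

test_that("rapid_decline threshold is inclusive at -5", {
  expect_true(rapid_decline(-5))
  expect_false(rapid_decline(-4.99))
  expect_true(rapid_decline(-12.3))
  expect_equal(rapid_decline(c(-6, 0, -5)), c(TRUE, FALSE, TRUE))
})

test_that("collapse_daily averages same-day duplicates and sorts", {
  d <- as.Date("2015-03-01") + c(5, 0, 0, 2)
  out <- collapse_daily(d, c(8, 6, 7, 9))
  expect_equal(as.numeric(out$dates - as.Date("2015-03-01")), c(0, 2, 5))
  expect_equal(out$values, c(6.5, 9, 8))
})
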