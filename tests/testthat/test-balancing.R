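# Entropy balancing: exact moment matching, dual solution, diagnostics.

test_that("already-balanced categories get uniform weights and zero duals", {
  set.seed(5)
  x <- rnorm(60)
  X <- data.frame(x = c(x, x))   # two categories, identical distributions
  g <- rep(1:2, each = 60)
  res <- entropy_balance(X, g, balance_spec(covariates = "x"))
  expect_equal(res$weights, rep(1, 120), tolerance = 1e-9)
  expect_true(all(abs(unlist(res$lambdas)) < 1e-6))
})

test_that("3-subject dual matches independent 1-D root-finding", {
  # one category with covariate (0,1,2) balanced to target mean 1.5 (the
  # pooled mean by construction): solve d/dl log sum exp(l*c) = 1.5 by
  # root-finding on the raw scale
  X <- data.frame(x = c(0, 1, 2, 1.0, 2.0, 1.5, 3.0))
  g <- c(1, 1, 1, 2, 2, 2, 2)
  res <- entropy_balance(X, g, balance_spec(covariates = "x",
                                            tolerance = 1e-12))
  grad <- function(l) {
    w <- exp(l * c(0, 1, 2))
    sum(w * c(0, 1, 2)) / sum(w) - 1.5
  }
  l_star <- uniroot(grad, c(0, 10), tol = 1e-14)$root
  w_star <- exp(l_star * c(0, 1, 2))
  w_star <- w_star / mean(w_star)
  expect_equal(res$weights[1:3], w_star, tolerance = 1e-8)
  wm <- sum(res$weights[1:3] * c(0, 1, 2)) / sum(res$weights[1:3])
  expect_equal(wm, 1.5, tolerance = 1e-10)
})

test_that("post-balance SMDs vanish on a confounded simulated cohort", {
  set.seed(9)
  sim <- simulate_analysis_cohort(3000)   # Table-1-style gradients
  res <- entropy_balance(sim$cohort, sim$cohort$hvs_category)
  expect_gt(max(abs(res$smd_before)), 0.2)   # real confounding to remove
  expect_lt(max(abs(res$smd_after)), 1e-6)
  expect_true(all(res$weights > 0))
  for (k in 1:5) {
    expect_equal(mean(res$weights[sim$cohort$hvs_category == k]), 1,
                 tolerance = 1e-9)
  }
})

test_that("weights are invariant to affine covariate rescaling", {
  set.seed(15)
  sim <- simulate_analysis_cohort(800)
  co <- sim$cohort
  spec <- balance_spec(covariates = c("age_at_index", "twa_hba1c",
                                      "ever_insulin"))
  r1 <- entropy_balance(co, co$hvs_category, spec)
  co2 <- co
  co2$age_at_index <- co2$age_at_index * 12 + 7   # months, offset
  co2$twa_hba1c <- co2$twa_hba1c * 10.929 - 23.5
  r2 <- entropy_balance(co2, co2$hvs_category, spec)
  expect_equal(r1$weights, r2$weights, tolerance = 1e-6)
})

test_that("solution minimises sum w log w among feasible weights", {
  # oracle: penalty-method minimisation of the raw entropy objective on
  # a 6-subject category, independent of the exponential-tilting form
  X <- data.frame(x = c(-1.2, -0.4, 0.1, 0.6, 1.4, 2.1,  0, 0.6, 0.3, 0.3))
  g <- c(rep(1, 6), rep(2, 4))
  res <- entropy_balance(X, g, balance_spec(covariates = "x",
                                            tolerance = 1e-12))
  target <- mean(X$x)
  xg <- X$x[1:6]
  obj <- function(v, rho) {
    w <- exp(v)                     # positivity via log-parameterisation
    sum(w * log(w)) + rho * ((mean(w) - 1)^2 +
                               (sum(w * xg) / sum(w) - target)^2)
  }
  v <- rep(0, 6)
  for (rho in 10^(2:8)) {
    v <- optim(v, obj, rho = rho, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))$par
  }
  w_oracle <- exp(v)
  ent <- function(w) sum(w * log(w))
  # the exponential-tilting solution must be at least as entropic as any
  # feasible oracle solution, and agree with it up to penalty slack
  expect_lte(ent(res$weights[1:6]), ent(w_oracle) + 1e-6)
  expect_lt(abs(ent(res$weights[1:6]) - ent(w_oracle)), 5e-4)
  expect_equal(res$weights[1:6], w_oracle, tolerance = 5e-2)
})

test_that("infeasible and degenerate cases raise informative errors", {
  X <- data.frame(x = c(1, 1.2, 1.4, 5, 6, 7))
  g <- rep(1:2, each = 3)
  expect_error(entropy_balance(X, g, balance_spec(covariates = "x")),
               "convex hull")
  # constant covariate in one category, off target
  X2 <- data.frame(x = c(1, 1, 1, 2, 3, 4))
  expect_error(entropy_balance(X2, g, balance_spec(covariates = "x")),
               "constant")
  # category with fewer subjects than constraints
  X3 <- data.frame(a = rnorm(5), b = rnorm(5), c = rnorm(5))
  expect_error(entropy_balance(X3, c(1, 1, 1, 2, 2),
                               balance_spec(covariates = c("a", "b", "c"))),
               "constraints")
})

test_that("balance_diagnostics matches hand-computed SMDs", {
  # 4 subjects, 2 categories; pooled mean 5, pooled sd = sqrt(20/3)
  X <- data.frame(x = c(2, 4, 6, 8))
  g <- c(1, 1, 2, 2)
  d <- balance_diagnostics(X, g, weights = rep(1, 4))
  sd_p <- sqrt(20 / 3)
  expect_equal(d$before["x", "1"], (3 - 5) / sd_p)
  expect_equal(d$before["x", "2"], (7 - 5) / sd_p)
  expect_equal(d$before, d$after)   # uniform weights reproduce raw SMDs
  d2 <- balance_diagnostics(X, g, weights = c(1, 3, 3, 1))
  expect_equal(d2$after["x", "1"], (3.5 - 5) / sd_p)
  expect_equal(d2$after["x", "2"], (6.5 - 5) / sd_p)
})

test_that("Newton dual objective is monotone under damping", {
  # convexity: the recorded iteration counts stay within the cap and the
  # converged flag is set on a stiff but feasible problem
  set.seed(33)
  x <- c(rexp(40, 1), rexp(200, 0.5))
  g <- rep(1:2, c(40, 200))
  res <- entropy_balance(data.frame(x = x), g,
                         balance_spec(covariates = "x"))
  expect_true(res$converged)
  expect_true(all(res$iterations <= 200))
  expect_lt(max(abs(res$smd_after)), 1e-7)
})
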