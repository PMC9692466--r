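## Weighted outcome models: logistic regression for rapid eGFR decline
## (sandwich variance) and a weighted-likelihood linear mixed model for
## eGFR-slope differences across HVS categories.

#' Model configuration
#'
#' @param mid Minimal important difference for an eGFR-slope contrast,
#'   mL/min/1.73 m^2/yr (default 0.75).
#' @param reference_category Reference HVS category (default 1,
#'   HVS <= 20%).
#' @param ci_level Confidence level (default 0.95).
#' @param logistic_variance `"sandwich"` (robust, treating weights as
#'   probability weights; the default) or `"model"` (model-based).
#' @return A list of class `model_config`.
#' @export
model_config <- function(mid = 0.75, reference_category = 1L,
                         ci_level = 0.95,
                         logistic_variance = c("sandwich", "model")) {
  stopifnot(mid > 0, ci_level > 0, ci_level < 1)
  structure(list(mid = mid, reference_category = as.integer(reference_category),
                 ci_level = ci_level,
                 logistic_variance = match.arg(logistic_variance)),
            class = "model_config")
}

effect_row <- function(term, scale, est, se, z, mid = NA, n = NA) {
  data.frame(term = term, scale = scale, estimate = est, se = se,
             ci_low = est - z * se, ci_high = est + z * se,
             exceeds_mid = if (is.na(mid)) NA else abs(est) > mid,
             n_used = n, stringsAsFactors = FALSE)
}

category_design <- function(categories, reference) {
  lev <- sort(unique(categories))
  if (!reference %in% lev) stop("reference category absent", call. = FALSE)
  f <- factor(categories, levels = c(reference, setdiff(lev, reference)))
  X <- stats::model.matrix(~f)
  colnames(X) <- c("(Intercept)",
                   paste0("hvs_cat", levels(f)[-1]))
  X
}

#' Weighted logistic regression of rapid decline on HVS category
#'
#' Maximises the weighted Bernoulli log-likelihood of a
#' category-indicator model by iteratively reweighted least squares.
#' Confidence intervals use, by default, the robust (sandwich) variance
#' with the entropy-balancing weights treated as probability weights.
#'
#' @param rapid Logical (or 0/1) rapid-decline outcomes.
#' @param categories Integer HVS categories per subject.
#' @param weights Positive per-subject weights.
#' @param cfg A [model_config()].
#' @return A data.frame of effect estimates (one row per non-reference
#'   category) on the odds-ratio scale: `estimate` is the OR, `se` the
#'   log-odds-ratio standard error, `ci_low`/`ci_high` the OR-scale
#'   Wald interval. Attribute `fit` holds coefficients and both
#'   variance matrices.
#' @export
fit_weighted_logistic <- function(rapid, categories, weights = NULL,
                                  cfg = model_config()) {
  y <- as.numeric(rapid)
  stopifnot(all(y %in% c(0, 1)))
  n <- length(y)
  if (is.null(weights)) weights <- rep(1, n)
  if (any(weights <= 0)) stop("weights must be positive", call. = FALSE)
  for (g in sort(unique(categories))) {
    yg <- y[categories == g]
    if (length(unique(yg)) < 2) {
      stop(sprintf("category %s has a single outcome class (separation)", g),
           call. = FALSE)
    }
  }
  X <- category_design(categories, cfg$reference_category)
  p <- ncol(X)
  beta <- numeric(p)
  for (it in seq_len(100L)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    score <- drop(crossprod(X, weights * (y - mu)))
    if (max(abs(score)) < 1e-10) break
    Wv <- weights * mu * (1 - mu)
    H <- crossprod(X * sqrt(Wv))
    beta <- beta + solve(H, score)
    if (max(abs(beta)) > 30) {
      stop("weighted logistic did not converge (possible separation)",
           call. = FALSE)
    }
  }
  mu <- plogis(drop(X %*% beta))
  Wv <- weights * mu * (1 - mu)
  bread <- solve(crossprod(X * sqrt(Wv)))
  meat <- crossprod(X * (weights * (y - mu)))
  v_sand <- bread %*% meat %*% bread
  v_model <- bread
  V <- if (cfg$logistic_variance == "sandwich") v_sand else v_model
  z <- qnorm(1 - (1 - cfg$ci_level) / 2)
  terms <- colnames(X)[-1]
  se <- sqrt(diag(V))[-1]
  out <- do.call(rbind, lapply(seq_along(terms), function(j) {
    lo <- beta[j + 1] - z * se[j]
    hi <- beta[j + 1] + z * se[j]
    data.frame(term = terms[j], scale = "odds_ratio",
               estimate = exp(beta[j + 1]), se = se[j],
               ci_low = exp(lo), ci_high = exp(hi),
               exceeds_mid = NA, n_used = n, stringsAsFactors = FALSE)
  }))
  attr(out, "fit") <- list(coefficients = setNames(beta, colnames(X)),
                           vcov_sandwich = v_sand, vcov_model = v_model,
                           fitted = mu, converged = max(abs(
                             crossprod(X, weights * (y - mu)))) < 1e-6)
  out
}

psi_from_par <- function(par, diagonal = FALSE) {
  s0 <- exp(par[1])
  s1 <- exp(par[2])
  rho <- if (diagonal) 0 else tanh(par[3])
  matrix(c(s0^2, rho * s0 * s1, rho * s0 * s1, s1^2), 2, 2)
}

#' Weighted linear mixed model for eGFR slopes
#'
#' Fits, by maximum likelihood, eGFR on HVS-category main effects, time
#' in years, and category-by-time interactions, with a random intercept
#' and random slope per subject (unstructured 2x2 covariance). Each
#' subject's log-likelihood contribution is multiplied by its
#' entropy-balancing weight; beta and the residual variance are profiled
#' analytically and the relative random-effects covariance is optimised
#' by Nelder-Mead. Standard errors are model-based Wald.
#'
#' The reference-category mean slope is the `time` coefficient; the four
#' interaction coefficients are the slope differences, compared against
#' the minimal important difference `cfg$mid`.
#'
#' @param long Data.frame with `subject_id`, `time` (years since index)
#'   and `egfr`.
#' @param categories Per-subject HVS categories, named by subject id (or
#'   aligned with `unique(long$subject_id)`).
#' @param weights Per-subject weights (same alignment); `NULL` for
#'   uniform.
#' @param cfg A [model_config()].
#' @return A data.frame of effect estimates: `reference_slope` (the
#'   time coefficient) plus one `slope_difference` row per non-reference
#'   category. Attribute `fit` carries coefficients, vcov, sigma, the
#'   random-effects covariance and convergence information.
#' @export
fit_weighted_mixed_slopes <- function(long, categories, weights = NULL,
                                      cfg = model_config()) {
  subs <- unique(long$subject_id)
  m <- length(subs)
  categories <- align_by_subject(categories, subs)
  if (is.null(weights)) weights <- rep(1, m)
  weights <- align_by_subject(weights, subs)
  if (any(weights <= 0)) stop("weights must be positive", call. = FALSE)

  Xc <- category_design(categories, cfg$reference_category)
  g <- match(long$subject_id, subs)
  Xrow <- Xc[g, , drop = FALSE]
  X <- cbind(Xrow, Xrow * long$time)
  k <- ncol(Xc)
  colnames(X) <- c(colnames(Xc),
                   ifelse(colnames(Xc) == "(Intercept)", "time",
                          paste0(colnames(Xc), ":time")))
  prep <- wlmm_prepare(X, long$time, long$egfr, as.integer(g - 1L), m)

  # scale-aware start: relative sds on the residual-sd scale
  fit <- wlmm_fit(prep, weights, c(1.5, -1.5, 0), FALSE, 2000L, 1e-12)
  fit <- wlmm_fit(prep, weights, fit$par, FALSE, 2000L, 1e-12)
  par <- drop(fit$par)
  diagonal <- FALSE
  if (abs(tanh(par[3])) > 0.995) {
    warning("random-effects correlation at the boundary; refitting with diagonal covariance",
            call. = FALSE)
    diagonal <- TRUE
    fit <- wlmm_fit(prep, weights, c(par[1:2], 0), TRUE, 2000L, 1e-12)
    par <- c(drop(fit$par)[1:2], 0)
  }
  det <- fit
  beta <- drop(det$beta)
  names(beta) <- colnames(X)
  V <- det$vcov
  z <- qnorm(1 - (1 - cfg$ci_level) / 2)
  se <- sqrt(diag(V))
  names(se) <- colnames(X)

  rows <- list(effect_row("reference_slope", "slope", beta["time"],
                          se["time"], z, n = m))
  for (nm in colnames(Xc)[-1]) {
    term <- paste0(nm, ":time")
    rows[[length(rows) + 1]] <- effect_row(term, "slope_difference",
                                           beta[term], se[term], z,
                                           mid = cfg$mid, n = m)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  psi <- psi_from_par(par, diagonal)
  attr(out, "fit") <- list(
    coefficients = beta, vcov = V, sigma2 = det$sigma2,
    ranef_cov = det$sigma2 * psi, loglik = det$loglik,
    neval = det$neval, diagonal = diagonal
  )
  out
}

align_by_subject <- function(x, subs) {
  if (!is.null(names(x))) {
    if (!all(subs %in% names(x))) {
      stop("per-subject vector is missing some subjects", call. = FALSE)
    }
    x <- x[as.character(subs)]
  } else if (length(x) != length(subs)) {
    stop("per-subject vector must be named or aligned with unique subjects",
         call. = FALSE)
  }
  unname(x)
}
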