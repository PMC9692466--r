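## Entropy balancing: per-category exponential-tilting weights that match
## covariate first moments to a common target, solved in the convex dual
## by damped Newton iterations.

#' Balance specification
#'
#' @param covariates Ordered character vector of cohort columns to
#'   balance. The default is the nine-covariate set used throughout:
#'   age, sex, baseline eGFR <60 flag, hypertension-or-ASCVD flag, ever
#'   insulin/statin/ARB-ACEI, time-weighted average HbA1c, adherence.
#' @param moment_order Moment order (1 = means, the default; 2 adds
#'   second raw moments of continuous covariates).
#' @param target `"pooled"` (balance every category to the full-sample
#'   unweighted moments; the default) or `"reference"` (to category 1's
#'   moments).
#' @param tolerance Convergence tolerance on the maximum standardized
#'   moment violation.
#' @param max_iter Maximum Newton iterations per category.
#' @return A list of class `balance_spec`.
#' @export
balance_spec <- function(covariates = c("age_at_index", "female",
                                        "baseline_egfr_lt60", "htn_or_ascvd",
                                        "ever_insulin", "ever_statin",
                                        "ever_arb_acei", "twa_hba1c",
                                        "adherence"),
                         moment_order = 1L, target = c("pooled", "reference"),
                         tolerance = 1e-8, max_iter = 200L) {
  if (length(covariates) == 0) stop("covariates must be nonempty",
                                    call. = FALSE)
  stopifnot(tolerance > 0, max_iter >= 1, moment_order %in% c(1L, 2L))
  structure(list(covariates = covariates, moment_order = moment_order,
                 target = match.arg(target), tolerance = tolerance,
                 max_iter = max_iter),
            class = "balance_spec")
}

moment_matrix <- function(X, order) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (order == 2L) {
    binary <- apply(X, 2, function(v) all(v %in% c(0, 1)))
    X2 <- X[, !binary, drop = FALSE]^2
    if (ncol(X2)) {
      colnames(X2) <- paste0(colnames(X)[!binary], "^2")
      X <- cbind(X, X2)
    }
  }
  X
}

#' Entropy-balancing weights
#'
#' For each category g, finds weights `w_i` proportional to
#' `exp(lambda_g . c(x_i))`, normalised to mean 1 within g, such that the
#' weighted covariate moments in g equal the target moments exactly (to
#' `tolerance`). These are the minimum-KL-divergence (maximum-entropy)
#' weights subject to the moment constraints; the dual is convex and is
#' solved per category by damped Newton with step halving. Covariates are
#' standardized internally (pooled mean/SD), which makes the weights
#' invariant to affine rescaling of any covariate.
#'
#' @param covariate_data A data.frame or matrix containing the columns
#'   named in `spec$covariates` (logicals are coerced to 0/1).
#' @param categories Integer category labels (1-5, or any small set).
#' @param spec A [balance_spec()].
#' @return A list of class `balance_result`: `weights` (per subject,
#'   mean 1 within category), `lambdas` (dual coefficients per category,
#'   standardized scale), `smd_before`, `smd_after` (covariate-by-category
#'   matrices), `converged`, `iterations`.
#' @export
entropy_balance <- function(covariate_data, categories,
                            spec = balance_spec()) {
  X0 <- covariate_data
  if (is.data.frame(X0)) {
    miss <- setdiff(spec$covariates, names(X0))
    if (length(miss)) stop("missing balance covariates: ",
                           paste(miss, collapse = ", "), call. = FALSE)
    X0 <- sapply(X0[spec$covariates], as.numeric)
  }
  X0 <- moment_matrix(X0, spec$moment_order)
  n <- nrow(X0)
  stopifnot(length(categories) == n)
  if (any(!is.finite(X0))) stop("covariates must be finite", call. = FALSE)

  cats <- sort(unique(categories))
  target_rows <- if (spec$target == "pooled") seq_len(n) else
    which(categories == cats[1])
  mu <- colMeans(X0[target_rows, , drop = FALSE])
  sdev <- apply(X0, 2, sd)
  if (any(sdev == 0)) {
    # a covariate constant in the whole sample carries no constraint
    keep <- sdev > 0
    X0 <- X0[, keep, drop = FALSE]
    mu <- mu[keep]
    sdev <- sdev[keep]
  }
  Xs <- sweep(sweep(X0, 2, mu), 2, sdev, "/")  # target moments become 0

  weights <- rep(1, n)
  lambdas <- list()
  iters <- integer(0)
  for (g in cats) {
    ix <- which(categories == g)
    if (length(ix) <= ncol(Xs)) {
      stop(sprintf("category %s has %d subjects for %d constraints",
                   g, length(ix), ncol(Xs)), call. = FALSE)
    }
    Xg <- Xs[ix, , drop = FALSE]
    # feasibility: target (0 on the standardized scale) must lie in the
    # convex hull of each covariate's values within the category
    lo <- apply(Xg, 2, min)
    hi <- apply(Xg, 2, max)
    infeas <- which(lo > 1e-12 | hi < -1e-12)
    const <- which(lo == hi)
    if (length(const)) {
      bad <- const[abs(Xg[1, const]) > spec$tolerance]
      if (length(bad)) {
        stop(sprintf("infeasible: covariate '%s' is constant in category %s but off target",
                     colnames(Xs)[bad[1]], g), call. = FALSE)
      }
    }
    infeas <- setdiff(infeas, const)
    if (length(infeas)) {
      stop(sprintf("infeasible: target mean of '%s' outside the convex hull of category %s",
                   colnames(Xs)[infeas[1]], g), call. = FALSE)
    }
    active <- setdiff(seq_len(ncol(Xs)), const)
    sol <- eb_newton(Xg[, active, drop = FALSE], spec$tolerance,
                     spec$max_iter)
    if (!sol$converged) {
      stop(sprintf("entropy balancing did not converge for category %s (gradient norm %.3g)",
                   g, sol$grad_norm), call. = FALSE)
    }
    lam <- numeric(ncol(Xs))
    lam[active] <- sol$lambda
    names(lam) <- colnames(Xs)
    lambdas[[as.character(g)]] <- lam
    weights[ix] <- sol$w
    iters <- c(iters, sol$iterations)
  }

  diag_tab <- balance_diagnostics(X0, categories, weights, mu = mu,
                                  sdev = sdev)
  structure(list(weights = weights, lambdas = lambdas,
                 smd_before = diag_tab$before, smd_after = diag_tab$after,
                 converged = TRUE, iterations = iters,
                 covariate_names = colnames(Xs), target_means = mu),
            class = "balance_result")
}

# damped Newton on the dual f(lambda) = log mean exp(lambda' x) with
# target 0; returns mean-1 weights
eb_newton <- function(X, tol, max_iter) {
  p <- ncol(X)
  lambda <- numeric(p)
  eta <- drop(X %*% lambda)
  f <- function(eta) {
    m <- max(eta)
    m + log(mean(exp(eta - m)))
  }
  fval <- f(eta)
  for (it in seq_len(max_iter)) {
    u <- exp(eta - max(eta))
    pr <- u / sum(u)
    grad <- drop(crossprod(X, pr))
    if (max(abs(grad)) < tol) {
      w <- pr * length(pr)
      return(list(lambda = lambda, w = w, converged = TRUE,
                  iterations = it, grad_norm = max(abs(grad))))
    }
    Xc <- sweep(X, 2, grad)
    H <- crossprod(Xc * sqrt(pr)) + diag(1e-12, p)
    step <- tryCatch(solve(H, grad), error = function(e) grad)
    # step halving keeps the convex dual monotone non-increasing
    alpha <- 1
    repeat {
      lam_new <- lambda - alpha * step
      eta_new <- drop(X %*% lam_new)
      f_new <- f(eta_new)
      if (f_new <= fval + 1e-14 || alpha < 1e-10) break
      alpha <- alpha / 2
    }
    lambda <- lam_new
    eta <- eta_new
    fval <- f_new
  }
  u <- exp(eta - max(eta))
  pr <- u / sum(u)
  grad <- drop(crossprod(X, pr))
  list(lambda = lambda, w = pr * length(pr),
       converged = max(abs(grad)) < tol, iterations = max_iter,
       grad_norm = max(abs(grad)))
}

#' Standardized-mean-difference balance diagnostics
#'
#' Per covariate and category: (weighted category mean - target mean) /
#' pooled SD, before (uniform weights) and after weighting. A covariate
#' with zero pooled SD reports 0 when the means agree and errors
#' otherwise.
#'
#' @param covariate_data Covariate data.frame/matrix (see
#'   [entropy_balance()]).
#' @param categories Category labels.
#' @param weights Per-subject weights.
#' @param covariates Columns to report when `covariate_data` is a
#'   data.frame.
#' @param mu,sdev Optional target means / pooled SDs (computed from the
#'   pooled sample when omitted).
#' @return A list with matrices `before` and `after`
#'   (covariate x category).
#' @export
balance_diagnostics <- function(covariate_data, categories, weights,
                                covariates = NULL, mu = NULL, sdev = NULL) {
  X <- covariate_data
  if (is.data.frame(X)) {
    if (is.null(covariates)) covariates <- names(X)
    X <- sapply(X[covariates], as.numeric)
  }
  X <- as.matrix(X)
  if (any(weights <= 0)) stop("weights must be positive", call. = FALSE)
  if (is.null(mu)) mu <- colMeans(X)
  if (is.null(sdev)) sdev <- apply(X, 2, sd)
  zero_sd <- sdev == 0
  cats <- sort(unique(categories))
  smd <- function(w) {
    out <- vapply(cats, function(g) {
      ix <- categories == g
      wm <- colSums(X[ix, , drop = FALSE] * w[ix]) / sum(w[ix])
      d <- wm - mu
      if (any(zero_sd & abs(d) > 1e-12)) {
        stop("zero pooled SD with unequal means for covariate ",
             colnames(X)[which(zero_sd & abs(d) > 1e-12)[1]], call. = FALSE)
      }
      ifelse(zero_sd, 0, d / ifelse(sdev == 0, 1, sdev))
    }, numeric(ncol(X)))
    out <- matrix(out, nrow = ncol(X))
    colnames(out) <- as.character(cats)
    rownames(out) <- colnames(X)
    out
  }
  list(before = smd(rep(1, length(weights))), after = smd(weights))
}
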