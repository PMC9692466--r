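## Subgroup and sensitivity suites: refit both primary models under the
## prespecified strata and robustness scenarios.

fit_both <- function(cohort, long, bspec, cfg) {
  bal <- entropy_balance(cohort, cohort$hvs_category, bspec)
  w <- setNames(bal$weights, cohort$subject_id)
  lg <- fit_weighted_logistic(cohort$rapid_decliner, cohort$hvs_category,
                              bal$weights, cfg)
  long <- long[long$subject_id %in% cohort$subject_id, , drop = FALSE]
  mx <- fit_weighted_mixed_slopes(
    long, setNames(cohort$hvs_category, cohort$subject_id), w, cfg)
  rbind(lg[, names(mx)], mx)
}

#' Subgroup analyses
#'
#' Refits both primary models within each stratum of the four
#' prespecified subgroups: sex, age at index (<60 vs >=60), ever use of
#' insulin, and baseline eGFR (<60 vs >=60). Balancing weights are
#' re-estimated within each stratum; the stratifying covariate drops out
#' of the balance constraints automatically (zero variance in-stratum).
#'
#' @param cohort A cohort data.frame from [build_cohort()] (or the
#'   subject-level simulator), with `rapid_decliner` and `hvs_category`.
#' @param long Long eGFR table (`subject_id`, `time`, `egfr`).
#' @param bspec A [balance_spec()].
#' @param cfg A [model_config()].
#' @param min_stratum Minimum stratum size; smaller strata are skipped
#'   with a logged reason.
#' @return A data.frame of effect estimates keyed by `subgroup` and
#'   `stratum`; attribute `skipped` logs strata not analysed.
#' @export
subgroup_suite <- function(cohort, long, bspec = balance_spec(),
                           cfg = model_config(), min_stratum = 100L) {
  defs <- list(
    sex = list(var = "female", strata = c(female = TRUE, male = FALSE)),
    age = list(var = "age_at_index",
               strata = c(`age<60` = TRUE, `age>=60` = FALSE),
               split = function(x) x < 60),
    insulin = list(var = "ever_insulin",
                   strata = c(insulin = TRUE, no_insulin = FALSE)),
    baseline_egfr = list(var = "baseline_egfr_lt60",
                         strata = c(`egfr<60` = TRUE, `egfr>=60` = FALSE))
  )
  out <- list()
  skipped <- list()
  for (sg in names(defs)) {
    d <- defs[[sg]]
    x <- cohort[[d$var]]
    if (!is.null(d$split)) x <- d$split(x)
    for (st in names(d$strata)) {
      ix <- x == d$strata[[st]]
      sub <- cohort[ix, , drop = FALSE]
      if (sum(ix) < min_stratum) {
        skipped[[paste(sg, st, sep = ":")]] <- sprintf(
          "stratum size %d below minimum %d", sum(ix), min_stratum)
        next
      }
      res <- tryCatch(fit_both(sub, long, bspec, cfg),
                      error = function(e) conditionMessage(e))
      if (is.character(res)) {
        skipped[[paste(sg, st, sep = ":")]] <- res
        next
      }
      res$subgroup <- sg
      res$stratum <- st
      out[[paste(sg, st, sep = ":")]] <- res
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "skipped") <- skipped
  res
}

#' Sensitivity analyses
#'
#' Re-runs derivation, balancing and both primary models under the
#' prespecified robustness scenarios:
#' \describe{
#'   \item{`windowed_2y` ... `windowed_5y`}{per-subject slopes and the
#'     mixed model restricted to the first 2/3/4/5 years of follow-up;
#'     subjects with fewer than three in-window eGFR measures are
#'     dropped from that scenario with a logged count. Balancing weights
#'     are carried over from the full cohort (the balance covariates are
#'     unchanged).}
#'   \item{`unparallel_90d`}{excludes subjects whose last HbA1c and last
#'     creatinine measurements are 90 or more days apart.}
#'   \item{`baseline_hba1c_weights`}{replaces time-weighted average
#'     HbA1c with baseline HbA1c in the balance constraints.}
#'   \item{`egfr_ge30`}{excludes subjects with baseline eGFR < 30.}
#'   \item{`no_sglt2i_glp1ra`}{excludes subjects ever prescribed SGLT2
#'     inhibitors or GLP-1 receptor agonists.}
#' }
#' Exclusion scenarios re-estimate balancing weights on the remaining
#' subjects. A scenario that empties an HVS category is marked
#' infeasible rather than fatal.
#'
#' @param cohort Cohort from [build_cohort()] (needs the `egfr_long`
#'   attribute, or pass `long`).
#' @param long Long eGFR table; defaults to `attr(cohort, "egfr_long")`.
#' @param bspec A [balance_spec()].
#' @param cfg A [model_config()].
#' @param scenarios Character vector selecting scenarios (default all).
#' @return A data.frame of effect estimates keyed by `scenario`;
#'   attribute `log` records per-scenario drop counts and infeasible
#'   scenarios.
#' @export
sensitivity_suite <- function(cohort, long = attr(cohort, "egfr_long"),
                              bspec = balance_spec(), cfg = model_config(),
                              scenarios = c("windowed_2y", "windowed_3y",
                                            "windowed_4y", "windowed_5y",
                                            "unparallel_90d",
                                            "baseline_hba1c_weights",
                                            "egfr_ge30",
                                            "no_sglt2i_glp1ra")) {
  stopifnot(!is.null(long))
  out <- list()
  log <- list()
  bal_full <- entropy_balance(cohort, cohort$hvs_category, bspec)
  w_full <- setNames(bal_full$weights, cohort$subject_id)

  run_subset <- function(name, keep, spec = bspec) {
    sub <- cohort[keep, , drop = FALSE]
    if (length(unique(sub$hvs_category)) <
        length(unique(cohort$hvs_category))) {
      log[[name]] <<- "infeasible: scenario empties an HVS category"
      return(NULL)
    }
    res <- tryCatch(fit_both(sub, long, spec, cfg),
                    error = function(e) conditionMessage(e))
    if (is.character(res)) {
      log[[name]] <<- paste("infeasible:", res)
      return(NULL)
    }
    log[[name]] <<- sprintf("dropped %d of %d subjects",
                            sum(!keep), nrow(cohort))
    res$scenario <- name
    res
  }

  for (sc in scenarios) {
    if (grepl("^windowed_", sc)) {
      win <- as.numeric(sub("windowed_([0-9]+)y", "\\1", sc))
      sl <- long[long$time <= win + 1e-12, , drop = FALSE]
      cnt <- table(factor(sl$subject_id, cohort$subject_id))
      ok <- cohort$subject_id[cnt >= 3]
      keep <- cohort$subject_id %in% ok
      if (length(unique(cohort$hvs_category[keep])) <
          length(unique(cohort$hvs_category))) {
        log[[sc]] <- "infeasible: scenario empties an HVS category"
        next
      }
      sub <- cohort[keep, , drop = FALSE]
      sl <- sl[sl$subject_id %in% ok, , drop = FALSE]
      # windowed per-subject slope and rapid flag
      spl <- split(seq_len(nrow(sl)), factor(sl$subject_id, ok))
      wslope <- vapply(spl, function(ix) {
        egfr_slope(sl$time[ix], sl$egfr[ix])$slope
      }, numeric(1))
      sub$mean_slope <- wslope[sub$subject_id]
      sub$rapid_decliner <- rapid_decline(sub$mean_slope)
      lg <- fit_weighted_logistic(sub$rapid_decliner, sub$hvs_category,
                                  unname(w_full[sub$subject_id]), cfg)
      mx <- fit_weighted_mixed_slopes(
        sl, setNames(sub$hvs_category, sub$subject_id),
        w_full[sub$subject_id], cfg)
      res <- rbind(lg[, names(mx)], mx)
      res$scenario <- sc
      out[[sc]] <- res
      log[[sc]] <- sprintf("dropped %d of %d subjects (fewer than 3 eGFR measures within %g years)",
                           sum(!keep), nrow(cohort), win)
    } else if (sc == "unparallel_90d") {
      out[[sc]] <- run_subset(sc, cohort$last_measure_gap_days < 90)
    } else if (sc == "baseline_hba1c_weights") {
      spec2 <- bspec
      spec2$covariates[spec2$covariates == "twa_hba1c"] <- "baseline_hba1c"
      out[[sc]] <- run_subset(sc, !is.na(cohort$baseline_hba1c), spec2)
    } else if (sc == "egfr_ge30") {
      out[[sc]] <- run_subset(sc, cohort$baseline_egfr >= 30)
    } else if (sc == "no_sglt2i_glp1ra") {
      out[[sc]] <- run_subset(sc, !cohort$ever_sglt2i_glp1ra)
    } else {
      stop("unknown scenario: ", sc, call. = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "log") <- log
  res
}
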