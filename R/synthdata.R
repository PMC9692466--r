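## Synthetic EMR generator: emits the five raw tables (subjects, visits,
## labs, meds, diagnoses) with known ground truth so every downstream stage
## is testable without access to the real database.

#' Simulation configuration
#'
#' Builds and validates the full specification of the synthetic cohort's
#' generative process. Defaults encode the published cohort's marginals:
#' category occupancy 506/585/661/444/201 of 2397, median follow-up 4.7
#' years (IQR 3.1-6.3, reproduced exactly by Uniform(1.5, 7.9)), median
#' 1.9 visits/year (IQR 1.3-2.7 via per-subject lognormal rates), Table-1
#' covariate gradients (e.g. insulin use rising 20.6% to 55.2% across
#' categories), and per-category true eGFR slopes of
#' (-0.33, -0.58, -0.83, -1.26, -2.16) mL/min/1.73 m^2/yr.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param follow_up_years Median follow-up in years.
#' @param follow_up_spread Half-width of the uniform follow-up
#'   distribution; follow-up is Uniform(median - spread, median + spread).
#' @param visit_rate Median outpatient visits per year (Poisson-process
#'   gaps; first visit is the index visit and always has an HbA1c).
#' @param visit_rate_logsd Log-SD of per-subject visit-rate heterogeneity
#'   (0.542 matches the published IQR 1.3-2.7 around median 1.9).
#' @param category_probs Marginal probabilities of the five HVS bands
#'   (sum to 1).
#' @param jump_prob_by_category Per-pair probability that |dHbA1c| >= 0.5%
#'   for subjects in each latent band (band midpoints by default).
#' @param hba1c_level_mean_by_category Mean HbA1c level (%) per band.
#' @param hba1c_level_sd_by_category Between-subject SD of the personal
#'   HbA1c level within each band (defaults follow the published
#'   per-category time-weighted-average IQRs, 0.4% in the reference band
#'   up to 1.3% in the top band; this heterogeneity is what keeps exact
#'   moment balance of average HbA1c feasible).
#' @param true_slope_by_category True mean eGFR slope per band,
#'   mL/min/1.73 m^2/yr (signed).
#' @param true_slope_sd Between-subject SD of the true slope around the
#'   band mean (real cohorts show wide slope heterogeneity; a nonzero
#'   value also produces a realistic share of rapid decliners).
#' @param baseline_egfr_mean,baseline_egfr_sd Baseline eGFR distribution
#'   (truncated to 20-140 mL/min/1.73 m^2).
#' @param egfr_noise_sd Measurement noise SD on the latent eGFR scale.
#' @param covariate_prevalence Named list of binary covariates mapping to
#'   5 per-category prevalences (hypertension, ascvd, insulin, statin,
#'   arb_acei, ccb, sglt2i_glp1ra).
#' @param age_mean_by_category,age_sd Age-at-index distribution (years,
#'   truncated to 20-90).
#' @param female_frac_by_category Proportion female per band.
#' @param p_miss_hba1c,p_miss_scr Probability a non-index visit lacks the
#'   HbA1c / creatinine measurement.
#' @param p_unparallel Probability a subject's creatinine measurements stop
#'   >= 120 days before the last visit (exercises the >= 90-day
#'   unparallel-measures sensitivity exclusion).
#' @param scr_unit Unit the labs table reports creatinine in
#'   (`"umol/L"`, the Chinese lab convention, or `"mg/dL"`).
#' @param index_date_range Character vector of two ISO dates bounding the
#'   index-date draw.
#' @param seed Integer seed; identical configs give byte-identical tables.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 2397,
                       follow_up_years = 4.7,
                       follow_up_spread = 3.2,
                       visit_rate = 1.9,
                       visit_rate_logsd = 0.542,
                       category_probs = c(506, 585, 661, 444, 201) / 2397,
                       jump_prob_by_category = c(0.10, 0.30, 0.50, 0.70, 0.90),
                       hba1c_level_mean_by_category = c(6.8, 7.1, 7.4, 7.8, 8.6),
                       hba1c_level_sd_by_category = c(0.4, 0.5, 0.8, 1.0, 1.3),
                       true_slope_by_category = c(-0.33, -0.58, -0.83, -1.26, -2.16),
                       true_slope_sd = 1.5,
                       baseline_egfr_mean = 90,
                       baseline_egfr_sd = 24,
                       egfr_noise_sd = 4,
                       covariate_prevalence = list(
                         hypertension  = c(0.686, 0.759, 0.691, 0.658, 0.602),
                         ascvd         = c(0.435, 0.463, 0.380, 0.347, 0.289),
                         insulin       = c(0.206, 0.354, 0.461, 0.536, 0.552),
                         statin        = c(0.646, 0.697, 0.667, 0.694, 0.697),
                         arb_acei      = c(0.421, 0.468, 0.446, 0.385, 0.428),
                         ccb           = c(0.342, 0.364, 0.357, 0.306, 0.289),
                         sglt2i_glp1ra = c(0.05, 0.05, 0.05, 0.05, 0.05)
                       ),
                       age_mean_by_category = c(60.3, 61.2, 57.5, 54.9, 53.4),
                       age_sd = 12,
                       female_frac_by_category = c(0.468, 0.407, 0.384, 0.396, 0.368),
                       p_miss_hba1c = 0.1,
                       p_miss_scr = 0.1,
                       p_unparallel = 0.1,
                       scr_unit = "umol/L",
                       index_date_range = c("2011-01-01", "2014-06-30"),
                       seed = 20221111L) {
  cfg <- list(
    n_subjects = n_subjects, follow_up_years = follow_up_years,
    follow_up_spread = follow_up_spread, visit_rate = visit_rate,
    visit_rate_logsd = visit_rate_logsd, category_probs = category_probs,
    jump_prob_by_category = jump_prob_by_category,
    hba1c_level_mean_by_category = hba1c_level_mean_by_category,
    hba1c_level_sd_by_category = hba1c_level_sd_by_category,
    true_slope_by_category = true_slope_by_category,
    true_slope_sd = true_slope_sd,
    baseline_egfr_mean = baseline_egfr_mean,
    baseline_egfr_sd = baseline_egfr_sd, egfr_noise_sd = egfr_noise_sd,
    covariate_prevalence = covariate_prevalence,
    age_mean_by_category = age_mean_by_category, age_sd = age_sd,
    female_frac_by_category = female_frac_by_category,
    p_miss_hba1c = p_miss_hba1c, p_miss_scr = p_miss_scr,
    p_unparallel = p_unparallel, scr_unit = scr_unit,
    index_date_range = index_date_range, seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' Errors name the offending field.
#' @param cfg A `sim_config`.
#' @return `cfg`, invisibly, if valid.
#' @export
validate_sim_config <- function(cfg) {
  fail <- function(field, why) {
    stop(sprintf("invalid sim_config: field '%s' %s", field, why),
         call. = FALSE)
  }
  if (!is.numeric(cfg$n_subjects) || cfg$n_subjects < 1 ||
      cfg$n_subjects != round(cfg$n_subjects)) {
    fail("n_subjects", "must be an integer >= 1")
  }
  if (cfg$follow_up_years <= 0) fail("follow_up_years", "must be > 0")
  if (cfg$follow_up_spread < 0 ||
      cfg$follow_up_spread >= cfg$follow_up_years) {
    fail("follow_up_spread", "must be in [0, follow_up_years)")
  }
  if (cfg$visit_rate <= 0) fail("visit_rate", "must be > 0")
  if (cfg$visit_rate_logsd < 0) fail("visit_rate_logsd", "must be >= 0")
  p <- cfg$category_probs
  if (length(p) != 5 || any(p < 0) || any(p > 1)) {
    fail("category_probs", "must be 5 probabilities in [0,1]")
  }
  if (abs(sum(p) - 1) > 1e-12) fail("category_probs", "must sum to 1")
  jp <- cfg$jump_prob_by_category
  if (length(jp) != 5 || any(jp < 0 | jp > 1)) {
    fail("jump_prob_by_category", "must be 5 probabilities in [0,1]")
  }
  for (f in c("hba1c_level_mean_by_category", "true_slope_by_category",
              "age_mean_by_category", "female_frac_by_category")) {
    if (length(cfg[[f]]) != 5 || any(!is.finite(cfg[[f]]))) {
      fail(f, "must be 5 finite values")
    }
  }
  if (any(cfg$female_frac_by_category < 0 | cfg$female_frac_by_category > 1)) {
    fail("female_frac_by_category", "must lie in [0,1]")
  }
  for (f in c("baseline_egfr_sd", "egfr_noise_sd", "age_sd",
              "true_slope_sd")) {
    if (cfg[[f]] < 0) fail(f, "must be >= 0")
  }
  if (length(cfg$hba1c_level_sd_by_category) != 5 ||
      any(cfg$hba1c_level_sd_by_category < 0)) {
    fail("hba1c_level_sd_by_category", "must be 5 values >= 0")
  }
  if (cfg$baseline_egfr_mean <= 0) fail("baseline_egfr_mean", "must be > 0")
  for (f in c("p_miss_hba1c", "p_miss_scr", "p_unparallel")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) fail(f, "must be a probability")
  }
  for (nm in names(cfg$covariate_prevalence)) {
    pv <- cfg$covariate_prevalence[[nm]]
    if (length(pv) != 5 || any(pv < 0 | pv > 1)) {
      fail(paste0("covariate_prevalence$", nm),
           "must be 5 probabilities in [0,1]")
    }
  }
  if (!cfg$scr_unit %in% c("umol/L", "mg/dL")) {
    fail("scr_unit", "must be 'umol/L' or 'mg/dL'")
  }
  invisible(cfg)
}

#' Simulate one HbA1c series
#'
#' At each successive pair the absolute change is, with probability
#' `jump_prob`, drawn at or above the 0.5% threshold (0.5 + half-normal,
#' sigma 0.4), otherwise uniform on `[0, 0.5)`. The direction
#' mean-reverts toward `level_mean` and values are kept inside 4-15%.
#' The expected HVS of the series is `100 * jump_prob`.
#'
#' @param level_mean Long-run HbA1c level in %.
#' @param jump_prob Per-pair probability of a change >= 0.5%.
#' @param n_visits Number of measurements (>= 2).
#' @param times Optional measurement times in years (defaults to
#'   half-yearly); length `n_visits`.
#' @return A data.frame with `time` and `value` (HbA1c %).
#' @export
simulate_hba1c_series <- function(level_mean, jump_prob, n_visits,
                                  times = (seq_len(n_visits) - 1) / 2) {
  if (n_visits < 2) {
    stop("n_visits must be >= 2 (HVS undefined otherwise)", call. = FALSE)
  }
  stopifnot(jump_prob >= 0, jump_prob <= 1, length(times) == n_visits)
  jumps <- runif(n_visits - 1) < jump_prob
  data.frame(time = times,
             value = hba1c_values_from_jumps(level_mean, jumps))
}

# realise HbA1c values for a given at/above-threshold indicator vector;
# |diff(values)| >= 0.5 exactly where jumps is TRUE
hba1c_values_from_jumps <- function(level_mean, jumps) {
  n <- length(jumps) + 1L
  v <- numeric(n)
  v[1] <- min(max(level_mean + rnorm(1, 0, 0.4), 4.2), 14.5)
  mag <- ifelse(jumps, 0.5 + abs(rnorm(n - 1, 0, 0.4)),
                runif(n - 1, 0, 0.5 - 1e-6))
  pd <- runif(n - 1)
  for (i in 2:n) {
    # mean-reverting direction, reflected at the 4-15% range bounds
    s <- if (pd[i - 1] < pnorm((v[i - 1] - level_mean) / 0.8)) -1 else 1
    if (v[i - 1] + s * mag[i - 1] > 15 || v[i - 1] + s * mag[i - 1] < 4) s <- -s
    v[i] <- v[i - 1] + s * mag[i - 1]
  }
  v
}

#' Simulate one creatinine series from a known eGFR trajectory
#'
#' The latent trajectory is `baseline_egfr + true_slope * t` plus Gaussian
#' noise, floored above 1 mL/min/1.73 m^2 (a warning names the subject if
#' the floor binds), then mapped to serum creatinine by inverting the
#' CKD-EPI equation at the attained age (`age + t`).
#'
#' @param baseline_egfr Baseline eGFR (> 0).
#' @param true_slope True slope, mL/min/1.73 m^2/yr.
#' @param times Measurement times in years since index, non-decreasing.
#' @param noise_sd Gaussian noise SD on the eGFR scale.
#' @param age Age at index in years.
#' @param sex `"F"` or `"M"`.
#' @param id Optional subject id used in the floor warning.
#' @return A data.frame with `time` and `creatinine` (mg/dL).
#' @export
simulate_creatinine_series <- function(baseline_egfr, true_slope, times,
                                       noise_sd, age, sex, id = NULL) {
  stopifnot(baseline_egfr > 0, !is.unsorted(times), noise_sd >= 0)
  g <- baseline_egfr + true_slope * times + rnorm(length(times), 0, noise_sd)
  if (any(g < 1)) {
    warning(sprintf("eGFR trajectory floored at 1 for subject %s",
                    if (is.null(id)) "<unknown>" else id), call. = FALSE)
    g <- pmax(g, 1)
  }
  data.frame(time = times,
             creatinine = creatinine_for_egfr(g, age + times, sex))
}

# right-skewed personal HbA1c level: mean `m`, SD `s`, gamma-shaped
# (skewness 2/sqrt(shape)); diabetic HbA1c distributions have a long
# right tail, which keeps the pooled balance target inside every
# category's support
rskew_level <- function(n, m, s, shape = 2) {
  pmin(pmax(m + s * (rgamma(n, shape) - shape) / sqrt(shape), 4.5), 14)
}

rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  x <- rnorm(n, mean, sd)
  bad <- x < lo | x > hi
  while (any(bad)) {
    x[bad] <- rnorm(sum(bad), mean, sd)
    bad <- x < lo | x > hi
  }
  x
}

#' Simulate the five raw EMR tables
#'
#' Each subject gets a latent HVS band drawn from `category_probs`; the
#' Bernoulli HbA1c series is redrawn (up to 1000 tries) until its realised
#' HVS falls in the assigned band, so realised band occupancy matches the
#' configured marginals exactly and planted per-band truths are
#' recoverable downstream. Creatinine series are induced from the band's
#' true eGFR slope; binary covariates follow per-band prevalences.
#'
#' @param config A [sim_config()].
#' @return A list of class `raw_tables` with data.frames `subjects`,
#'   `visits`, `labs`, `meds`, `diagnoses`, and attribute `truth` (per
#'   subject: latent band, realised band, true slope, baseline eGFR).
#' @export
simulate_cohort <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_subjects
  prev <- config$covariate_prevalence

  fu <- runif(n, config$follow_up_years - config$follow_up_spread,
              config$follow_up_years + config$follow_up_spread)
  rate <- rlnorm(n, log(config$visit_rate), config$visit_rate_logsd)
  band <- sample.int(5L, n, replace = TRUE, prob = config$category_probs)
  age <- rtruncnorm1(n, config$age_mean_by_category[band], config$age_sd, 20, 90)
  age <- round(age * 365.25) / 365.25  # quantize to whole birth-date days
  sex <- ifelse(runif(n) < config$female_frac_by_category[band], "F", "M")
  b_egfr <- rtruncnorm1(n, config$baseline_egfr_mean, config$baseline_egfr_sd,
                        20, 140)
  hb_level <- rskew_level(n, config$hba1c_level_mean_by_category[band],
                          config$hba1c_level_sd_by_category[band])
  slope_i <- config$true_slope_by_category[band] +
    rnorm(n, 0, config$true_slope_sd)
  index_date <- as.Date(config$index_date_range[1]) +
    floor(runif(n) * (as.numeric(as.Date(config$index_date_range[2]) -
                                 as.Date(config$index_date_range[1])) + 1))
  flags <- lapply(prev, function(p) runif(n) < p[band])

  ids <- sprintf("S%05d", seq_len(n))
  band_lo <- c(0, 20, 40, 60, 80)
  band_hi <- c(20, 40, 60, 80, 100)

  visits_l <- vector("list", n)
  labs_l <- vector("list", n)
  meds_l <- vector("list", n)
  diag_l <- vector("list", n)
  realised <- integer(n)

  for (i in seq_len(n)) {
    # Poisson visit process; visit 1 (day 0) is the index visit
    gaps <- rexp(ceiling(fu[i] * rate[i] * 3) + 10, rate[i])
    t_vis <- c(0, cumsum(gaps))
    t_vis <- t_vis[t_vis <= fu[i]]
    days <- unique(round(t_vis * 365.25))
    nv <- length(days)
    t_vis <- days / 365.25

    has_h <- c(TRUE, runif(nv - 1) >= config$p_miss_hba1c)[seq_len(nv)]
    has_s <- runif(nv) >= config$p_miss_scr
    if (!any(has_s)) has_s[sample.int(nv, 1)] <- TRUE
    if (runif(1) < config$p_unparallel && nv > 2) {
      has_s[t_vis > max(t_vis) - 120 / 365.25] <- FALSE
      if (!any(has_s)) has_s[1] <- TRUE
    }

    t_h <- t_vis[has_h]
    k <- band[i]
    if (length(t_h) >= 2) {
      npair <- length(t_h) - 1L
      # realised HVS equals the jump-indicator mean exactly, so the band
      # rejection runs on the cheap Bernoulli vector; some small series
      # cannot realise every band (e.g. 2 pairs can only give 0/50/100),
      # in which case the nearest draw is kept
      feasible <- any(hvs_category(100 * (0:npair) / npair) == k)
      jp <- config$jump_prob_by_category[k]
      jumps <- runif(npair) < jp
      if (feasible && hvs_category(100 * mean(jumps)) != k) {
        best <- jumps
        best_gap <- Inf
        for (try in seq_len(1000L)) {
          jumps <- runif(npair) < jp
          h <- 100 * mean(jumps)
          if (hvs_category(h) == k) { best <- jumps; break }
          gap <- max(band_lo[k] - h, h - band_hi[k])
          if (gap < best_gap) { best <- jumps; best_gap <- gap }
        }
        jumps <- best
      }
      hb <- data.frame(
        time = t_h,
        value = hba1c_values_from_jumps(hb_level[i], jumps))
    } else if (length(t_h) == 1) {
      hb <- data.frame(time = t_h, value = hb_level[i] + rnorm(1, 0, 0.3))
    } else {
      hb <- data.frame(time = numeric(0), value = numeric(0))
    }
    realised[i] <- if (nrow(hb) >= 2) hvs_category(hvs(hb$value)) else NA_integer_

    t_s <- t_vis[has_s]
    scr <- simulate_creatinine_series(b_egfr[i], slope_i[i],
                                      t_s, config$egfr_noise_sd,
                                      age[i], sex[i], id = ids[i])
    scr_val <- if (config$scr_unit == "umol/L") scr$creatinine * 88.4 else scr$creatinine

    visits_l[[i]] <- list(n = length(days), date = index_date[i] + days)
    labs_l[[i]] <- list(
      date = index_date[i] + c(round(hb$time * 365.25), round(t_s * 365.25)),
      analyte = c(rep("HBA1C", nrow(hb)), rep("SCR", length(t_s))),
      value = c(hb$value, scr_val),
      unit = c(rep("%", nrow(hb)), rep(config$scr_unit, length(t_s)))
    )

    med_classes <- c(INSULIN = flags$insulin[i], STATIN = flags$statin[i],
                     ARB_ACEI = flags$arb_acei[i], CCB = flags$ccb[i],
                     SGLT2I_GLP1RA = flags$sglt2i_glp1ra[i])
    used <- names(med_classes)[med_classes]
    if (length(used)) {
      md <- lapply(used, function(cl) {
        d <- sample(days, min(length(days), sample.int(3L, 1)))
        list(date = index_date[i] + d, cls = rep(cl, length(d)))
      })
      meds_l[[i]] <- list(date = do.call(c, lapply(md, `[[`, "date")),
                          cls = unlist(lapply(md, `[[`, "cls")))
    }

    dcodes <- "E11.9"
    if (flags$hypertension[i]) dcodes <- c(dcodes, "I10")
    if (flags$ascvd[i]) dcodes <- c(dcodes, "I25.1")
    diag_l[[i]] <- dcodes
  }

  nvis <- vapply(visits_l, `[[`, 0L, "n")
  nlab <- vapply(labs_l, function(l) length(l$date), 0L)
  nmed <- vapply(meds_l, function(l) if (is.null(l)) 0L else length(l$date), 0L)
  ndia <- lengths(diag_l)
  meds_keep <- meds_l[nmed > 0]
  raw <- list(
    subjects = data.frame(id = ids, sex = sex,
                          birth_date = index_date - round(age * 365.25)),
    visits = data.frame(id = rep(ids, nvis),
                        visit_date = do.call(c, lapply(visits_l, `[[`, "date"))),
    labs = data.frame(id = rep(ids, nlab),
                      date = do.call(c, lapply(labs_l, `[[`, "date")),
                      analyte = unlist(lapply(labs_l, `[[`, "analyte")),
                      value = unlist(lapply(labs_l, `[[`, "value")),
                      unit = unlist(lapply(labs_l, `[[`, "unit"))),
    meds = if (length(meds_keep)) {
      data.frame(id = rep(ids[nmed > 0], nmed[nmed > 0]),
                 date = do.call(c, lapply(meds_keep, `[[`, "date")),
                 drug_class = unlist(lapply(meds_keep, `[[`, "cls")))
    } else {
      data.frame(id = character(0), date = as.Date(character(0)),
                 drug_class = character(0))
    },
    diagnoses = data.frame(id = rep(ids, ndia),
                           date = rep(index_date, ndia),
                           icd10_code = unlist(diag_l))
  )
  attr(raw, "truth") <- data.frame(
    id = ids, latent_category = band, realised_category = realised,
    true_slope = slope_i,
    true_slope_band_mean = config$true_slope_by_category[band],
    baseline_egfr = b_egfr, age_at_index = age, sex = sex,
    index_date = index_date
  )
  attr(raw, "config_seed") <- config$seed
  class(raw) <- "raw_tables"
  raw
}

#' Simulate a derived analysis cohort directly (subject level)
#'
#' Skips the raw-table layer and generates the derived per-subject record
#' the models consume: HVS category, the nine balancing covariates with
#' Table-1-style category gradients, a rapid-decline indicator with
#' planted per-category log-odds offsets, and (optionally) a longitudinal
#' eGFR table with planted per-category slopes. Used for logistic
#' parameter-recovery and null-calibration studies where the lab-series
#' machinery does not enter the estimand.
#'
#' @param n_subjects Number of subjects.
#' @param category_probs Five band probabilities.
#' @param rapid_ref_prob Rapid-decline probability in the reference band.
#' @param rapid_log_or Five log-odds offsets (first must be 0).
#' @param slope_by_category Five true eGFR slopes (mL/min/1.73 m^2/yr).
#' @param slope_insulin_extra Additional slope (signed) for insulin users,
#'   applied uniformly; nonzero values plant an insulin-by-category
#'   subgroup contrast for tests.
#' @param slope_sd Between-subject SD of the true slope within a
#'   category (mL/min/1.73 m^2/yr); real cohorts show substantial slope
#'   heterogeneity, and a nonzero value keeps the mixed model's
#'   random-slope variance interior.
#' @param egfr_noise_sd Measurement noise SD for the longitudinal table.
#' @param baseline_egfr_mean,baseline_egfr_sd Baseline eGFR distribution.
#' @param visit_rate,follow_up_years,follow_up_spread Longitudinal
#'   measurement process (Poisson gaps, uniform follow-up).
#' @param hba1c_level_mean_by_category Per-band mean used for the
#'   time-weighted-average-HbA1c covariate.
#' @param age_mean_by_category,age_sd,female_frac_by_category,covariate_prevalence
#'   As in [sim_config()].
#' @param adherence_median_by_category Per-band median visits/yr for the
#'   adherence covariate.
#' @param longitudinal Emit the long eGFR table (needed for mixed-model
#'   fits)?
#' @param confounded If `TRUE` (default), covariate distributions carry
#'   the Table-1-style category gradients; if `FALSE` they are drawn
#'   category-independently at the pooled marginals (the
#'   parameter-recovery and null-calibration world, where the balance
#'   target sits at every category's centre and weights stay moderate).
#' @return A list with `cohort` (one row per subject) and `long`
#'   (subject_id, time, egfr; `NULL` unless `longitudinal = TRUE`).
#' @export
simulate_analysis_cohort <- function(n_subjects,
                                     category_probs = c(506, 585, 661, 444, 201) / 2397,
                                     rapid_ref_prob = 0.10,
                                     rapid_log_or = log(c(1, 1.05, 1.08, 1.11, 1.26)),
                                     slope_by_category = c(-0.33, -0.58, -0.83, -1.26, -2.16),
                                     slope_insulin_extra = 0,
                                     slope_sd = 1,
                                     egfr_noise_sd = 4,
                                     baseline_egfr_mean = 90,
                                     baseline_egfr_sd = 24,
                                     visit_rate = 1.9,
                                     follow_up_years = 4.7,
                                     follow_up_spread = 3.2,
                                     hba1c_level_mean_by_category = c(6.8, 7.1, 7.4, 7.8, 8.6),
                                     age_mean_by_category = c(60.3, 61.2, 57.5, 54.9, 53.4),
                                     age_sd = 12,
                                     female_frac_by_category = c(0.468, 0.407, 0.384, 0.396, 0.368),
                                     covariate_prevalence = sim_config()$covariate_prevalence,
                                     adherence_median_by_category = c(1.9, 2.0, 1.9, 1.8, 1.6),
                                     longitudinal = FALSE,
                                     confounded = TRUE) {
  stopifnot(abs(sum(category_probs) - 1) < 1e-12, rapid_log_or[1] == 0)
  n <- n_subjects
  k <- sample.int(5L, n, replace = TRUE, prob = category_probs)
  twa_sd <- c(0.4, 0.5, 0.8, 1.0, 1.3)
  if (!confounded) {
    # category-independent covariates at the pooled marginals: balancing
    # is still estimated and applied, but the target sits at every
    # category's centre (the parameter-recovery / null-calibration world)
    pool <- function(x) rep(sum(x * category_probs), 5)
    covariate_prevalence <- lapply(covariate_prevalence, pool)
    age_mean_by_category <- pool(age_mean_by_category)
    female_frac_by_category <- pool(female_frac_by_category)
    hba1c_level_mean_by_category <- pool(hba1c_level_mean_by_category)
    adherence_median_by_category <- pool(adherence_median_by_category)
    twa_sd <- rep(0.8, 5)
  }
  prev <- covariate_prevalence
  insulin <- runif(n) < prev$insulin[k]
  cohort <- data.frame(
    subject_id = sprintf("S%05d", seq_len(n)),
    hvs_category = k,
    age_at_index = rtruncnorm1(n, age_mean_by_category[k], age_sd, 20, 90),
    female = runif(n) < female_frac_by_category[k],
    baseline_egfr = rtruncnorm1(n, baseline_egfr_mean, baseline_egfr_sd, 20, 140),
    htn_or_ascvd = runif(n) < pmin(prev$hypertension[k] + prev$ascvd[k] *
                                     (1 - prev$hypertension[k]), 1),
    ever_insulin = insulin,
    ever_statin = runif(n) < prev$statin[k],
    ever_arb_acei = runif(n) < prev$arb_acei[k],
    ever_ccb = runif(n) < prev$ccb[k],
    ever_sglt2i_glp1ra = runif(n) < prev$sglt2i_glp1ra[k],
    twa_hba1c = rskew_level(n, hba1c_level_mean_by_category[k], twa_sd[k]),
    adherence = rlnorm(n, log(adherence_median_by_category[k]), 0.542)
  )
  cohort$baseline_egfr_lt60 <- cohort$baseline_egfr < 60
  true_slope <- slope_by_category[k] + slope_insulin_extra * insulin +
    rnorm(n, 0, slope_sd)
  cohort$true_slope <- true_slope
  eta <- qlogis(rapid_ref_prob) + rapid_log_or[k]
  cohort$rapid_decliner <- runif(n) < plogis(eta)

  long <- NULL
  if (longitudinal) {
    fu <- runif(n, follow_up_years - follow_up_spread,
                follow_up_years + follow_up_spread)
    nobs <- pmax(3L, rpois(n, visit_rate * fu)) + 1L
    sid <- rep(cohort$subject_id, nobs)
    t <- unlist(lapply(seq_len(n), function(i) {
      c(0, sort(runif(nobs[i] - 1L, 0, fu[i])))
    }))
    g <- rep(cohort$baseline_egfr, nobs) + rep(true_slope, nobs) * t +
      rnorm(length(t), 0, egfr_noise_sd)
    long <- data.frame(subject_id = sid, time = t, egfr = pmax(g, 1))
    cohort$follow_up_years <- fu
    cohort$mean_slope <- vapply(split(seq_along(sid), sid)[cohort$subject_id],
                                function(ix) {
                                  egfr_slope(t[ix], g[ix], min_points = 2L)$slope
                                }, numeric(1))
  }
  list(cohort = cohort, long = long)
}

#' @importFrom stats rpois plogis qlogis
NULL

fnv1a <- function(x) {
  # 32-bit FNV-1a over a character scalar; stable across sessions.
  # Arithmetic is split 16/16 bits so intermediates stay exact doubles.
  bytes <- utf8ToInt(x)
  h <- 2166136261
  m <- 16777619
  for (b in bytes) {
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), as.integer(b))
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- (((hi * m) %% 65536) * 65536 + lo * m) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

config_hash <- function(cfg) {
  fnv1a(paste(deparse(unclass(cfg), control = "all"), collapse = "\n"))
}

#' Write raw tables as delimited text
#'
#' Writes the five tables as CSV (ISO-8601 dates, UTF-8, header row) plus
#' a `manifest.json` recording the seed and config hash.
#'
#' @param raw A `raw_tables` object.
#' @param dir Output directory (created if missing).
#' @param config Optional `sim_config` used to produce `raw` (hashed into
#'   the manifest).
#' @return `dir`, invisibly.
#' @export
write_raw_tables <- function(raw, dir, config = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("subjects", "visits", "labs", "meds", "diagnoses")) {
    write.csv(raw[[nm]], file.path(dir, paste0(nm, ".csv")),
              row.names = FALSE)
  }
  manifest <- list(
    seed = attr(raw, "config_seed"),
    config_hash = if (is.null(config)) NA else config_hash(config),
    n_subjects = nrow(raw$subjects)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Read raw tables written by [write_raw_tables()]
#'
#' @param dir Directory containing the five CSV tables.
#' @return A `raw_tables` object.
#' @export
read_raw_tables <- function(dir) {
  rd <- function(nm, datecol) {
    df <- read.csv(file.path(dir, paste0(nm, ".csv")),
                   stringsAsFactors = FALSE)
    for (dc in datecol) df[[dc]] <- as.Date(df[[dc]])
    df
  }
  raw <- list(
    subjects = rd("subjects", "birth_date"),
    visits = rd("visits", "visit_date"),
    labs = rd("labs", "date"),
    meds = rd("meds", "date"),
    diagnoses = rd("diagnoses", "date")
  )
  class(raw) <- "raw_tables"
  raw
}
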