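## Cohort construction: eligibility, analysis window, baseline capture,
## adherence, comorbidity flags, and assembly of the per-subject record.

#' Eligibility configuration
#'
#' @param min_visits Minimum outpatient visits in the analysis window
#'   (default 5).
#' @param min_span_years Minimum span from index to last visit (default 1).
#' @param min_creatinine_measures Minimum serum creatinine measurements
#'   (default 3).
#' @param min_baseline_egfr Minimum baseline eGFR, mL/min/1.73 m^2
#'   (default 15).
#' @param baseline_window_days Two integers: baseline capture window
#'   around the index date (default -30 to +365).
#' @param min_age Adults-only filter: minimum age at index (default 18).
#' @return A list of class `eligibility_config`.
#' @export
eligibility_config <- function(min_visits = 5L, min_span_years = 1,
                               min_creatinine_measures = 3L,
                               min_baseline_egfr = 15,
                               baseline_window_days = c(-30L, 365L),
                               min_age = 18) {
  stopifnot(min_visits > 0, min_span_years > 0,
            min_creatinine_measures > 0, min_baseline_egfr > 0,
            length(baseline_window_days) == 2,
            baseline_window_days[1] < baseline_window_days[2])
  structure(list(min_visits = min_visits, min_span_years = min_span_years,
                 min_creatinine_measures = min_creatinine_measures,
                 min_baseline_egfr = min_baseline_egfr,
                 baseline_window_days = baseline_window_days,
                 min_age = min_age),
            class = "eligibility_config")
}

#' Index and end of the analysis window
#'
#' Index date is the chronologically first HbA1c measurement; the window
#' ends at the last HbA1c or creatinine measurement, whichever is later.
#'
#' @param hba1c_dates `Date` vector of HbA1c measurement dates (>= 1).
#' @param scr_dates `Date` vector of creatinine dates (may be empty).
#' @return A list with `index_date` and `end_date`.
#' @export
index_and_end <- function(hba1c_dates, scr_dates = as.Date(character(0))) {
  if (length(hba1c_dates) == 0) stop("no index: subject has no HbA1c",
                                     call. = FALSE)
  index <- min(hba1c_dates)
  end <- max(c(max(hba1c_dates), if (length(scr_dates)) max(scr_dates)))
  list(index_date = index, end_date = end)
}

#' Baseline measurement nearest the index date
#'
#' Picks, within the baseline window, the measurement nearest in absolute
#' time to the index date, breaking ties toward the earlier record.
#'
#' @param dates `Date` vector of measurement dates.
#' @param values Values, same length.
#' @param index_date Index `Date`.
#' @param window_days Two integers, window relative to index.
#' @return A list with `date` and `value`, or `NULL` when no measurement
#'   falls in the window.
#' @export
baseline_nearest <- function(dates, values, index_date,
                             window_days = c(-30L, 365L)) {
  off <- as.numeric(dates - index_date)
  keep <- off >= window_days[1] & off <= window_days[2]
  if (!any(keep)) return(NULL)
  off <- off[keep]
  values <- values[keep]
  dates <- dates[keep]
  ord <- order(abs(off), off)  # ties in |offset| -> earlier record
  list(date = dates[ord[1]], value = values[ord[1]])
}

#' Adherence: outpatient visits per year of follow-up
#'
#' @param visit_dates `Date` vector of visit dates.
#' @param index_date,end_date Analysis window bounds.
#' @return Visits per year (count of visits inside the window divided by
#'   the window length in years).
#' @export
adherence <- function(visit_dates, index_date, end_date) {
  span <- as.numeric(end_date - index_date) / 365.25
  if (span <= 0) stop("zero follow-up: end_date must exceed index_date",
                      call. = FALSE)
  sum(visit_dates >= index_date & visit_dates <= end_date) / span
}

#' Comorbidity flags from ICD-10 code prefixes
#'
#' A flag is true iff any diagnosis code starts with one of the configured
#' prefixes; matching is case-insensitive and ignores dots. The published
#' appendix code lists are not available, so the prefixes are
#' configurable; defaults cover hypertension (I10-I15) and common ASCVD
#' rubrics (I20-I25 ischaemic heart disease, I63-I66/I70 cerebrovascular
#' and peripheral atherosclerosis).
#'
#' @param codes Character vector of ICD-10 codes.
#' @param hypertension_prefixes,ascvd_prefixes Nonempty prefix lists.
#' @return A list with logical `hypertension` and `ascvd`.
#' @export
flag_comorbidity <- function(codes,
                             hypertension_prefixes = paste0("I1", 0:5),
                             ascvd_prefixes = c(paste0("I2", 0:5),
                                                "I63", "I64", "I65", "I66",
                                                "I70")) {
  if (length(hypertension_prefixes) == 0 || length(ascvd_prefixes) == 0) {
    stop("comorbidity code prefix lists must be nonempty", call. = FALSE)
  }
  norm <- function(x) toupper(gsub(".", "", x, fixed = TRUE))
  codes <- norm(codes)
  match_any <- function(prefixes) {
    prefixes <- norm(prefixes)
    any(vapply(prefixes, function(p) any(startsWith(codes, p)), TRUE))
  }
  list(hypertension = match_any(hypertension_prefixes),
       ascvd = match_any(ascvd_prefixes))
}

subject_split <- function(raw) {
  ids <- raw$subjects$id
  list(
    ids = ids,
    visits = split(raw$visits$visit_date, factor(raw$visits$id, ids)),
    lab_rows = split(seq_len(nrow(raw$labs)), factor(raw$labs$id, ids)),
    med_rows = split(seq_len(max(nrow(raw$meds), 0)),
                     factor(raw$meds$id, ids)),
    diag_rows = split(seq_len(nrow(raw$diagnoses)),
                      factor(raw$diagnoses$id, ids))
  )
}

#' Apply the eligibility rules
#'
#' Evaluates, per subject and in fixed order, the exclusion reasons
#' `no_index` (no HbA1c at all), `not_adult` (age at index below the
#' minimum), `min_visits`, `min_span`, `min_scr` (too few creatinine
#' measurements in the window), `insufficient_hba1c` (fewer than two
#' HbA1c measures, HVS undefined), `no_baseline_egfr` (no creatinine in
#' the baseline window) and `min_baseline_egfr`. Each excluded subject
#' carries exactly the first reason that fires.
#'
#' @param raw A `raw_tables` object.
#' @param cfg An [eligibility_config()].
#' @return A list with `included` (character ids) and `exclusions`
#'   (data.frame id, reason).
#' @export
apply_eligibility <- function(raw, cfg = eligibility_config()) {
  dec <- eligibility_decisions(raw, cfg)
  list(included = dec$id[is.na(dec$reason)],
       exclusions = dec[!is.na(dec$reason), c("id", "reason")])
}

eligibility_decisions <- function(raw, cfg) {
  sp <- subject_split(raw)
  labs <- raw$labs
  reason <- rep(NA_character_, length(sp$ids))
  for (j in seq_along(sp$ids)) {
    id <- sp$ids[j]
    lr <- sp$lab_rows[[id]]
    h <- lr[labs$analyte[lr] == "HBA1C"]
    s <- lr[labs$analyte[lr] == "SCR"]
    if (length(h) == 0) { reason[j] <- "no_index"; next }
    win <- index_and_end(labs$date[h], labs$date[s])
    age <- as.numeric(win$index_date - raw$subjects$birth_date[j]) / 365.25
    if (age < cfg$min_age) { reason[j] <- "not_adult"; next }
    vis <- sp$visits[[id]]
    nvis <- sum(vis >= win$index_date & vis <= win$end_date)
    if (nvis < cfg$min_visits) { reason[j] <- "min_visits"; next }
    span <- as.numeric(win$end_date - win$index_date) / 365.25
    if (span < cfg$min_span_years) { reason[j] <- "min_span"; next }
    s_in <- s[labs$date[s] >= win$index_date & labs$date[s] <= win$end_date]
    # creatinine measures counted per distinct day (same-day duplicates
    # are averaged downstream)
    if (length(unique(labs$date[s_in])) < cfg$min_creatinine_measures) {
      reason[j] <- "min_scr"; next
    }
    h_in <- h[labs$date[h] >= win$index_date & labs$date[h] <= win$end_date]
    if (length(unique(labs$date[h_in])) < 2) {
      reason[j] <- "insufficient_hba1c"; next
    }
    sex <- normalize_sex(raw$subjects$sex[j])
    scr_mgdl <- scr_to_mgdl(labs$value[s], labs$unit[s])
    bl <- baseline_nearest(labs$date[s], scr_mgdl, win$index_date,
                           cfg$baseline_window_days)
    if (is.null(bl)) { reason[j] <- "no_baseline_egfr"; next }
    bl_age <- as.numeric(bl$date - raw$subjects$birth_date[j]) / 365.25
    bl_egfr <- egfr_ckdepi(bl$value, max(bl_age, 18), sex)
    if (bl_egfr < cfg$min_baseline_egfr) {
      reason[j] <- "min_baseline_egfr"; next
    }
  }
  data.frame(id = sp$ids, reason = reason, stringsAsFactors = FALSE)
}

#' Build the derived analysis cohort
#'
#' Applies eligibility, then derives for each included subject the
#' analysis window, baseline covariates, time-weighted average HbA1c,
#' HVS and its category, adherence, the full-follow-up eGFR slope and
#' the rapid-decline flag. Same-day duplicate labs are averaged before
#' any series computation; creatinine is converted to mg/dL; eGFR is
#' computed at the attained age of each measurement.
#'
#' @param raw A `raw_tables` object.
#' @param cfg An [eligibility_config()].
#' @param hypertension_prefixes,ascvd_prefixes ICD-10 prefix lists, see
#'   [flag_comorbidity()].
#' @return A data.frame (one `cohort_row` per included subject) with
#'   attributes `exclusions` (the exclusion log) and `egfr_long` (the
#'   long table of (subject_id, time, egfr) the mixed model consumes).
#' @export
build_cohort <- function(raw, cfg = eligibility_config(),
                         hypertension_prefixes = paste0("I1", 0:5),
                         ascvd_prefixes = c(paste0("I2", 0:5), "I63", "I64",
                                            "I65", "I66", "I70")) {
  dec <- eligibility_decisions(raw, cfg)
  keep <- is.na(dec$reason)
  ids <- dec$id[keep]
  sp <- subject_split(raw)
  labs <- raw$labs
  meds <- raw$meds
  diags <- raw$diagnoses
  subj_row <- match(ids, raw$subjects$id)

  nI <- length(ids)
  col_num <- function() numeric(nI)
  col_lgl <- function() logical(nI)
  out <- list(
    index_date = as.Date(rep(NA, nI)), end_date = as.Date(rep(NA, nI)),
    follow_up_years = col_num(), age_at_index = col_num(),
    female = col_lgl(), baseline_egfr = col_num(),
    hypertension = col_lgl(), ascvd = col_lgl(),
    ever_insulin = col_lgl(), ever_statin = col_lgl(),
    ever_arb_acei = col_lgl(), ever_ccb = col_lgl(),
    ever_sglt2i_glp1ra = col_lgl(), baseline_hba1c = col_num(),
    twa_hba1c = col_num(), adherence = col_num(), hvs = col_num(),
    mean_slope = col_num(), n_hba1c = integer(nI), n_scr = integer(nI),
    last_measure_gap_days = col_num()
  )
  long <- vector("list", nI)
  for (j in seq_along(ids)) {
    id <- ids[j]
    lr <- sp$lab_rows[[id]]
    h <- lr[labs$analyte[lr] == "HBA1C"]
    s <- lr[labs$analyte[lr] == "SCR"]
    win <- index_and_end(labs$date[h], labs$date[s])
    index <- win$index_date
    end <- win$end_date
    fu <- as.numeric(end - index) / 365.25
    sex <- normalize_sex(raw$subjects$sex[subj_row[j]])
    birth <- raw$subjects$birth_date[subj_row[j]]
    age0 <- as.numeric(index - birth) / 365.25

    hb <- collapse_daily(labs$date[h], labs$value[h])
    in_h <- hb$dates >= index & hb$dates <= end
    hb_t <- as.numeric(hb$dates[in_h] - index) / 365.25
    hb_v <- hb$values[in_h]

    sc <- collapse_daily(labs$date[s], scr_to_mgdl(labs$value[s], labs$unit[s]))
    in_s <- sc$dates >= index & sc$dates <= end
    sc_t <- as.numeric(sc$dates[in_s] - index) / 365.25
    sc_v <- sc$values[in_s]
    egfr <- egfr_ckdepi(sc_v, pmax(age0 + sc_t, 18), sex)

    bl <- baseline_nearest(sc$dates, sc$values, index, cfg$baseline_window_days)
    bl_age <- as.numeric(bl$date - birth) / 365.25
    bl_egfr <- egfr_ckdepi(bl$value, max(bl_age, 18), sex)
    bl_hb <- baseline_nearest(hb$dates, hb$values, index,
                              cfg$baseline_window_days)

    dr <- sp$diag_rows[[id]]
    dr <- dr[diags$date[dr] <= index + cfg$baseline_window_days[2]]
    com <- flag_comorbidity(diags$icd10_code[dr], hypertension_prefixes,
                            ascvd_prefixes)

    mr <- sp$med_rows[[id]]
    mr <- mr[meds$date[mr] >= index & meds$date[mr] <= end]
    ever <- function(cl) any(meds$drug_class[mr] == cl)

    sl <- egfr_slope(sc_t, egfr)

    out$index_date[j] <- index
    out$end_date[j] <- end
    out$follow_up_years[j] <- fu
    out$age_at_index[j] <- age0
    out$female[j] <- sex == "F"
    out$baseline_egfr[j] <- bl_egfr
    out$hypertension[j] <- com$hypertension
    out$ascvd[j] <- com$ascvd
    out$ever_insulin[j] <- ever("INSULIN")
    out$ever_statin[j] <- ever("STATIN")
    out$ever_arb_acei[j] <- ever("ARB_ACEI")
    out$ever_ccb[j] <- ever("CCB")
    out$ever_sglt2i_glp1ra[j] <- ever("SGLT2I_GLP1RA")
    out$baseline_hba1c[j] <- if (is.null(bl_hb)) NA_real_ else bl_hb$value
    out$twa_hba1c[j] <- twa_hba1c(hb_t, hb_v)
    out$adherence[j] <- adherence(sp$visits[[id]], index, end)
    out$hvs[j] <- hvs(hb_v)
    out$mean_slope[j] <- sl$slope
    out$n_hba1c[j] <- length(hb_v)
    out$n_scr[j] <- length(sc_v)
    out$last_measure_gap_days[j] <-
      abs(as.numeric(max(hb$dates[in_h]) - max(sc$dates[in_s])))
    long[[j]] <- list(id = id, t = sc_t, g = egfr)
  }
  nlong <- vapply(long, function(l) length(l$t), 0L)
  egfr_long <- data.frame(
    subject_id = rep(ids, nlong),
    time = unlist(lapply(long, `[[`, "t")),
    egfr = unlist(lapply(long, `[[`, "g"))
  )
  cohort <- data.frame(subject_id = ids, out, stringsAsFactors = FALSE)
  cohort$baseline_egfr_lt60 <- cohort$baseline_egfr < 60
  cohort$htn_or_ascvd <- cohort$hypertension | cohort$ascvd
  cohort$hvs_category <- hvs_category(cohort$hvs)
  cohort$rapid_decliner <- rapid_decline(cohort$mean_slope)
  attr(cohort, "exclusions") <- dec[!keep, c("id", "reason")]
  attr(cohort, "egfr_long") <- egfr_long
  cohort
}
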