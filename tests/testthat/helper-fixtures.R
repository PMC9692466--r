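# Hand-built raw tables used across cohort / acceptance tests.
# Creatinine values were frozen from an independent closed-form
# evaluation of the CKD-EPI equation and its inverse (external to the
# package); each subject's latent eGFR trajectory, HVS and eligibility
# status are worked out by hand in the comments.

fx_day0 <- as.Date("2012-01-01")

fx_subject <- function(id, sex, birth_offset_days, visit_days,
                       hba1c = NULL, scr = NULL, scr_unit = "mg/dL",
                       meds = NULL, diags = NULL) {
  list(
    subject = data.frame(id = id, sex = sex,
                         birth_date = fx_day0 - birth_offset_days),
    visits = data.frame(id = id, visit_date = fx_day0 + visit_days),
    labs = rbind(
      if (!is.null(hba1c)) data.frame(id = id, date = fx_day0 + hba1c$day,
                                      analyte = "HBA1C",
                                      value = hba1c$value, unit = "%"),
      if (!is.null(scr)) data.frame(id = id, date = fx_day0 + scr$day,
                                    analyte = "SCR", value = scr$value,
                                    unit = scr_unit)
    ),
    meds = if (!is.null(meds)) data.frame(id = id, date = fx_day0 + meds$day,
                                          drug_class = meds$class),
    diags = if (!is.null(diags)) data.frame(id = id,
                                            date = fx_day0 + diags$day,
                                            icd10_code = diags$code)
  )
}

# Ten hand-built subjects with known eligibility decisions:
#  S01 included: 5 visits/2y, HVS 50 (cat 3), eGFR 90-5t -> slope -5,
#      rapid (boundary, inclusive); baseline eGFR 90; hypertensive (I10),
#      insulin during follow-up.
#  S02 excluded min_visits: 4 visits (also has no SCR -- first reason wins).
#  S03 excluded min_span: 5 visits over 328 days (0.898 y).
#  S04 excluded min_scr: only 2 creatinine days.
#  S05 excluded min_baseline_egfr: constant eGFR 12 < 15.
#  S06 excluded no_index: no HbA1c at all.
#  S07 excluded no_baseline_egfr: creatinine only at days 400-600 (outside
#      the -30..+365 baseline window).
#  S08 excluded not_adult: age 17 at index.
#  S09 included: equidistant creatinine at days -20/+20 (tie -> earlier:
#      baseline eGFR 83.94524298425736); constant HbA1c -> HVS 0 (cat 1);
#      eGFR 84 + t -> slope +1, not rapid.
#  S10 included: HVS 100 (cat 5); eGFR 88 - 12.3 t -> rapid; creatinine
#      reported in umol/L; last HbA1c (day 800) vs last SCR (day 700)
#      100 days apart (exercises the >=90-day unparallel exclusion).
fixture_raw_10 <- function() {
  subs <- list(
    fx_subject("S01", "F", 18262, c(0, 100, 300, 500, 730),
               hba1c = list(day = c(0, 100, 300, 500, 730),
                            value = c(7.0, 7.6, 7.5, 8.2, 8.1)),
               scr = list(day = c(0, 365, 730),
                          value = c(0.7702159360550808, 0.802802514646544,
                                    0.8391667452494512)),
               meds = list(day = c(100, 500), class = c("INSULIN", "STATIN")),
               diags = list(day = c(0, 0), code = c("E11.9", "I10"))),
    fx_subject("S02", "M", 20000, c(0, 200, 400, 600),
               hba1c = list(day = c(0, 600), value = c(7.0, 7.2))),
    fx_subject("S03", "F", 19000, c(0, 30, 90, 180, 328),
               hba1c = list(day = c(0, 328), value = c(6.5, 6.6)),
               scr = list(day = c(0, 100, 300), value = c(0.8, 0.8, 0.8))),
    fx_subject("S04", "M", 21000, c(0, 200, 400, 600, 800),
               hba1c = list(day = c(0, 400, 800), value = c(8.0, 8.1, 8.0)),
               scr = list(day = c(0, 400), value = c(1.0, 1.0))),
    fx_subject("S05", "M", 23741, c(0, 100, 200, 300, 400),
               hba1c = list(day = c(0, 200, 400), value = c(9.0, 8.9, 9.1)),
               scr = list(day = c(0, 200, 400),
                          value = c(4.734625236403998, 4.719585822064211,
                                    4.704594180034245))),
    fx_subject("S06", "F", 20000, c(0, 200, 400, 600, 800),
               scr = list(day = c(0, 300, 600), value = c(0.9, 0.9, 0.9))),
    fx_subject("S07", "F", 14610, c(0, 150, 300, 450, 600),
               hba1c = list(day = c(0, 300, 600), value = c(7.5, 7.4, 7.6)),
               scr = list(day = c(400, 500, 600),
                          value = c(0.8941061033341862, 0.892684921418848,
                                    0.891265998472584))),
    fx_subject("S08", "M", 6210, c(0, 200, 400, 600, 800),
               hba1c = list(day = c(0, 400, 800), value = c(7.0, 7.1, 7.2)),
               scr = list(day = c(0, 400, 800), value = c(0.9, 0.9, 0.9))),
    fx_subject("S09", "F", 21915, c(-20, 0, 20, 200, 400, 600),
               hba1c = list(day = c(0, 200, 400, 600),
                            value = c(6.8, 6.8, 6.8, 6.8)),
               scr = list(day = c(-20, 20, 400, 600),
                          value = c(0.7700718667127037, 0.7687525811886937,
                                    0.7563841294084472, 0.7499919413046677)),
               diags = list(day = 10, code = "i25.1")),
    fx_subject("S10", "M", 20089, c(0, 150, 300, 500, 700, 800),
               hba1c = list(day = c(0, 300, 700, 800),
                            value = c(7.0, 7.6, 7.0, 8.0)),
               scr = list(day = c(0, 300, 700),
                          value = c(85.35941874158988, 93.96881392021102,
                                    109.24974605257847)),
               scr_unit = "umol/L",
               meds = list(day = 300, class = "SGLT2I_GLP1RA"))
  )
  raw <- list(
    subjects = do.call(rbind, lapply(subs, `[[`, "subject")),
    visits = do.call(rbind, lapply(subs, `[[`, "visits")),
    labs = do.call(rbind, lapply(subs, `[[`, "labs")),
    meds = do.call(rbind, lapply(subs, `[[`, "meds")),
    diagnoses = do.call(rbind, lapply(subs, `[[`, "diags"))
  )
  rownames(raw$subjects) <- rownames(raw$visits) <- NULL
  rownames(raw$labs) <- rownames(raw$meds) <- rownames(raw$diagnoses) <- NULL
  class(raw) <- "raw_tables"
  raw
}

# expected eligibility decisions for fixture_raw_10, worked by hand
fixture_expected_reasons <- c(
  S01 = NA, S02 = "min_visits", S03 = "min_span", S04 = "min_scr",
  S05 = "min_baseline_egfr", S06 = "no_index", S07 = "no_baseline_egfr",
  S08 = "not_adult", S09 = NA, S10 = NA
)
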