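## Derived biomarkers: CKD-EPI eGFR, HVS, time-weighted average HbA1c,
## per-subject eGFR slopes, rapid-decline classification.

#' Estimated GFR from serum creatinine (CKD-EPI 2009)
#'
#' Computes eGFR in mL/min/1.73 m^2 from serum creatinine using the 2009
#' CKD-EPI creatinine equation. The race coefficient is fixed at 1 (the
#' pipeline targets a Chinese cohort); the female adjustment multiplies the
#' result by 1.018.
#'
#' @param creatinine Serum creatinine in mg/dL (strictly positive). Use
#'   [scr_to_mgdl()] first for values reported in µmol/L.
#' @param age Age in years at the time of the measurement (>= 18).
#' @param sex `"F"` or `"M"` (recycled against `creatinine`).
#' @return eGFR in mL/min/1.73 m^2.
#' @examples
#' egfr_ckdepi(0.7, age = 50, sex = "F")
#' egfr_ckdepi(1.4, age = 65, sex = "M")
#' @export
egfr_ckdepi <- function(creatinine, age, sex) {
  if (any(!is.finite(creatinine)) || any(creatinine <= 0)) {
    stop("creatinine must be strictly positive and finite", call. = FALSE)
  }
  if (any(!is.finite(age)) || any(age < 18)) {
    stop("age must be finite and >= 18", call. = FALSE)
  }
  sex <- normalize_sex(sex)
  n <- max(length(creatinine), length(age), length(sex))
  creatinine <- rep_len(creatinine, n)
  age <- rep_len(age, n)
  sex <- rep_len(sex, n)
  female <- sex == "F"
  kappa <- ifelse(female, 0.7, 0.9)
  alpha <- ifelse(female, -0.329, -0.411)
  r <- creatinine / kappa
  141 * pmin(r, 1)^alpha * pmax(r, 1)^-1.209 * 0.993^age *
    ifelse(female, 1.018, 1)
}

#' Serum creatinine yielding a given eGFR (inverse CKD-EPI)
#'
#' The CKD-EPI curve is a strictly decreasing piecewise power function of
#' creatinine, so it inverts in closed form. Round-trips with
#' [egfr_ckdepi()] to better than 1e-6.
#'
#' @param egfr Target eGFR in mL/min/1.73 m^2 (strictly positive).
#' @inheritParams egfr_ckdepi
#' @return Serum creatinine in mg/dL.
#' @export
creatinine_for_egfr <- function(egfr, age, sex) {
  if (any(!is.finite(egfr)) || any(egfr <= 0)) {
    stop("egfr must be strictly positive and finite", call. = FALSE)
  }
  sex <- normalize_sex(sex)
  n <- max(length(egfr), length(age), length(sex))
  egfr <- rep_len(egfr, n)
  age <- rep_len(age, n)
  sex <- rep_len(sex, n)
  female <- sex == "F"
  kappa <- ifelse(female, 0.7, 0.9)
  alpha <- ifelse(female, -0.329, -0.411)
  # factor the age/sex terms out: egfr = 141 * f(Scr/kappa) * base
  base <- 141 * 0.993^age * ifelse(female, 1.018, 1)
  a <- egfr / base           # = f(r); f(1) = 1, f decreasing
  r <- ifelse(a >= 1, a^(1 / alpha), a^(-1 / 1.209))
  r * kappa
}

#' Convert serum creatinine to mg/dL
#'
#' @param value Creatinine values.
#' @param unit Character vector of units, one of `"mg/dL"` or `"umol/L"`
#'   (`"µmol/L"` accepted).
#' @return Values in mg/dL (µmol/L divided by 88.4).
#' @export
scr_to_mgdl <- function(value, unit) {
  unit <- tolower(gsub("µ", "u", unit))
  n <- max(length(value), length(unit))
  value <- rep_len(value, n)
  unit <- rep_len(unit, n)
  ok <- unit %in% c("mg/dl", "umol/l")
  if (any(!ok)) {
    stop("unknown creatinine unit: ", paste(unique(unit[!ok]), collapse = ", "),
         call. = FALSE)
  }
  ifelse(unit == "umol/l", value / 88.4, value)
}

normalize_sex <- function(sex) {
  s <- toupper(substr(as.character(sex), 1, 1))
  if (any(!s %in% c("F", "M"))) {
    stop("sex must be 'F' or 'M'", call. = FALSE)
  }
  s
}

#' HbA1c variability score
#'
#' HVS is the percentage of successive HbA1c measurements that differ from
#' the previous one by at least 0.5 percentage points (NGSP units; about
#' 5.5 mmol/mol). The comparison is inclusive at 0.5.
#'
#' @param values HbA1c values in %, in chronological order.
#' @return HVS in percent, in `[0, 100]`.
#' @examples
#' hvs(c(7.0, 7.6, 7.5, 8.2, 8.1))  # 50
#' @export
hvs <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2) {
    stop("HVS undefined: fewer than 2 HbA1c measures", call. = FALSE)
  }
  d <- abs(diff(values))
  # tolerance guards float representation of e.g. 8.2 - 7.7
  100 * mean(d >= 0.5 - 1e-9)
}

#' HVS category (five 20%-wide bands)
#'
#' Band 1 is `[0, 20]` (the reference, "HVS <= 20%"); bands 2-5 are
#' left-open: `(20, 40]`, `(40, 60]`, `(60, 80]`, `(80, 100]`.
#'
#' @param hvs HVS values in percent.
#' @return Integer category 1-5.
#' @export
hvs_category <- function(hvs) {
  if (any(!is.finite(hvs)) || any(hvs < 0 | hvs > 100)) {
    stop("hvs must lie in [0, 100]", call. = FALSE)
  }
  cat <- findInterval(hvs, c(0, 20, 40, 60, 80), left.open = TRUE)
  as.integer(pmax(cat, 1L))
}

#' Time-weighted average HbA1c
#'
#' Integral of the piecewise-linear interpolant of HbA1c over the spanned
#' follow-up, divided by the span; a single measurement returns its own
#' value.
#'
#' @param times Measurement times in years, non-decreasing.
#' @param values HbA1c in %, same length as `times`.
#' @return Time-weighted average HbA1c in %.
#' @export
twa_hba1c <- function(times, values) {
  stopifnot(length(times) == length(values), length(times) >= 1)
  if (is.unsorted(times)) stop("times must be non-decreasing", call. = FALSE)
  if (length(times) == 1 || times[length(times)] == times[1]) {
    return(mean(values))
  }
  dt <- diff(times)
  mids <- (values[-1] + values[-length(values)]) / 2
  sum(dt * mids) / (times[length(times)] - times[1])
}

#' NGSP percent to IFCC mmol/mol
#'
#' `(pct - 2.15) * 10.929`; display tables round to integer mmol/mol.
#'
#' @param pct HbA1c in NGSP % (> 2.15).
#' @return HbA1c in mmol/mol (unrounded).
#' @export
hba1c_pct_to_mmolmol <- function(pct) {
  if (any(!is.finite(pct)) || any(pct <= 2.15)) {
    stop("HbA1c % must exceed 2.15 for IFCC conversion", call. = FALSE)
  }
  (pct - 2.15) * 10.929
}

#' Per-subject eGFR slope by ordinary least squares
#'
#' Least-squares regression of eGFR on time in years, optionally restricted
#' to a follow-up window. Two points define the math; analyses require
#' three (enforced by `min_points`).
#'
#' @param times Years since index, non-decreasing.
#' @param egfr eGFR values, same length.
#' @param window_years `"full"` (default) or a positive number: only
#'   measurements with `times <= window_years` enter the fit.
#' @param min_points Minimum in-window points for a defined slope
#'   (default 3, the analysis requirement; set 2 for the bare math).
#' @return A list of class `slope_estimate` with `slope`, `intercept`,
#'   `n_points`, `window_years`, or `NULL` when fewer than `min_points`
#'   points fall in the window.
#' @export
egfr_slope <- function(times, egfr, window_years = "full", min_points = 3L) {
  stopifnot(length(times) == length(egfr))
  if (!identical(window_years, "full")) {
    stopifnot(is.numeric(window_years), window_years > 0)
    keep <- times <= window_years + 1e-12
    times <- times[keep]
    egfr <- egfr[keep]
  }
  if (length(times) < min_points) return(NULL)
  tbar <- mean(times)
  ybar <- mean(egfr)
  sxx <- sum((times - tbar)^2)
  if (sxx == 0) return(NULL)  # all measures at one time point
  slope <- sum((times - tbar) * (egfr - ybar)) / sxx
  structure(
    list(slope = slope, intercept = ybar - slope * tbar,
         n_points = length(times), window_years = window_years),
    class = "slope_estimate"
  )
}

#' Rapid eGFR decline flag
#'
#' TRUE iff the mean eGFR slope is -5 mL/min/1.73 m^2/year or steeper
#' (inclusive at -5).
#'
#' @param slope Mean eGFR slope in mL/min/1.73 m^2/year.
#' @return Logical vector.
#' @export
rapid_decline <- function(slope) {
  if (any(!is.finite(slope))) stop("slope must be finite", call. = FALSE)
  slope <= -5
}

#' Average same-day duplicate measurements
#'
#' Collapses a (date, value) series to one value per day (the mean),
#' sorted by date. Applied to every lab series before HVS, TWA or slope
#' computations so successive pairs never have zero time gap.
#'
#' @param dates `Date` vector.
#' @param values Numeric vector.
#' @return A list with sorted unique `dates` and per-day mean `values`.
#' @export
collapse_daily <- function(dates, values) {
  stopifnot(length(dates) == length(values))
  if (length(dates) == 0) return(list(dates = dates, values = values))
  key <- as.integer(dates)
  ord <- order(key)
  key <- key[ord]
  values <- values[ord]
  if (!anyDuplicated(key)) {
    return(list(dates = as.Date(key, origin = "1970-01-01"),
                values = values))
  }
  m <- rowsum(values, key) / as.vector(rowsum(rep(1, length(key)), key))
  days <- as.integer(rownames(m))
  list(dates = as.Date(days, origin = "1970-01-01"),
       values = as.vector(m))
}
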