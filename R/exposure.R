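#' Construct a validated drug administration calendar
#'
#' The exposure calendar is the long-format record of nephrotoxic drug
#' administrations: one row per (patient, drug, postnatal day) event. All
#' lagged and cumulative exposure coding is derived from it.
#'
#' @param x Data frame with columns `patient_id`, `drug`, `pna_day`. `drug`
#'   must be one of `"ibuprofen"`, `"amikacin"`, `"vancomycin"`.
#' @return A tibble of class `exposure_calendar`, deduplicated and sorted.
#' @export
as_exposure_calendar <- function(x) {
  x <- as_tibble(x)
  req <- c("patient_id", "drug", "pna_day")
  if (!all(req %in% names(x))) {
    abort(paste0("exposure calendar needs columns: ", paste(req, collapse = ", ")))
  }
  x$patient_id <- as.character(x$patient_id)
  x$drug <- as.character(x$drug)
  x$pna_day <- as.integer(x$pna_day)
  if (nrow(x) > 0) {
    bad <- setdiff(unique(x$drug), NEPHROTOXIC_DRUGS)
    if (length(bad) > 0) {
      abort(paste0("unknown drug(s) in calendar: ", paste(bad, collapse = ", "),
                   "; expected one of ", paste(NEPHROTOXIC_DRUGS, collapse = ", ")))
    }
    if (any(x$pna_day < 1)) abort("administration days must be >= 1")
  }
  x <- distinct(x[, req]) %>% arrange(.data$patient_id, .data$drug, .data$pna_day)
  class(x) <- c("exposure_calendar", class(x))
  x
}

#' Empty exposure calendar
#' @return An `exposure_calendar` with zero rows.
#' @export
empty_calendar <- function() {
  as_exposure_calendar(tibble(patient_id = character(),
                              drug = character(),
                              pna_day = integer()))
}

resolve_drug_group <- function(drug_group) {
  if (is.character(drug_group) && length(drug_group) == 1 &&
      drug_group %in% names(DRUG_GROUPS)) {
    return(DRUG_GROUPS[[drug_group]])
  }
  bad <- setdiff(drug_group, NEPHROTOXIC_DRUGS)
  if (length(bad) > 0) {
    abort(paste0("unknown drug(s) in drug_group: ", paste(bad, collapse = ", ")))
  }
  drug_group
}

# run length of uninterrupted administration ending on `day - 1`, vectorised
# over (patient_id, day) pairs. The lag-1 convention means the exposure seen
# by an observation on day d is the treatment run that ended the day before.
consecutive_days_ending_lag1 <- function(calendar, patient_id, drug_group, day) {
  drugs <- resolve_drug_group(drug_group)
  patient_id <- as.character(patient_id)
  day <- as.integer(day)
  stopifnot(length(patient_id) == length(day))
  if (any(day < 1)) abort("day must be >= 1")
  cal <- filter(calendar, .data$drug %in% drugs)
  if (nrow(cal) == 0 || length(day) == 0) return(integer(length(day)))
  # per patient, run length r(x) at administered day x; 0 otherwise
  runs <- cal %>%
    distinct(.data$patient_id, .data$pna_day) %>%
    arrange(.data$patient_id, .data$pna_day) %>%
    group_by(.data$patient_id) %>%
    mutate(run_id = cumsum(c(1L, diff(.data$pna_day) != 1L))) %>%
    group_by(.data$patient_id, .data$run_id) %>%
    mutate(run_len = row_number()) %>%
    ungroup()
  key <- paste(runs$patient_id, runs$pna_day)
  lookup <- setNames(runs$run_len, key)
  out <- unname(lookup[paste(patient_id, day - 1L)])
  out[is.na(out)] <- 0L
  as.integer(out)
}

#' Lag-1 binary exposure indicator
#'
#' Codes treatment as 1 if any drug in `drug_group` was administered on the
#' day before outcome evaluation, and 0 otherwise (including day 1, which has
#' no prior day). This 1-day lag reflects the expected delay between a
#' nephrotoxic dose and its creatinine signal.
#'
#' @param calendar An [as_exposure_calendar()] object.
#' @param patient_id Character vector (recycled against `day` pairwise; equal
#'   lengths required).
#' @param drug_group Character vector of drugs, or a name from [DRUG_GROUPS].
#' @param day Integer vector of evaluation days (>= 1).
#' @return Integer vector of 0/1 indicators.
#' @export
#' @examples
#' cal <- as_exposure_calendar(
#'   data.frame(patient_id = "a", drug = "ibuprofen", pna_day = 4))
#' lag_indicator(cal, "a", "ibuprofen", day = 4:5)  # 0 then 1
lag_indicator <- function(calendar, patient_id, drug_group, day) {
  as.integer(consecutive_days_ending_lag1(calendar, patient_id, drug_group, day) >= 1L)
}

#' Consecutive days of exposure ending the day before evaluation
#'
#' Counts the length of the uninterrupted run of administration days (within
#' `drug_group`) that ends exactly on `day - 1`. A gap of one or more days
#' resets the count to 0, and day 1 is always 0 (no prior day). This is the
#' exposure-duration variable of the cumulative-effect model.
#'
#' @inheritParams lag_indicator
#' @param as_category If `TRUE` (default) return the capped factor with
#'   levels 0,1,2,3,4,5+; otherwise the raw integer run length.
#' @return Factor (default) or integer vector.
#' @export
#' @examples
#' cal <- as_exposure_calendar(data.frame(
#'   patient_id = "a", drug = "ibuprofen", pna_day = 3:5))
#' consecutive_days(cal, rep("a", 4), "ibuprofen", day = 4:7)
#' # categories 1, 2, 3, 0
consecutive_days <- function(calendar, patient_id, drug_group, day,
                             as_category = TRUE) {
  k <- consecutive_days_ending_lag1(calendar, patient_id, drug_group, day)
  if (as_category) consec_category(k) else k
}

#' Validate a creatinine observation table
#'
#' @param obs Data frame with `patient_id`, `pna_day`, `scr_mg_dl`.
#' @return Validated tibble.
#' @export
validate_observations <- function(obs) {
  obs <- as_tibble(obs)
  req <- c("patient_id", "pna_day", "scr_mg_dl")
  if (!all(req %in% names(obs))) {
    abort(paste0("observation table needs columns: ", paste(req, collapse = ", ")))
  }
  obs$patient_id <- as.character(obs$patient_id)
  obs$pna_day <- as.integer(obs$pna_day)
  if (anyNA(obs$pna_day) || anyNA(obs$scr_mg_dl)) {
    abort("observations contain missing pna_day or scr_mg_dl")
  }
  if (nrow(obs) > 0 && any(obs$pna_day < 1)) abort("pna_day must be >= 1")
  if (nrow(obs) > 0 && any(obs$scr_mg_dl <= 0)) abort("scr_mg_dl must be positive")
  obs
}

#' Restrict observations to the analysis window
#'
#' Keeps observations with postnatal day in `[1, max_day]` (boundary
#' inclusive). The number of rows dropped is reported as attribute
#' `n_dropped`.
#'
#' @param obs Observation table.
#' @param max_day Last day retained, default 28.
#' @return Filtered tibble.
#' @export
restrict_window <- function(obs, max_day = 28) {
  obs <- validate_observations(obs)
  keep <- obs$pna_day >= 1L & obs$pna_day <= max_day
  out <- obs[keep, , drop = FALSE]
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Apply the cohort exclusion rules
#'
#' Excludes patients for (in fixed priority order, one reason per patient):
#' duplicated `patient_id` in the demographics table; early neonatal death
#' (death before postnatal day 7); late referral (admission at or after day
#' 15); insufficient baseline data (fewer than `min_baseline_obs` creatinine
#' observations on days 1-3). The priority order makes the disposition
#' deterministic when several rules apply.
#'
#' @param demographics Tibble with `patient_id`, `admission_day`, `death_day`
#'   (`NA` if alive); other columns pass through.
#' @param obs Creatinine observation table.
#' @param calendar Exposure calendar.
#' @param min_baseline_obs Minimum days-1-3 observations required (default 1).
#' @return List with elements `demographics`, `obs`, `calendar` (filtered to
#'   included patients) and `log`, a tibble of per-patient dispositions of
#'   class `cohort_filter_log`.
#' @export
apply_exclusions <- function(demographics, obs, calendar, min_baseline_obs = 1) {
  demographics <- as_tibble(demographics)
  req <- c("patient_id", "admission_day", "death_day")
  if (!all(req %in% names(demographics))) {
    abort(paste0("demographics needs columns: ", paste(req, collapse = ", ")))
  }
  demographics$patient_id <- as.character(demographics$patient_id)
  obs <- validate_observations(obs)
  calendar <- as_exposure_calendar(calendar)

  ids <- demographics$patient_id
  reason <- rep(NA_character_, length(ids))

  dup_ids <- unique(ids[duplicated(ids)])
  reason[ids %in% dup_ids] <- "duplicate"

  early <- !is.na(demographics$death_day) & demographics$death_day < 7
  reason[is.na(reason) & early] <- "early_death"

  late <- !is.na(demographics$admission_day) & demographics$admission_day >= 15
  reason[is.na(reason) & late] <- "late_referral"

  base_n <- obs %>%
    filter(.data$pna_day >= 1, .data$pna_day <= 3) %>%
    count(.data$patient_id, name = "n_baseline")
  nb <- base_n$n_baseline[match(ids, base_n$patient_id)]
  nb[is.na(nb)] <- 0L
  reason[is.na(reason) & nb < min_baseline_obs] <- "insufficient_baseline"

  log <- tibble(
    patient_id = ids,
    disposition = if_else(is.na(reason), "included", "excluded"),
    reason = reason
  )
  class(log) <- c("cohort_filter_log", class(log))
  keep <- unique(ids[is.na(reason)])
  list(
    demographics = filter(demographics, .data$patient_id %in% keep) %>%
      distinct(.data$patient_id, .keep_all = TRUE),
    obs = filter(obs, .data$patient_id %in% keep),
    calendar = as_exposure_calendar(filter(calendar, .data$patient_id %in% keep)),
    log = log
  )
}

#' Summarise a cohort filter log
#' @param object A `cohort_filter_log`.
#' @param ... Unused.
#' @return Tibble of counts per disposition/reason.
#' @export
summary.cohort_filter_log <- function(object, ...) {
  object %>%
    mutate(reason = if_else(is.na(.data$reason), "included", .data$reason)) %>%
    count(.data$reason, name = "n_patients")
}
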