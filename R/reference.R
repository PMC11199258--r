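#' Read a postnatal-day p50 creatinine reference table
#'
#' A reference table maps postnatal age (PNA, day of birth = day 1) to the
#' median (p50) serum creatinine of a drug-free reference population, in
#' mg/dL. It supplies the denominator Q of the Pottel score Scr/Q.
#'
#' @param path Path to a CSV with header `day,p50_scr_mg_dl`, one row per
#'   day, days ascending and contiguous. Lines starting with `#` are ignored.
#' @return A tibble of class `pottel_reference` with integer column `day` and
#'   positive double column `p50_scr_mg_dl`.
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("day,p50_scr_mg_dl", "1,0.60", "2,0.75", "3,0.85"), f)
#' read_reference(f)
read_reference <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("reference file not found: ", path))
  }
  raw <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                         col_types = readr::cols(
                           day = readr::col_integer(),
                           p50_scr_mg_dl = readr::col_double()
                         ))
  validate_reference(raw)
}

#' Validate and classify a reference table
#'
#' Checks the invariants every reference table must satisfy: positive p50
#' values, no duplicated days, contiguous day coverage. Tables extending
#' beyond day 28 are accepted but flagged, since the standard analysis window
#' is the first 28 postnatal days.
#'
#' @param ref Data frame with columns `day` and `p50_scr_mg_dl`.
#' @return The validated table as a `pottel_reference` tibble, with attribute
#'   `beyond_window` set if coverage exceeds day 28.
#' @export
validate_reference <- function(ref) {
  ref <- as_tibble(ref)
  req <- c("day", "p50_scr_mg_dl")
  if (!all(req %in% names(ref))) {
    abort(paste0("reference table must have columns: ", paste(req, collapse = ", ")))
  }
  ref$day <- as.integer(ref$day)
  if (nrow(ref) == 0) abort("reference table is empty")
  if (anyNA(ref$day) || anyNA(ref$p50_scr_mg_dl)) {
    abort("reference table contains missing values")
  }
  dup <- ref$day[duplicated(ref$day)]
  if (length(dup) > 0) {
    abort(paste0("duplicate reference rows for day(s): ",
                 paste(sort(unique(dup)), collapse = ", ")))
  }
  ref <- arrange(ref, .data$day)
  if (any(ref$day < 1)) abort("reference days must be >= 1 (day of birth = day 1)")
  bad <- ref$day[ref$p50_scr_mg_dl <= 0]
  if (length(bad) > 0) {
    abort(paste0("non-positive p50 at day(s): ", paste(bad, collapse = ", ")))
  }
  gaps <- setdiff(seq(min(ref$day), max(ref$day)), ref$day)
  if (length(gaps) > 0) {
    abort(paste0("gap in reference day sequence at day(s): ",
                 paste(gaps, collapse = ", ")))
  }
  if (max(ref$day) > 28) {
    attr(ref, "beyond_window") <- TRUE
    warn("reference table extends beyond postnatal day 28 (standard analysis window)")
  }
  class(ref) <- c("pottel_reference", class(ref))
  ref
}

#' Write a reference table to CSV
#'
#' Inverse of [read_reference()]: the round trip is value-identical.
#'
#' @param ref A validated reference table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_reference <- function(ref, path) {
  ref <- validate_reference(ref)
  readr::write_csv(ref[, c("day", "p50_scr_mg_dl")], path)
  invisible(path)
}

#' Day range covered by a reference table
#' @param ref A validated reference table.
#' @return Integer vector `c(min_day, max_day)`.
#' @export
reference_day_range <- function(ref) {
  range(ref$day)
}

#' Look up p50 for given postnatal days
#'
#' Never extrapolates: a day outside coverage is an error, not a guess.
#'
#' @param ref A validated reference table.
#' @param day Integer vector of postnatal days.
#' @return Numeric vector of p50 values (mg/dL).
#' @export
reference_p50 <- function(ref, day) {
  idx <- match(as.integer(day), ref$day)
  if (anyNA(idx)) {
    missing_days <- sort(unique(day[is.na(idx)]))
    abort(paste0("postnatal day(s) outside reference coverage [",
                 min(ref$day), ", ", max(ref$day), "]: ",
                 paste(missing_days, collapse = ", ")))
  }
  ref$p50_scr_mg_dl[idx]
}

#' Estimate a p50 reference table from drug-free observations
#'
#' For each postnatal day, the p50 is the median serum creatinine over
#' observations on drug-free days (no ibuprofen, amikacin, or vancomycin
#' administered the day before the measurement). Days with fewer than
#' `min_n_per_day` eligible observations are filled by linear interpolation
#' between the nearest estimated days (at the ends, the nearest estimated
#' value is carried over) and flagged in the provenance log.
#'
#' Restricting to drug-free days matters because nephrotoxic exposure shifts
#' creatinine upwards; including exposed days would inflate the reference
#' medians and mask drug effects when the table is later used for scoring.
#'
#' @param obs Creatinine observations: tibble with `patient_id`, `pna_day`,
#'   `scr_mg_dl`.
#' @param calendar Drug administration calendar (see
#'   [as_exposure_calendar()]).
#' @param min_n_per_day Minimum eligible observations for a day to be
#'   estimated directly (default 5).
#' @param day_range Integer `c(min, max)` days to cover (default `c(1, 28)`).
#' @return A `pottel_reference` tibble with an additional logical column
#'   `interpolated`, plus attribute `n_per_day` (eligible counts).
#' @export
build_reference <- function(obs, calendar, min_n_per_day = 5,
                            day_range = c(1L, 28L)) {
  obs <- validate_observations(obs)
  obs <- restrict_window(obs, max_day = day_range[2])
  obs <- filter(obs, .data$pna_day >= day_range[1])
  if (nrow(obs) == 0) abort("no observations in requested day range")
  df <- drug_free_days(calendar, obs$patient_id, obs$pna_day)
  elig <- obs[df, , drop = FALSE]
  if (nrow(elig) == 0) abort("no drug-free observations available to estimate a reference")

  days <- seq(day_range[1], day_range[2])
  est <- elig %>%
    group_by(.data$pna_day) %>%
    summarise(n = n(), p50 = median(.data$scr_mg_dl), .groups = "drop")
  n_per_day <- setNames(integer(length(days)), days)
  n_per_day[as.character(est$pna_day)] <- est$n
  direct <- filter(est, .data$n >= min_n_per_day)
  if (nrow(direct) < 2) {
    abort(paste0("fewer than 2 days have >= ", min_n_per_day,
                 " drug-free observations; cannot interpolate a reference table"))
  }
  # linear interpolation between estimated days; constant at the ends
  filled <- approx(x = direct$pna_day, y = direct$p50, xout = days,
                   method = "linear", rule = 2)$y
  ref <- tibble(
    day = as.integer(days),
    p50_scr_mg_dl = filled,
    interpolated = !(days %in% direct$pna_day)
  )
  out <- validate_reference(ref)
  attr(out, "n_per_day") <- n_per_day
  attr(out, "min_n_per_day") <- min_n_per_day
  out
}

#' Bundled synthetic default reference table
#'
#' A smooth synthetic p50 curve with the physiologic ELBW shape: a rise from
#' birth peaking around postnatal days 3-4 followed by a slow decline. These
#' are NOT published reference values; they exist so the pipeline runs
#' end-to-end without external data. Real analyses must supply a reference
#' estimated from an appropriate drug-free population.
#'
#' @param days Integer vector of postnatal days (default 1:28).
#' @return A `pottel_reference` tibble.
#' @export
synthetic_reference <- function(days = 1:28) {
  tibble(day = as.integer(days),
         p50_scr_mg_dl = q_curve(days)) %>%
    validate_reference()
}

#' Synthetic physiologic p50 creatinine curve
#'
#' `q_inf + (q_peak - q_inf) * (d / d_peak) * exp(1 - d / d_peak)`: rises
#' from birth, peaks at `d_peak`, then declines slowly towards `q_inf`.
#'
#' @param day Numeric vector of postnatal days.
#' @param q_peak Peak p50 (mg/dL), default 0.95.
#' @param q_inf Late asymptote (mg/dL), default 0.35.
#' @param d_peak Day of the peak, default 3.5 (peak spans days 3-4).
#' @return Numeric vector of p50 values (mg/dL).
#' @export
q_curve <- function(day, q_peak = 0.95, q_inf = 0.35, d_peak = 3.5) {
  stopifnot(q_peak > q_inf, q_inf > 0, d_peak > 0)
  q_inf + (q_peak - q_inf) * (day / d_peak) * exp(1 - day / d_peak)
}
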