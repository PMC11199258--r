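#' Neonatal modified KDIGO stage-1 creatinine rule
#'
#' Flags, for each patient's ordered creatinine series, every observation
#' whose value rose by at least 0.3 mg/dL or by at least 50% compared with the
#' immediately preceding measured value. The first observation of a series is
#' never flagged (no previous value exists). When both rules fire, the
#' reported `trigger` is `absolute_rise` (priority), with both component
#' indicators kept in `rise_abs` / `rise_rel`.
#'
#' "Previous value" is the immediately preceding measurement — not a rolling
#' 48-hour window or a lowest-prior baseline. This literal single-lookback
#' rule is the comparator against which the Pottel score is assessed: because
#' ELBW neonates show a physiologic creatinine rise peaking around days 3-4,
#' the rule can flag healthy trajectories as stage-1 AKI.
#'
#' @param obs Observation table (`patient_id`, `pna_day`, `scr_mg_dl`); one
#'   or many patients. Within each patient, rows must be sortable by
#'   `pna_day`; ties (duplicate days) are processed in input order.
#' @return Tibble with input columns plus `reference_previous_scr`,
#'   `rise_abs`, `rise_rel`, `stage1_flag`, and
#'   `trigger` in `{"absolute_rise", "relative_rise", "none"}`.
#' @export
#' @examples
#' x <- data.frame(patient_id = "a", pna_day = 1:3,
#'                 scr_mg_dl = c(0.5, 0.8, 0.7))
#' mkdigo_stage1(x)
mkdigo_stage1 <- function(obs) {
  obs <- validate_observations(obs)
  unsorted <- obs %>%
    group_by(.data$patient_id) %>%
    summarise(ok = !is.unsorted(.data$pna_day), .groups = "drop")
  if (any(!unsorted$ok)) {
    abort(paste0("series not sorted by pna_day for patient(s): ",
                 paste(unsorted$patient_id[!unsorted$ok], collapse = ", ")))
  }
  obs %>%
    group_by(.data$patient_id) %>%
    mutate(
      reference_previous_scr = lag(.data$scr_mg_dl),
      # creatinine values are decimal fractions with no exact binary
      # representation; a 1e-9 slack keeps decimal-exact boundaries
      # (rise of exactly 0.30, ratio of exactly 1.5) on the flagged side
      rise_abs = !is.na(.data$reference_previous_scr) &
        (.data$scr_mg_dl - .data$reference_previous_scr >= 0.3 - 1e-9),
      rise_rel = !is.na(.data$reference_previous_scr) &
        (.data$scr_mg_dl / .data$reference_previous_scr >= 1.5 - 1e-9),
      stage1_flag = .data$rise_abs | .data$rise_rel,
      trigger = dplyr::case_when(
        rise_abs ~ "absolute_rise",
        rise_rel ~ "relative_rise",
        TRUE ~ "none"
      )
    ) %>%
    ungroup()
}

#' Concordance between the Pottel flag and the mKDIGO stage-1 rule
#'
#' Cross-tabulates the two detectors on the same observations, at the
#' observation level and at the patient level (flagged on any day). Both
#' inputs must cover exactly the same (patient, day) observations.
#'
#' @param staged Output of [mkdigo_stage1()].
#' @param flags Output of [flag_scores()] (or its `$flags` tibble).
#' @return List with `observation` and `patient` tibbles of counts in the
#'   four cells `both`, `pottel_only`, `mkdigo_only`, `neither`.
#' @export
compare_detectors <- function(staged, flags) {
  if (inherits(flags, "pottel_flags")) flags <- flags$flags
  key_a <- paste(staged$patient_id, staged$pna_day)
  key_b <- paste(flags$patient_id, flags$pna_day)
  if (!identical(sort(key_a), sort(key_b))) {
    abort("detectors were computed on different observation sets")
  }
  joined <- inner_join(
    select(staged, "patient_id", "pna_day", mkdigo = "stage1_flag"),
    select(flags, "patient_id", "pna_day", pottel = "flag"),
    by = c("patient_id", "pna_day"),
    relationship = "many-to-many"
  )
  cell <- function(m, p) {
    dplyr::case_when(m & p ~ "both", !m & p ~ "pottel_only",
                     m & !p ~ "mkdigo_only", TRUE ~ "neither")
  }
  obs_tab <- joined %>%
    mutate(cell = cell(.data$mkdigo, .data$pottel)) %>%
    count(.data$cell, name = "n") %>%
    tidyr::complete(cell = c("both", "pottel_only", "mkdigo_only", "neither"),
                    fill = list(n = 0L))
  pat_tab <- joined %>%
    group_by(.data$patient_id) %>%
    summarise(mkdigo = any(.data$mkdigo), pottel = any(.data$pottel),
              .groups = "drop") %>%
    mutate(cell = cell(.data$mkdigo, .data$pottel)) %>%
    count(.data$cell, name = "n") %>%
    tidyr::complete(cell = c("both", "pottel_only", "mkdigo_only", "neither"),
                    fill = list(n = 0L))
  list(observation = obs_tab, patient = pat_tab)
}
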