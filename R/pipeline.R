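#' Run the full nephrotoxicity analysis pipeline on a cohort
#'
#' Composes the stages in the order a study analysis runs them: cohort
#' exclusions, restriction to the first 28 postnatal days, Pottel scoring
#' against the reference table, then both linear mixed model families
#' (day-wise lag-1 exposure and cumulative consecutive-days exposure) for
#' ibuprofen and for the combined antibiotics, each unadjusted and adjusted
#' for the other drug group.
#'
#' @param demographics,obs,calendar Cohort tables (see
#'   [apply_exclusions()]).
#' @param ref Reference table.
#' @param days Days at which to evaluate day-wise contrasts; default all
#'   observed days with enough exposed patients.
#' @param max_day Analysis window (default 28).
#' @param min_baseline_obs Exclusion-rule setting (default 1).
#' @return List of class `pottel_analysis`: `effects` (one combined effect
#'   table with an `adjusted` column), `fits` (named list of model objects),
#'   `scored`, `drug_free_summary`, `filter_log`, and stage `counts`.
#' @export
analyze_cohort <- function(demographics, obs, calendar, ref,
                           days = NULL, max_day = 28, min_baseline_obs = 1) {
  excl <- apply_exclusions(demographics, obs, calendar,
                           min_baseline_obs = min_baseline_obs)
  scored <- score_cohort(excl$obs, ref, excl$calendar, max_day = max_day)
  dfree <- summarize_drug_free(scored)

  analyses <- list(
    list(drug = "ibuprofen", adj = NULL),
    list(drug = "ibuprofen", adj = DRUG_GROUPS$antibiotics),
    list(drug = "antibiotics", adj = NULL),
    list(drug = "antibiotics", adj = "ibuprofen")
  )
  fits <- list()
  effects <- list()
  for (a in analyses) {
    tag <- paste0(a$drug, if (is.null(a$adj)) "" else "_adjusted")
    dw <- fit_daywise_model(scored, excl$calendar, a$drug, adjust_group = a$adj)
    dd <- days %||% seq(dw$day_range[1], dw$day_range[2])
    dw_eff <- suppressWarnings(estimate_day_contrasts(dw, dd))
    cm <- fit_cumulative_model(scored, excl$calendar, a$drug,
                               adjust_group = a$adj)
    fits[[paste0(tag, "_daywise")]] <- dw
    fits[[paste0(tag, "_cumulative")]] <- cm$fit
    effects[[tag]] <- bind_rows(dw_eff, cm$effects) %>%
      mutate(adjusted = !is.null(a$adj))
  }
  eff <- bind_rows(effects)
  class(eff) <- c("pottel_effects", class(eff))
  structure(
    list(
      effects = eff,
      fits = fits,
      scored = scored,
      drug_free_summary = dfree,
      filter_log = excl$log,
      counts = tibble(
        patients_in = n_distinct(as_tibble(demographics)$patient_id),
        patients_included = n_distinct(excl$obs$patient_id),
        obs_scored = nrow(scored),
        obs_drug_free = sum(scored$drug_free)
      )
    ),
    class = "pottel_analysis"
  )
}

#' @export
print.pottel_analysis <- function(x, ...) {
  cat("Pottel-score nephrotoxicity analysis\n")
  cat(sprintf("  %d patients included (of %d), %d observations scored (%d drug-free)\n",
              x$counts$patients_included, x$counts$patients_in,
              x$counts$obs_scored, x$counts$obs_drug_free))
  cat(sprintf("  drug-free score: mean %.3f, sd %.3f\n",
              x$drug_free_summary$mean, x$drug_free_summary$sd))
  cat("  effect table rows:", nrow(x$effects), "\n")
  invisible(x)
}

#' Write an effect table to CSV with a provenance header
#'
#' @param effects An effect table.
#' @param path Output path.
#' @param seed Seed to record in the provenance line (optional).
#' @return `path`, invisibly.
#' @export
write_effects <- function(effects, path, seed = NA) {
  prov <- sprintf("# pottelscore %s | seed=%s",
                  as.character(utils::packageVersion("pottelscore")),
                  as.character(seed))
  writeLines(prov, path)
  readr::write_csv(as_tibble(effects), path, append = TRUE, col_names = TRUE)
  invisible(path)
}
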