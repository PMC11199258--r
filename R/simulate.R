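#' Parameters of the synthetic ELBW cohort generator
#'
#' Returns the full generative specification of a synthetic extremely low
#' birth weight (ELBW) cohort. Defaults emulate the structure the analysis
#' assumes: 201 patients observed over postnatal days 1-28 (about 3200
#' creatinine values), a physiologic creatinine trajectory peaking around
#' days 3-4 ([q_curve()]), multiplicative between-patient variability giving
#' drug-free Pottel scores centred on 1 with SD about 0.25, ibuprofen courses
#' (median 3 days, starting days 2-6, 62% of patients) and antibiotic courses
#' (medians 6-7 days, starting from day 4 for late-onset sepsis, about 81% of
#' patients), saturating cumulative drug effects on the score scale, a
#' decreasing per-day sampling schedule, and late-death dropout.
#'
#' The creatinine model is
#' `Scr(i, d) = Q(d) * exp(b0_i + b1_i * log d) * C(d) * M(i, d) * exp(e)`,
#' with `b0_i ~ N(0, sigma_b^2)`, `b1_i ~ N(0, sigma_s^2)`,
#' `e ~ N(0, sigma_e^2)`, and `M(i, d)` the product of the active drug
#' multipliers determined by the consecutive-exposure runs ending on day
#' `d - 1`. `C(d) = exp(-(sigma_b^2 + sigma_s^2 log(d)^2 + sigma_e^2) / 2)`
#' is the log-normal mean correction, so that on drug-free days
#' `E[Scr/Q] = 1` exactly.
#'
#' @param n_patients Number of patients.
#' @param max_day Last postnatal day simulated (default 28).
#' @param q_fun Reference curve Q(d) in mg/dL, default [q_curve()].
#' @param sigma_b Between-patient intercept SD, log scale.
#' @param sigma_s Between-patient slope SD on log(day), log scale.
#' @param sigma_e Residual SD, log scale.
#' @param p_ibuprofen Probability a patient receives an ibuprofen course.
#' @param ibu_start_days,ibu_start_probs Course start-day distribution
#'   (persistent ductus arteriosus treatment window, days 2-6).
#' @param ibu_duration_days,ibu_duration_probs Course duration distribution
#'   (median 3 days, range 1-14).
#' @param ibu_effect Multiplier on Scr (equivalently on the score) for
#'   consecutive exposure days 1,2,3,4,5+; saturating by default.
#' @param p_abx_episode Probability of an antibiotic episode (any of
#'   amikacin/vancomycin).
#' @param p_both_given_episode Probability the episode uses both antibiotics;
#'   the remainder splits equally between amikacin-only and vancomycin-only.
#' @param abx_start_days,abx_start_probs Episode start-day distribution
#'   (late-onset sepsis, > 72 h postnatal age, so from day 4).
#' @param amik_duration_days,amik_duration_probs Amikacin duration
#'   distribution (median 6, range 1-17).
#' @param vanc_duration_days,vanc_duration_probs Vancomycin duration
#'   distribution (median 7, range 1-21).
#' @param abx_effect Multiplier profile for the combined antibiotic run
#'   (consecutive days 1..5+); smaller than ibuprofen's.
#' @param abx_follow_ibu_prob Probability that a patient with an ibuprofen
#'   course also gets an antibiotic episode starting the same day
#'   (co-occurring illness). Default 0 = exposures independent; raise it to
#'   construct confounding between the two exposures.
#' @param sampling_base,sampling_decay Per-day observation probability
#'   `sampling_base * exp(-sampling_decay * (d - 1))`; defaults give about
#'   16 observations per surviving patient over 28 days.
#' @param p_late_death Probability of late neonatal death (day >= 7), which
#'   truncates the series at the death day.
#' @param death_days Days on which a late death may occur.
#' @param seed Integer seed fixing the whole cohort.
#' @return A `sim_params` list, validated.
#' @export
sim_params <- function(n_patients = 201,
                       max_day = 28,
                       q_fun = q_curve,
                       sigma_b = 0.20,
                       sigma_s = 0.05,
                       sigma_e = 0.12,
                       p_ibuprofen = 0.617,
                       ibu_start_days = 2:6,
                       ibu_start_probs = c(0.35, 0.30, 0.20, 0.10, 0.05),
                       ibu_duration_days = 1:14,
                       ibu_duration_probs = c(0.20, 0.25, 0.20, 0.12, 0.08,
                                              0.05, 0.04, 0.02, 0.015, 0.01,
                                              0.005, 0.004, 0.003, 0.003),
                       ibu_effect = c(1.030, 1.058, 1.082, 1.100, 1.112),
                       p_abx_episode = 0.81,
                       p_both_given_episode = 0.87,
                       abx_start_days = 4:20,
                       abx_start_probs = exp(-0.12 * (0:16)),
                       amik_duration_days = 1:17,
                       amik_duration_probs = exp(-((1:17 - 6) / 4)^2),
                       vanc_duration_days = 1:21,
                       vanc_duration_probs = exp(-((1:21 - 7) / 4.5)^2),
                       abx_effect = c(1.005, 1.010, 1.015, 1.020, 1.027),
                       abx_follow_ibu_prob = 0,
                       sampling_base = 0.95,
                       sampling_decay = 0.04,
                       p_late_death = 0.085,
                       death_days = 7:28,
                       seed = 1L) {
  p <- as.list(environment())
  validate_sim_params(p)
  class(p) <- "sim_params"
  p
}

validate_sim_params <- function(p) {
  stopifnot(
    p$n_patients >= 1, p$max_day >= 2,
    p$sigma_b >= 0, p$sigma_s >= 0, p$sigma_e >= 0,
    all(p$ibu_effect > 0), all(p$abx_effect > 0),
    length(p$ibu_effect) == 5, length(p$abx_effect) == 5,
    p$p_ibuprofen >= 0, p$p_ibuprofen <= 1,
    p$p_abx_episode >= 0, p$p_abx_episode <= 1,
    p$abx_follow_ibu_prob >= 0, p$abx_follow_ibu_prob <= 1,
    p$sampling_base > 0, p$sampling_base <= 1
  )
  q <- p$q_fun(seq_len(p$max_day))
  if (any(!is.finite(q)) || any(q <= 0)) {
    abort("q_fun must be positive and finite over the simulated day range")
  }
  invisible(p)
}

# multiplier for a consecutive-days count k given a length-5 profile (k >= 5
# uses the last entry; k = 0 is 1)
profile_multiplier <- function(k, profile) {
  # index with k clamped to [1, 5] first: a zero index would drop elements
  # and misalign the vector
  ifelse(k == 0, 1, profile[pmax(pmin(k, 5L), 1L)])
}

sample1 <- function(x, prob) {
  if (length(x) == 1) return(x)
  sample(x, 1L, prob = prob)
}

#' Simulate a synthetic ELBW cohort
#'
#' Draws a complete cohort — demographics, drug administration calendar,
#' creatinine observations — from the generative model in [sim_params()],
#' together with the ground truth needed to verify every downstream stage:
#' per-patient random effects, the per-observation true drug multiplier and
#' noiseless creatinine, and the reference curve Q(d) used. The same seed
#' always reproduces the identical cohort.
#'
#' @param params A [sim_params()] object.
#' @return List of class `synthetic_cohort`: `demographics`, `obs`,
#'   `calendar`, `ground_truth` (with `patients`, `observations`,
#'   `reference`), and `params`.
#' @export
simulate_cohort <- function(params = sim_params()) {
  validate_sim_params(params)
  withr::with_seed(params$seed, simulate_cohort_impl(params))
}

simulate_cohort_impl <- function(p) {
  n <- p$n_patients
  ids <- sprintf("P%03d", seq_len(n))
  days <- seq_len(p$max_day)
  qd <- p$q_fun(days)

  # demographics: ELBW profile (GA ~ 27 wk, BW ~ 808 g), late deaths only
  ga <- pmin(pmax(round(rnorm(n, 27, 2)), 23), 34)
  bw <- pmin(pmax(round(rnorm(n, 808, 135)), 370), 1000)
  sex <- ifelse(runif(n) < 0.532, "F", "M")
  death_day <- rep(NA_integer_, n)
  dies <- runif(n) < p$p_late_death
  death_day[dies] <- vapply(which(dies), function(i) {
    sample1(p$death_days, prob = NULL)
  }, integer(1))
  demographics <- tibble(
    patient_id = ids, ga_weeks = ga, bw_g = bw, sex = sex,
    admission_day = 1L, death_day = death_day
  )

  # drug courses
  cal_rows <- vector("list", n)
  for (i in seq_len(n)) {
    rows <- list()
    has_ibu <- runif(1) < p$p_ibuprofen
    ibu_start <- NA_integer_
    if (has_ibu) {
      ibu_start <- sample1(p$ibu_start_days, p$ibu_start_probs)
      dur <- sample1(p$ibu_duration_days, p$ibu_duration_probs)
      d <- intersect(ibu_start:(ibu_start + dur - 1L), days)
      rows$ibu <- tibble(patient_id = ids[i], drug = "ibuprofen", pna_day = d)
    }
    forced <- has_ibu && runif(1) < p$abx_follow_ibu_prob
    has_abx <- forced || runif(1) < p$p_abx_episode
    if (has_abx) {
      abx_start <- if (forced) ibu_start else sample1(p$abx_start_days, p$abx_start_probs)
      u <- runif(1)
      p_single <- (1 - p$p_both_given_episode) / 2
      which_abx <- if (u < p$p_both_given_episode) c("amikacin", "vancomycin")
                   else if (u < p$p_both_given_episode + p_single) "amikacin"
                   else "vancomycin"
      if ("amikacin" %in% which_abx) {
        dur <- sample1(p$amik_duration_days, p$amik_duration_probs)
        d <- intersect(abx_start:(abx_start + dur - 1L), days)
        rows$amik <- tibble(patient_id = ids[i], drug = "amikacin", pna_day = d)
      }
      if ("vancomycin" %in% which_abx) {
        dur <- sample1(p$vanc_duration_days, p$vanc_duration_probs)
        d <- intersect(abx_start:(abx_start + dur - 1L), days)
        rows$vanc <- tibble(patient_id = ids[i], drug = "vancomycin", pna_day = d)
      }
    }
    cal_rows[[i]] <- bind_rows(rows)
  }
  cal_tbl <- bind_rows(cal_rows)
  calendar <- if (nrow(cal_tbl) == 0) empty_calendar() else as_exposure_calendar(cal_tbl)

  # random effects and observations
  b0 <- rnorm(n, 0, p$sigma_b)
  b1 <- rnorm(n, 0, p$sigma_s)
  logd <- log(days)
  # log-normal mean correction so E[Scr/Q] = 1 on drug-free days
  corr <- exp(-(p$sigma_b^2 + p$sigma_s^2 * logd^2 + p$sigma_e^2) / 2)

  grid <- tidyr::expand_grid(i = seq_len(n), pna_day = days) %>%
    mutate(patient_id = ids[.data$i])
  last_day <- ifelse(is.na(death_day), p$max_day, death_day)
  grid <- filter(grid, .data$pna_day <= last_day[.data$i])
  p_obs <- p$sampling_base * exp(-p$sampling_decay * (grid$pna_day - 1))
  grid <- grid[runif(nrow(grid)) < p_obs, , drop = FALSE]

  k_ibu <- consecutive_days_ending_lag1(calendar, grid$patient_id,
                                        "ibuprofen", grid$pna_day)
  k_abx <- consecutive_days_ending_lag1(calendar, grid$patient_id,
                                        c("amikacin", "vancomycin"),
                                        grid$pna_day)
  mult <- profile_multiplier(k_ibu, p$ibu_effect) *
    profile_multiplier(k_abx, p$abx_effect)
  noiseless <- qd[grid$pna_day] *
    exp(b0[grid$i] + b1[grid$i] * log(grid$pna_day)) *
    corr[grid$pna_day] * mult
  scr <- noiseless * exp(rnorm(nrow(grid), 0, p$sigma_e))

  obs <- tibble(
    patient_id = grid$patient_id,
    pna_day = as.integer(grid$pna_day),
    scr_mg_dl = scr
  )
  ground_truth <- list(
    patients = tibble(patient_id = ids, b0 = b0, b1 = b1),
    observations = tibble(
      patient_id = grid$patient_id,
      pna_day = as.integer(grid$pna_day),
      true_multiplier = mult,
      true_scr_noiseless = noiseless
    ),
    reference = tibble(day = as.integer(days), q = qd)
  )
  structure(
    list(demographics = demographics, obs = obs, calendar = calendar,
         ground_truth = ground_truth, params = p),
    class = "synthetic_cohort"
  )
}

#' Null cohort: exposures assigned, all drug effects switched off
#'
#' Identical to [simulate_cohort()] except that every drug multiplier is
#' forced to 1, so drug exposure has no effect on creatinine while the design
#' matrices stay non-degenerate. This is the type-I-error harness for the
#' mixed models and the detector-divergence comparison.
#'
#' @param params A [sim_params()] object; its effect profiles are overridden.
#' @return A `synthetic_cohort`.
#' @export
null_cohort <- function(params = sim_params()) {
  params$ibu_effect <- rep(1, 5)
  params$abx_effect <- rep(1, 5)
  simulate_cohort(params)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic ELBW cohort (seed ", x$params$seed, ")\n", sep = "")
  cat(sprintf("  %d patients, %d creatinine observations, days 1-%d\n",
              nrow(x$demographics), nrow(x$obs), x$params$max_day))
  cat(sprintf("  %d drug administration days (%s)\n", nrow(x$calendar),
              paste(unique(x$calendar$drug), collapse = ", ")))
  invisible(x)
}

#' Write a synthetic cohort to CSV files
#'
#' Emits `demographics.csv`, `observations.csv`, `exposures.csv`, and
#' `ground_truth.csv` into `dir`, each starting with a provenance comment
#' line recording the package version and the generating seed. Re-running
#' with the same seed reproduces every file byte-for-byte.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the paths written, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  prov <- sprintf("# pottelscore %s | seed=%d",
                  as.character(utils::packageVersion("pottelscore")),
                  cohort$params$seed)
  gt <- left_join(cohort$ground_truth$observations,
                  cohort$ground_truth$patients, by = "patient_id")
  tables <- list(
    demographics = cohort$demographics,
    observations = cohort$obs,
    exposures = as_tibble(cohort$calendar),
    ground_truth = gt
  )
  paths <- vapply(names(tables), function(nm) {
    path <- file.path(dir, paste0(nm, ".csv"))
    writeLines(prov, path)
    readr::write_csv(tables[[nm]], path, append = TRUE, col_names = TRUE)
    path
  }, character(1))
  invisible(paths)
}

#' Read a cohort back from CSV files written by [write_cohort()]
#'
#' @param dir Directory holding `demographics.csv`, `observations.csv`,
#'   `exposures.csv`.
#' @return List with `demographics`, `obs`, `calendar`.
#' @export
read_cohort <- function(dir) {
  rd <- function(nm) readr::read_csv(file.path(dir, paste0(nm, ".csv")),
                                     comment = "#", show_col_types = FALSE)
  list(
    demographics = rd("demographics"),
    obs = validate_observations(rd("observations")),
    calendar = as_exposure_calendar(rd("exposures"))
  )
}
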