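# independent brute-force oracles and random-case generators for the
# property-style tests

# run length of uninterrupted administration ending exactly on day - 1,
# by walking backwards one day at a time
oracle_consec <- function(admin_days, day) {
  k <- 0L
  d <- day - 1L
  while (d >= 1L && d %in% admin_days) {
    k <- k + 1L
    d <- d - 1L
  }
  k
}

random_calendar <- function(n_patients = 3, max_day = 15, p_admin = 0.3) {
  rows <- list()
  for (i in seq_len(n_patients)) {
    for (drug in NEPHROTOXIC_DRUGS) {
      days <- which(runif(max_day) < p_admin)
      if (length(days) > 0) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          patient_id = paste0("p", i), drug = drug, pna_day = days)
      }
    }
  }
  if (length(rows) == 0) return(empty_calendar())
  as_exposure_calendar(dplyr::bind_rows(rows))
}

# independent re-scan of all consecutive pairs of one patient's series
oracle_stage1 <- function(scr) {
  n <- length(scr)
  flag <- logical(n)
  if (n >= 2) {
    for (j in 2:n) {
      flag[j] <- (scr[j] - scr[j - 1] >= 0.3 - 1e-9) ||
        (scr[j] / scr[j - 1] >= 1.5 - 1e-9)
    }
  }
  flag
}

random_series <- function(n = 8, include_boundaries = FALSE) {
  scr <- round(runif(n, 0.2, 1.6), 2)
  if (include_boundaries && n >= 4) {
    # engineered exact boundary pairs: rise of exactly 0.3 and ratio exactly 1.5
    scr[1] <- 0.5; scr[2] <- 0.8    # 0.8 - 0.5 >= 0.3
    scr[3] <- 0.5; scr[4] <- 0.75   # 0.75 / 0.5 == 1.5 exactly
  }
  tibble::tibble(patient_id = "s1", pna_day = seq_len(n), scr_mg_dl = scr)
}

# reference table matching a synthetic cohort's own generating curve
cohort_reference <- function(cohort) {
  validate_reference(data.frame(
    day = cohort$ground_truth$reference$day,
    p50_scr_mg_dl = cohort$ground_truth$reference$q))
}

# patient-level (cluster) standard error of the mean score: observations
# within a patient share random effects and are not independent
cluster_se <- function(scores, patient_id) {
  m <- tapply(scores, patient_id, mean)
  stats::sd(m) / sqrt(length(m))
}
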