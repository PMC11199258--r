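test_that("pottel_score is the exact ratio to the day's p50", {
  ref <- validate_reference(data.frame(day = 1:3,
                                       p50_scr_mg_dl = c(0.60, 0.75, 0.85)))
  expect_identical(pottel_score(0.75, 2, ref), 1)       # scr == p50
  expect_identical(pottel_score(1.20, 1, ref), 2)
  expect_equal(pottel_score(0.51, 3, ref), 0.6)         # hand division
  expect_error(pottel_score(-1, 1, ref), "positive")
  expect_error(pottel_score(0.5, 5, ref), "outside reference coverage")
})

test_that("drug-free days follow the lag-1 rule over all three drugs", {
  cal <- as_exposure_calendar(tibble::tibble(
    patient_id = c("a", "b"), drug = c("ibuprofen", "vancomycin"),
    pna_day = c(4L, 9L)))
  # ibuprofen on day 4: day 5 is exposed, day 4 itself is still drug-free
  expect_false(drug_free_days(cal, "a", 5))
  expect_true(drug_free_days(cal, "a", 4))
  # any of the three drugs triggers
  expect_false(drug_free_days(cal, "b", 10))
  # day 1 has no prior day; empty calendar means every day is drug-free
  expect_true(drug_free_days(cal, "a", 1))
  expect_true(all(drug_free_days(empty_calendar(), rep("x", 5), 1:5)))
})

test_that("score_cohort preserves cardinality and reports range errors", {
  ref <- synthetic_reference(1:28)
  obs <- tibble::tibble(patient_id = c("a", "a", "b"),
                        pna_day = c(1L, 3L, 7L),
                        scr_mg_dl = c(0.7, 0.9, 0.6))
  scored <- score_cohort(obs, ref, empty_calendar())
  expect_equal(nrow(scored), 3L)
  expect_true(all(c("pottel_score", "drug_free") %in% names(scored)))

  short_ref <- synthetic_reference(1:10)
  bad <- tibble::tibble(patient_id = "zz9", pna_day = 11L, scr_mg_dl = 0.5)
  expect_error(score_cohort(bad, short_ref, empty_calendar(), max_day = 28),
               "zz9.*11")
})

test_that("drug-free summary computes n-1 moments and guards its inputs", {
  scored <- tibble::tibble(patient_id = "a", pna_day = 1:3,
                           scr_mg_dl = 1, pottel_score = c(0.9, 1.0, 1.1),
                           drug_free = TRUE)
  s <- summarize_drug_free(scored)
  expect_equal(s$mean, 1.0)
  expect_equal(s$sd, 0.1)
  scored$drug_free <- FALSE
  expect_error(summarize_drug_free(scored), "at least 2")
})

test_that("flagging is a strict threshold rule, monotone in the threshold", {
  scored <- tibble::tibble(patient_id = c("a", "a"), pna_day = 1:2,
                           scr_mg_dl = 1, pottel_score = c(1.2, 1.4),
                           drug_free = TRUE)
  fl <- flag_scores(scored, 1.33)
  expect_equal(fl$flags$flag, c(FALSE, TRUE))
  expect_equal(fl$first_flag_day$first_flag_day, 2L)
  expect_error(flag_scores(scored, 0), "positive")

  co <- simulate_cohort(sim_params(n_patients = 60, seed = 5))
  scored <- score_cohort(co$obs, cohort_reference(co), co$calendar)
  rates <- vapply(c(0.5, 1, 1.3, 1.6, 2),
                  function(th) flag_scores(scored, th)$flag_rate, numeric(1))
  expect_true(all(diff(rates) <= 0))
})

test_that("null-cohort drug-free scores are calibrated around 1", {
  co <- null_cohort(sim_params(n_patients = 150, seed = 8))
  scored <- score_cohort(co$obs, cohort_reference(co), co$calendar)
  s <- summarize_drug_free(scored)
  dfree <- scored[scored$drug_free, ]
  se <- cluster_se(dfree$pottel_score, dfree$patient_id)
  expect_lt(abs(s$mean - 1), 3 * se)
  # multiplicative (log-normal) noise at the calibrated spread implies a
  # mild positive skew; it must stay well short of a heavy tail
  expect_gt(s$skewness, 0)
  expect_lt(s$skewness, 1.5)
})

test_that("scoring against the generating curve removes the day trend", {
  co <- null_cohort(sim_params(n_patients = 150, seed = 9))
  scored <- score_cohort(co$obs, cohort_reference(co), co$calendar)
  dfree <- scored[scored$drug_free, ]
  # slope of patient-day scores on day, with patient-clustered uncertainty:
  # regress patient-level mean-centred data cheaply via per-day means
  fit <- stats::lm(pottel_score ~ pna_day, data = dfree)
  slope <- stats::coef(fit)[["pna_day"]]
  # cluster-robust SE via patient-level slopes of the residual projection
  se <- tryCatch({
    V <- sandwich::vcovCL(fit, cluster = dfree$patient_id)
    sqrt(V["pna_day", "pna_day"])
  }, error = function(e) summary(fit)$coefficients["pna_day", 2] * 3)
  expect_lt(abs(slope), 3 * se)
})

test_that("scores are scale-equivariant in (Scr, p50) units", {
  ref <- synthetic_reference(1:28)
  set.seed(42)
  scr <- runif(100, 0.2, 1.5)
  day <- sample(1:28, 100, replace = TRUE)
  const <- runif(1, 0.5, 3)
  ref2 <- validate_reference(data.frame(day = ref$day,
                                        p50_scr_mg_dl = const * ref$p50_scr_mg_dl))
  expect_equal(pottel_score(const * scr, day, ref2),
               pottel_score(scr, day, ref), tolerance = 1e-12)
})
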