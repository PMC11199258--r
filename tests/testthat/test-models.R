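# shared small fixtures: one moderate synthetic cohort per effect regime
make_scored <- function(params) {
  co <- simulate_cohort(params)
  list(cohort = co,
       scored = score_cohort(co$obs, cohort_reference(co), co$calendar))
}

test_that("day contrasts follow the closed form beta_e + beta_i * log(d)", {
  x <- make_scored(sim_params(n_patients = 80, seed = 31))
  fit <- fit_daywise_model(x$scored, x$cohort$calendar, "ibuprofen")
  beta <- lme4::fixef(fit$fit)
  eff <- suppressWarnings(estimate_day_contrasts(fit, c(4, 7, 12)))
  want <- beta[["exposed"]] + beta[["t_day:exposed"]] * log(c(4, 7, 12))
  expect_equal(eff$diff, want, tolerance = 1e-6)
  expect_equal(eff$mean_exposed - eff$mean_unexposed, eff$diff)
  expect_true(all(eff$ci_lo <= eff$diff & eff$diff <= eff$ci_hi))
  expect_true(all(eff$p_value > 0 & eff$p_value <= 1))

  # no extrapolation beyond the observed day range
  expect_error(estimate_day_contrasts(fit, 40), "extrapolate")
})

test_that("near-noiseless data reproduce the injected coefficients", {
  # tiny noise, constant multiplicative effect 1.2: estimated day-wise
  # difference must sit on the generator's effect within a tight tolerance
  params <- sim_params(n_patients = 60, seed = 32,
                       sigma_b = 0.01, sigma_s = 0.002, sigma_e = 0.01,
                       ibu_effect = rep(1.2, 5), abx_effect = rep(1, 5))
  x <- make_scored(params)
  fit <- fit_daywise_model(x$scored, x$cohort$calendar, "ibuprofen")
  eff <- suppressWarnings(estimate_day_contrasts(fit, 5))
  expect_equal(eff$diff, 0.2, tolerance = 0.02)
})

test_that("model preconditions and fallbacks are enforced", {
  one <- tibble::tibble(patient_id = "a", pna_day = 1:6, scr_mg_dl = 0.6,
                        pottel_score = 1, drug_free = TRUE)
  expect_error(fit_daywise_model(one, empty_calendar(), "ibuprofen"),
               "at least 2 patients")

  # singular random-effects structure triggers a recorded downgrade
  params <- sim_params(n_patients = 40, seed = 33, sigma_s = 0, sigma_b = 0.001)
  x <- make_scored(params)
  fit <- fit_daywise_model(x$scored, x$cohort$calendar, "ibuprofen")
  expect_true(fit$downgraded)
  expect_match(fit$re_structure, "intercept")
})

test_that("cumulative model: category means, merging, degenerate input", {
  x <- make_scored(sim_params(n_patients = 120, seed = 34))
  cm <- fit_cumulative_model(x$scored, x$cohort$calendar, "ibuprofen")
  eff <- cm$effects
  expect_equal(eff$day_or_category[1], "0")
  expect_equal(eff$diff[1], 0)
  expect_true(all(is.na(eff$p_value[1])))
  expect_true(all(eff$mean_ci_lo <= eff$mean_exposed &
                    eff$mean_exposed <= eff$mean_ci_hi))
  # category-vs-0 contrast equals the category mean minus the baseline mean
  expect_equal(eff$diff[-1], eff$mean_exposed[-1] - eff$mean_unexposed[-1],
               tolerance = 1e-10)

  # no drug given at all: only category 0, no contrasts
  co0 <- simulate_cohort(sim_params(n_patients = 30, seed = 35,
                                    p_ibuprofen = 0, p_abx_episode = 0))
  sc0 <- score_cohort(co0$obs, cohort_reference(co0), co0$calendar)
  cm0 <- fit_cumulative_model(sc0, co0$calendar, "ibuprofen")
  expect_equal(cm0$effects$day_or_category, "0")

  # a category observed once merges upward and is logged
  cal <- as_exposure_calendar(tibble::tibble(
    patient_id = "p1", drug = "ibuprofen", pna_day = 2:3))
  obs <- tidyr::expand_grid(patient_id = sprintf("p%d", 1:12), pna_day = 1:8) |>
    dplyr::mutate(scr_mg_dl = 0.6 + 0.01 * (seq_along(pna_day) %% 7))
  ref <- validate_reference(data.frame(day = 1:8, p50_scr_mg_dl = rep(0.6, 8)))
  scored <- score_cohort(obs, ref, cal)
  cm1 <- fit_cumulative_model(scored, cal, "ibuprofen")
  expect_true(length(cm1$fit$merged_categories) >= 1)
})

test_that("co-drug adjustment changes nothing without co-exposure, and
           collinear exposures are refused", {
  params <- sim_params(n_patients = 60, seed = 36, p_abx_episode = 0,
                       abx_follow_ibu_prob = 0)
  x <- make_scored(params)
  un <- fit_daywise_model(x$scored, x$cohort$calendar, "ibuprofen")
  ad <- fit_daywise_model(x$scored, x$cohort$calendar, "ibuprofen",
                          adjust_group = DRUG_GROUPS$antibiotics)
  expect_equal(lme4::fixef(un$fit), lme4::fixef(ad$fit))
  e_un <- suppressWarnings(estimate_day_contrasts(un, 5))
  e_ad <- suppressWarnings(estimate_day_contrasts(ad, 5))
  expect_equal(e_un$diff, e_ad$diff)

  # identical administration days for both drugs in every patient
  cal <- as_exposure_calendar(dplyr::bind_rows(
    tibble::tibble(patient_id = rep(c("a", "b"), each = 3),
                   drug = "ibuprofen", pna_day = rep(2:4, 2)),
    tibble::tibble(patient_id = rep(c("a", "b"), each = 3),
                   drug = "amikacin", pna_day = rep(2:4, 2))))
  obs <- tidyr::expand_grid(patient_id = c("a", "b"), pna_day = 1:8) |>
    dplyr::mutate(scr_mg_dl = 0.6)
  ref <- validate_reference(data.frame(day = 1:8, p50_scr_mg_dl = rep(0.6, 8)))
  scored <- score_cohort(obs, ref, cal)
  expect_error(
    fit_daywise_model(scored, cal, "ibuprofen", adjust_group = "amikacin"),
    "collinear")
})

test_that("effect tables are invariant to patient relabeling and row order", {
  x <- make_scored(sim_params(n_patients = 60, seed = 37))
  eff1 <- suppressWarnings(estimate_day_contrasts(
    fit_daywise_model(x$scored, x$cohort$calendar, "ibuprofen"), c(4, 8)))
  relabel <- setNames(sprintf("Z%03d", seq_along(unique(x$scored$patient_id))),
                      sample(unique(x$scored$patient_id)))
  scored2 <- x$scored |>
    dplyr::mutate(patient_id = unname(relabel[patient_id])) |>
    dplyr::arrange(pottel_score)
  cal2 <- x$cohort$calendar |>
    dplyr::mutate(patient_id = unname(relabel[patient_id])) |>
    as_exposure_calendar()
  eff2 <- suppressWarnings(estimate_day_contrasts(
    fit_daywise_model(scored2, cal2, "ibuprofen"), c(4, 8)))
  expect_equal(eff1$diff, eff2$diff, tolerance = 1e-6)
  expect_equal(eff1$p_value, eff2$p_value, tolerance = 1e-4)
})

test_that("log-time model is preferred by AIC on log-trended data", {
  # score the cohort against a reference deflated by d^-0.1 so the true
  # score trend is exp(0.1 * log d): log-linear in time
  wins <- 0L
  for (s in 1:10) {
    co <- null_cohort(sim_params(n_patients = 60, seed = 400 + s))
    gt <- co$ground_truth$reference
    ref <- validate_reference(data.frame(
      day = gt$day, p50_scr_mg_dl = gt$q * gt$day^-0.1))
    scored <- score_cohort(co$obs, ref, co$calendar)
    f_log <- fit_daywise_model(scored, co$calendar, "ibuprofen",
                               time_scale = "log")
    f_lin <- fit_daywise_model(scored, co$calendar, "ibuprofen",
                               time_scale = "linear")
    wins <- wins + (glance(f_log)$AIC <= glance(f_lin)$AIC)
  }
  expect_gte(wins, 9L)
})

test_that("tidy and glance expose the fit the broom way", {
  x <- make_scored(sim_params(n_patients = 50, seed = 38))
  fit <- fit_daywise_model(x$scored, x$cohort$calendar, "ibuprofen")
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "std.error", "p.value") %in% names(td)))
  expect_true("exposed" %in% td$term)
  gl <- glance(fit)
  expect_equal(gl$n_patients, 50L)
  expect_true(is.finite(gl$AIC))
})
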