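#' Build the per-observation model frame for a drug analysis
#'
#' Joins scored observations with the exposure coding for a drug group:
#' the lag-1 binary indicator (`exposed`), the consecutive-days category
#' (`consec`), the time variable `t_day` (log of postnatal day by default),
#' and, when an adjustment group is given, the co-drug's lag indicator
#' (`adj_exposed`).
#'
#' @param scored Output of [score_cohort()].
#' @param calendar Exposure calendar.
#' @param drug_group Primary drug group (name from [DRUG_GROUPS] or drug
#'   vector).
#' @param adjust_group Optional co-drug group for confounding adjustment.
#' @param time_scale `"log"` (default) or `"linear"` time.
#' @return Tibble ready for model fitting.
#' @export
build_model_frame <- function(scored, calendar, drug_group,
                              adjust_group = NULL,
                              time_scale = c("log", "linear")) {
  time_scale <- match.arg(time_scale)
  calendar <- as_exposure_calendar(calendar)
  k <- consecutive_days_ending_lag1(calendar, scored$patient_id,
                                    drug_group, scored$pna_day)
  out <- scored %>%
    mutate(
      t_day = if (time_scale == "log") log(.data$pna_day) else as.numeric(.data$pna_day),
      exposed = as.integer(k >= 1L),
      consec = consec_category(k)
    )
  if (!is.null(adjust_group)) {
    out$adj_exposed <- lag_indicator(calendar, scored$patient_id,
                                     adjust_group, scored$pna_day)
    if (sum(out$adj_exposed) > 0 &&
        all(out$adj_exposed == out$exposed)) {
      abort("primary and adjustment exposure indicators are identical across all rows (collinear); adjustment is not identifiable")
    }
  }
  attr(out, "time_scale") <- time_scale
  out
}

# Random-effects fallback ladder: correlated intercept+slope -> uncorrelated
# -> intercept only. A structure is rejected on error or singular fit.
fit_re_ladder <- function(fixed_rhs, data) {
  ladder <- c("(1 + t_day | patient_id)",
              "(1 + t_day || patient_id)",
              "(1 | patient_id)")
  labels <- c("intercept+slope", "intercept+slope (uncorrelated)",
              "intercept only")
  ctrl <- lme4::lmerControl(calc.derivs = FALSE)
  for (j in seq_along(ladder)) {
    f <- stats::as.formula(paste("pottel_score ~", fixed_rhs, "+", ladder[j]))
    fit <- tryCatch(
      suppressMessages(lme4::lmer(f, data = data, REML = TRUE, control = ctrl)),
      error = function(e) NULL
    )
    if (!is.null(fit) && !lme4::isSingular(fit, tol = 1e-4)) {
      return(list(fit = fit, re_structure = labels[j], downgraded = j > 1))
    }
    if (!is.null(fit) && j == length(ladder)) {
      return(list(fit = fit, re_structure = labels[j], downgraded = TRUE))
    }
  }
  abort("linear mixed model failed to converge under all random-effects structures")
}

new_pottel_lmm <- function(fit, frame, coding, drug_group, adjust_group,
                           re_info, merged = NULL) {
  exposed_patients_by_day <- frame %>%
    filter(.data$exposed == 1L) %>%
    group_by(.data$pna_day) %>%
    summarise(n_exposed_patients = n_distinct(.data$patient_id),
              .groups = "drop")
  structure(
    list(
      fit = fit,
      coding = coding,
      drug_group = drug_group,
      adjust_group = adjust_group,
      re_structure = re_info$re_structure,
      downgraded = re_info$downgraded,
      time_scale = attr(frame, "time_scale"),
      day_range = range(frame$pna_day),
      t_day_mean = mean(frame$t_day),
      n_obs = nrow(frame),
      n_patients = n_distinct(frame$patient_id),
      exposed_patients_by_day = exposed_patients_by_day,
      merged_categories = merged
    ),
    class = "pottel_lmm"
  )
}

check_model_preconditions <- function(frame) {
  per_pat <- count(frame, .data$patient_id)
  if (sum(per_pat$n >= 2) < 2) {
    abort("need at least 2 patients with at least 2 observations each")
  }
}

#' Fit the day-wise drug-exposure linear mixed model
#'
#' Models the Pottel score as a function of time (log postnatal day),
#' the lag-1 binary drug exposure, and their interaction, with per-patient
#' random intercept and random slope on the same time scale, estimated by
#' restricted maximum likelihood. The interaction lets the exposed-vs-
#' unexposed difference grow or shrink with postnatal age. When an adjustment
#' group is supplied, the co-drug's lag indicator and its time interaction
#' enter the fixed effects (multivariable confounding adjustment).
#'
#' If the full random-intercept-and-slope structure is singular or fails, the
#' fit falls back to an uncorrelated structure and then to intercept-only;
#' any downgrade is recorded in the returned object.
#'
#' @inheritParams build_model_frame
#' @return An object of class `pottel_lmm`.
#' @export
fit_daywise_model <- function(scored, calendar, drug_group,
                              adjust_group = NULL,
                              time_scale = c("log", "linear")) {
  time_scale <- match.arg(time_scale)
  frame <- build_model_frame(scored, calendar, drug_group,
                             adjust_group = adjust_group,
                             time_scale = time_scale)
  check_model_preconditions(frame)
  rhs <- "t_day * exposed"
  if (!is.null(adjust_group) && sum(frame$adj_exposed) > 0) {
    rhs <- paste(rhs, "+ t_day * adj_exposed")
  }
  re_info <- fit_re_ladder(rhs, frame)
  new_pottel_lmm(re_info$fit, frame, coding = "lag1_binary",
                 drug_group = drug_group, adjust_group = adjust_group,
                 re_info = re_info)
}

time_transform <- function(object, day) {
  if (object$time_scale == "log") log(day) else as.numeric(day)
}

#' Exposed-vs-unexposed contrasts at chosen postnatal days
#'
#' From a fitted day-wise model, computes the model-based mean Pottel score
#' for exposed and unexposed infants at each requested day, their difference
#' `beta_exposed + beta_interaction * t(day)`, a 95% Wald confidence interval
#' from the fixed-effect covariance, and the two-sided p-value. Any co-drug
#' adjustment indicator is fixed at 0 (unexposed to the co-drug). Days
#' outside the fitted data's range are an error, and days on which fewer
#' than `min_exposed_patients` distinct patients were exposed are dropped
#' (estimates there would rest on almost no data).
#'
#' @param object A `pottel_lmm` from [fit_daywise_model()].
#' @param days Integer vector of postnatal days to evaluate.
#' @param level Confidence level (default 0.95).
#' @param min_exposed_patients Minimum distinct exposed patients required at
#'   a day for it to be reported (default 2).
#' @return An effect table tibble: `analysis`, `drug_group`,
#'   `day_or_category`, `mean_exposed`, `mean_unexposed`, `diff`, `ci_lo`,
#'   `ci_hi`, `p_value`.
#' @export
estimate_day_contrasts <- function(object, days, level = 0.95,
                                   min_exposed_patients = 2) {
  stopifnot(inherits(object, "pottel_lmm"), object$coding == "lag1_binary")
  days <- as.integer(days)
  if (any(days < object$day_range[1] | days > object$day_range[2])) {
    abort(paste0("requested day(s) outside the fitted range [",
                 object$day_range[1], ", ", object$day_range[2],
                 "]; refusing to extrapolate"))
  }
  ok <- object$exposed_patients_by_day %>%
    filter(.data$n_exposed_patients >= min_exposed_patients) %>%
    pull(.data$pna_day)
  dropped <- setdiff(days, ok)
  if (length(dropped) > 0) {
    warn(paste0("dropping day(s) with < ", min_exposed_patients,
                " exposed patients: ", paste(dropped, collapse = ", ")))
    days <- intersect(days, ok)
  }
  beta <- lme4::fixef(object$fit)
  V <- as.matrix(vcov(object$fit))
  z <- qnorm(1 - (1 - level) / 2)
  out <- purrr::map_dfr(days, function(d) {
    td <- time_transform(object, d)
    l_diff <- setNames(numeric(length(beta)), names(beta))
    l_diff["exposed"] <- 1
    l_diff["t_day:exposed"] <- td
    l_un <- setNames(numeric(length(beta)), names(beta))
    l_un["(Intercept)"] <- 1
    l_un["t_day"] <- td
    diff <- sum(l_diff * beta)
    se <- sqrt(drop(t(l_diff) %*% V %*% l_diff))
    mu0 <- sum(l_un * beta)
    tibble(
      analysis = "daywise",
      drug_group = paste(resolve_drug_group(object$drug_group), collapse = "+"),
      day_or_category = as.character(d),
      mean_exposed = mu0 + diff,
      mean_unexposed = mu0,
      diff = diff,
      ci_lo = diff - z * se,
      ci_hi = diff + z * se,
      p_value = 2 * pnorm(-abs(diff / se))
    )
  })
  class(out) <- c("pottel_effects", class(out))
  out
}

#' Fit the cumulative consecutive-days exposure model
#'
#' Models the Pottel score as an effect of the number of consecutive days of
#' drug administration (categories 0, 1, 2, 3, 4, 5+, reference 0), with the
#' same log-time fixed effect, random-effects structure, and fallback ladder
#' as the day-wise model. Categories observed fewer than `min_obs_per_cat`
#' times are merged upward into the next category (the top category merges
#' downward), and the merges are recorded. Category means are evaluated at
#' the mean log-day of the fitted data, with any co-drug indicator fixed at
#' 0; each category is contrasted against category 0.
#'
#' @inheritParams build_model_frame
#' @param min_obs_per_cat Minimum observations per category (default 2).
#' @param level Confidence level for the effect table (default 0.95).
#' @return List with `fit` (a `pottel_lmm`) and `effects` (the category
#'   effect table).
#' @export
fit_cumulative_model <- function(scored, calendar, drug_group,
                                 adjust_group = NULL,
                                 min_obs_per_cat = 2,
                                 level = 0.95) {
  frame <- build_model_frame(scored, calendar, drug_group,
                             adjust_group = adjust_group, time_scale = "log")
  check_model_preconditions(frame)

  # merge sparse categories upward (top category merges into the one below)
  merged <- character(0)
  lv <- levels(frame$consec)
  for (j in seq(2, length(lv))) {
    cnt <- sum(frame$consec == lv[j], na.rm = TRUE)
    if (cnt > 0 && cnt < min_obs_per_cat) {
      target <- if (j < length(lv)) lv[j + 1] else lv[j - 1]
      frame$consec[frame$consec == lv[j]] <- target
      merged <- c(merged, paste0(lv[j], "->", target))
    }
  }
  frame$consec <- droplevels(frame$consec)

  if (nlevels(frame$consec) == 1) {
    re_info <- fit_re_ladder("t_day", frame)
    fit <- new_pottel_lmm(re_info$fit, frame, coding = "consecutive_category",
                          drug_group = drug_group, adjust_group = adjust_group,
                          re_info = re_info, merged = merged)
    return(list(fit = fit, effects = cumulative_effects(fit, level)))
  }

  rhs <- "t_day + consec"
  if (!is.null(adjust_group) && sum(frame$adj_exposed) > 0) {
    rhs <- paste(rhs, "+ t_day * adj_exposed")
  }
  re_info <- fit_re_ladder(rhs, frame)
  fit <- new_pottel_lmm(re_info$fit, frame, coding = "consecutive_category",
                        drug_group = drug_group, adjust_group = adjust_group,
                        re_info = re_info, merged = merged)
  fit$consec_levels <- levels(frame$consec)
  list(fit = fit, effects = cumulative_effects(fit, level))
}

cumulative_effects <- function(object, level = 0.95) {
  beta <- lme4::fixef(object$fit)
  V <- as.matrix(vcov(object$fit))
  z <- qnorm(1 - (1 - level) / 2)
  lv <- object$consec_levels %||% "0"
  L <- mean(object$t_day_mean)
  base <- setNames(numeric(length(beta)), names(beta))
  base["(Intercept)"] <- 1
  base["t_day"] <- L
  grp <- paste(resolve_drug_group(object$drug_group), collapse = "+")
  out <- purrr::map_dfr(lv, function(cc) {
    l <- base
    nm <- paste0("consec", cc)
    if (cc != "0") l[nm] <- 1
    mu <- sum(l * beta)
    se_mu <- sqrt(drop(t(l) %*% V %*% l))
    if (cc == "0") {
      d <- 0; se_d <- NA_real_; pv <- NA_real_
      lo <- NA_real_; hi <- NA_real_
    } else {
      d <- beta[nm]
      se_d <- sqrt(V[nm, nm])
      lo <- d - z * se_d; hi <- d + z * se_d
      pv <- 2 * pnorm(-abs(d / se_d))
    }
    tibble(
      analysis = "cumulative",
      drug_group = grp,
      day_or_category = cc,
      mean_exposed = mu,
      mean_unexposed = sum(base * beta),
      mean_ci_lo = mu - z * se_mu,
      mean_ci_hi = mu + z * se_mu,
      diff = unname(d),
      ci_lo = unname(lo),
      ci_hi = unname(hi),
      p_value = unname(pv)
    )
  })
  class(out) <- c("pottel_effects", class(out))
  out
}

#' Confounding-adjusted analysis of one drug corrected for another
#'
#' Fits the multivariable model including both the primary drug's and the
#' adjustment group's exposure terms, and returns the primary drug's effect
#' table. If the adjustment group has no administrations at all, the fit is
#' identical to the unadjusted analysis. Identical exposure indicators
#' (perfect collinearity) are an error.
#'
#' @inheritParams build_model_frame
#' @param analysis `"daywise"` or `"cumulative"`.
#' @param days Days to evaluate (day-wise analysis only).
#' @param ... Passed on to the underlying fit function.
#' @return An effect table tibble (day-wise), or the [fit_cumulative_model()]
#'   list (cumulative).
#' @export
adjusted_analysis <- function(scored, calendar, drug_group, adjust_group,
                              analysis = c("daywise", "cumulative"),
                              days = NULL, ...) {
  analysis <- match.arg(analysis)
  if (analysis == "daywise") {
    fit <- fit_daywise_model(scored, calendar, drug_group,
                             adjust_group = adjust_group, ...)
    if (is.null(days)) {
      days <- seq(object_min_day(fit), object_max_day(fit))
    }
    estimate_day_contrasts(fit, days)
  } else {
    fit_cumulative_model(scored, calendar, drug_group,
                         adjust_group = adjust_group, ...)
  }
}

object_min_day <- function(object) object$day_range[1]
object_max_day <- function(object) object$day_range[2]

#' @export
print.pottel_lmm <- function(x, ...) {
  cat("Pottel-score linear mixed model (", x$coding, ")\n", sep = "")
  cat("  drug group:", paste(resolve_drug_group(x$drug_group), collapse = "+"))
  if (!is.null(x$adjust_group)) {
    cat(" | adjusted for:", paste(resolve_drug_group(x$adjust_group), collapse = "+"))
  }
  cat("\n  random effects:", x$re_structure,
      if (isTRUE(x$downgraded)) "(downgraded)" else "", "\n")
  cat(sprintf("  %d observations, %d patients, days %d-%d\n",
              x$n_obs, x$n_patients, x$day_range[1], x$day_range[2]))
  print(lme4::fixef(x$fit))
  invisible(x)
}

#' Tidy the fixed effects of a Pottel-score mixed model
#'
#' @param x A `pottel_lmm`.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value` (Wald normal).
#' @export
tidy.pottel_lmm <- function(x, ...) {
  beta <- lme4::fixef(x$fit)
  se <- sqrt(diag(as.matrix(vcov(x$fit))))
  tibble(
    term = names(beta),
    estimate = unname(beta),
    std.error = unname(se),
    statistic = unname(beta / se),
    p.value = 2 * pnorm(-abs(unname(beta / se)))
  )
}

#' One-row model summary
#'
#' @param x A `pottel_lmm`.
#' @param ... Unused.
#' @return Tibble with fit information: `nobs`, `n_patients`, `AIC`,
#'   `logLik`, `sigma`, `re_structure`, `downgraded`.
#' @export
glance.pottel_lmm <- function(x, ...) {
  tibble(
    nobs = x$n_obs,
    n_patients = x$n_patients,
    AIC = AIC(x$fit),
    logLik = as.numeric(logLik(x$fit)),
    sigma = stats::sigma(x$fit),
    re_structure = x$re_structure,
    downgraded = isTRUE(x$downgraded)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
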