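#' Plot an effect table
#'
#' Day-wise rows are drawn as exposed/unexposed mean curves over postnatal
#' day with the difference's confidence band; cumulative rows as category
#' means with 95% intervals, mirroring the standard presentation of these
#' analyses.
#'
#' @param object A `pottel_effects` effect table.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pottel_effects <- function(object, ...) {
  df <- as_tibble(object)
  if (all(df$analysis == "cumulative")) {
    df$day_or_category <- factor(df$day_or_category, levels = CONSEC_LEVELS)
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$day_or_category,
                                          y = .data$mean_exposed)) +
      ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean_ci_lo,
                                            ymax = .data$mean_ci_hi)) +
      ggplot2::labs(x = "consecutive days of administration (lagged)",
                    y = "estimated mean Pottel score")
  } else {
    dw <- filter(df, .data$analysis == "daywise") %>%
      mutate(day = as.integer(.data$day_or_category))
    p <- ggplot2::ggplot(dw, ggplot2::aes(x = .data$day)) +
      ggplot2::geom_ribbon(ggplot2::aes(
        ymin = .data$mean_unexposed + .data$ci_lo,
        ymax = .data$mean_unexposed + .data$ci_hi), alpha = 0.2) +
      ggplot2::geom_line(ggplot2::aes(y = .data$mean_unexposed,
                                      linetype = "unexposed")) +
      ggplot2::geom_line(ggplot2::aes(y = .data$mean_exposed,
                                      linetype = "exposed")) +
      ggplot2::labs(x = "postnatal day", y = "estimated mean Pottel score",
                    linetype = NULL)
  }
  if (length(unique(df$drug_group)) > 1 || length(unique(df$analysis)) > 1) {
    p <- p + ggplot2::facet_grid(analysis ~ drug_group, scales = "free_x")
  }
  p + ggplot2::theme_minimal()
}

#' Spaghetti plot of scored creatinine trajectories
#'
#' @param scored Output of [score_cohort()].
#' @param what `"pottel_score"` (default) or `"scr_mg_dl"`.
#' @param max_patients Subsample of patients to draw (default 60).
#' @return A ggplot object.
#' @export
plot_trajectories <- function(scored, what = c("pottel_score", "scr_mg_dl"),
                              max_patients = 60) {
  what <- match.arg(what)
  ids <- unique(scored$patient_id)
  if (length(ids) > max_patients) ids <- head(ids, max_patients)
  df <- filter(scored, .data$patient_id %in% ids)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pna_day, y = .data[[what]],
                                   group = .data$patient_id)) +
    ggplot2::geom_line(alpha = 0.25) +
    ggplot2::geom_hline(yintercept = if (what == "pottel_score") 1 else NA,
                        linetype = 2, na.rm = TRUE) +
    ggplot2::labs(x = "postnatal day",
                  y = if (what == "pottel_score") "Pottel score" else "Scr (mg/dL)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
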