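#' Forest plot of GEE coefficients
#'
#' @param object A `crp_gee` fit.
#' @param conf_level Confidence level for the intervals.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.crp_gee <- function(object, conf_level = 0.95, ...) {
  td <- tidy(object, conf_level = conf_level) |>
    dplyr::filter(.data$term != "(Intercept)")
  ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate,
                                   y = stats::reorder(.data$term, .data$estimate))) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::labs(
      x = "Coefficient on log serum CRP (95% CI)", y = NULL,
      title = sprintf("GEE %s (%s exposure, stratum %s)",
                      object$design_meta$model_id,
                      object$design_meta$exposure_coding,
                      object$design_meta$stratum)
    ) +
    ggplot2::theme_minimal()
}

#' Bar chart of ACE variance fractions
#'
#' @param object A `crp_ace` fit.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.crp_ace <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$component, y = .data$estimate)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$conf.low, ymax = .data$conf.high),
      width = 0.2, na.rm = TRUE
    ) +
    ggplot2::labs(x = NULL, y = "Fraction of log-CRP variance",
                  title = "ACE decomposition of CRP levels") +
    ggplot2::theme_minimal()
}

#' Mean log-CRP by victimization exposure, optionally by sex
#'
#' Group means of log serum CRP with standard-error bars across the
#' winsorized exposure categories.
#'
#' @param table Analysis-ready cohort tibble.
#' @param by_sex Facet the plot by sex?
#' @return A ggplot.
#' @export
plot_exposure_crp <- function(table, by_sex = FALSE) {
  grp <- if (by_sex) c("victimization_category", "sex") else "victimization_category"
  dat <- table |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(
      mean_log_crp = mean(.data$log_crp),
      se = sd(.data$log_crp) / sqrt(dplyr::n()),
      .groups = "drop"
    )
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$victimization_category,
                                         y = .data$mean_log_crp)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_log_crp - .data$se,
                   ymax = .data$mean_log_crp + .data$se),
      width = 0.15
    ) +
    ggplot2::labs(x = "Childhood victimization", y = "Mean log serum CRP") +
    ggplot2::theme_minimal()
  if (by_sex) p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$sex))
  p
}

#' Mean log-CRP by latent genetic score
#'
#' @param table Analysis-ready cohort tibble with `genetic_score`.
#' @return A ggplot.
#' @export
plot_score_crp <- function(table) {
  dat <- table |>
    dplyr::filter(!is.na(.data$genetic_score)) |>
    dplyr::group_by(.data$genetic_score) |>
    dplyr::summarise(
      mean_log_crp = mean(.data$log_crp),
      se = sd(.data$log_crp) / sqrt(dplyr::n()),
      .groups = "drop"
    )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$genetic_score,
                                    y = .data$mean_log_crp)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_log_crp - .data$se,
                   ymax = .data$mean_log_crp + .data$se),
      width = 0.1
    ) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "steelblue") +
    ggplot2::labs(x = "Latent genetic risk score (0-3)",
                  y = "Mean log serum CRP") +
    ggplot2::theme_minimal()
}
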