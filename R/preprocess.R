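#' Blood-spot to serum CRP conversion parameters
#'
#' Affine calibration mapping dried-blood-spot CRP to serum-equivalent CRP:
#' `serum = slope * bloodspot + intercept`. Defaults are the within-study
#' calibration values (slope 6.51, intercept 0.14 mg/L).
#'
#' @param slope Serum units per blood-spot unit; must be positive.
#' @param intercept Serum mg/L at zero blood-spot signal.
#' @return A `conversion_params` list.
#' @export
conversion_params <- function(slope = 6.51, intercept = 0.14) {
  if (!is.numeric(slope) || length(slope) != 1L || slope <= 0) {
    stop_config("invariant violated: conversion `slope` must be a positive scalar")
  }
  structure(list(slope = slope, intercept = intercept), class = "conversion_params")
}

#' Convert blood-spot CRP to serum-equivalent CRP
#'
#' Applies the affine calibration `slope * x + intercept`. Strictly
#' increasing in `x`; vectorized.
#'
#' @param bloodspot_value Non-negative blood-spot CRP value(s).
#' @param params A [conversion_params()] object.
#' @return Serum-equivalent CRP in mg/L.
#' @export
#' @examples
#' dbs_to_serum(0) # 0.14
#' dbs_to_serum(1) # 6.65
dbs_to_serum <- function(bloodspot_value, params = conversion_params()) {
  if (any(is.na(bloodspot_value))) {
    stop_data("blood-spot CRP values must not be missing")
  }
  if (any(bloodspot_value < 0)) {
    stop_data("blood-spot CRP values must be non-negative")
  }
  params$slope * bloodspot_value + params$intercept
}

#' Exclude records with acute-range serum CRP
#'
#' Drops individuals whose serum-equivalent CRP strictly exceeds `threshold`
#' (default 10 mg/L, the conventional acute-inflammation cut), returning the
#' filtered table together with a reconciled exclusion report. All rows must
#' carry a non-missing `serum_crp` value (complete-case requirement).
#'
#' @param table Cohort tibble with a `serum_crp` column.
#' @param threshold Serum mg/L; exclusion is strict (`> threshold`).
#' @return A list with elements `table` (retained rows, original order) and
#'   `report` (an `exclusion_report` with `n_input`, `n_excluded`,
#'   `n_retained`, `threshold`).
#' @export
apply_exclusions <- function(table, threshold = 10) {
  if (!"serum_crp" %in% names(table)) {
    stop_data("`serum_crp` column is required; run dbs_to_serum() first")
  }
  if (any(is.na(table$serum_crp))) {
    stop_data("serum-equivalent CRP is missing for some rows; complete data required")
  }
  keep <- table$serum_crp <= threshold
  report <- structure(
    list(
      n_input = nrow(table),
      n_excluded = sum(!keep),
      n_retained = sum(keep),
      threshold = threshold
    ),
    class = "exclusion_report"
  )
  list(table = table[keep, , drop = FALSE], report = report)
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat(sprintf(
    "<exclusion_report> %d of %d excluded (serum CRP > %g mg/L); N = %d retained\n",
    x$n_excluded, x$n_input, x$threshold, x$n_retained
  ))
  invisible(x)
}

#' Winsorize victimization-type counts into three exposure categories
#'
#' Collapses the 0--5 victimization-type count into the analysis categories
#' `none` (0), `one` (1) and `poly` (2 or more types). Idempotent: a factor
#' already on those levels is returned unchanged.
#'
#' @param count Integer counts in 0--5, or an already-categorized factor.
#' @return Ordered factor with levels `none < one < poly`.
#' @export
#' @examples
#' winsorize_victimization(c(0, 1, 5))
winsorize_victimization <- function(count) {
  lv <- c("none", "one", "poly")
  if (is.factor(count)) {
    if (identical(levels(count), lv)) {
      return(factor(count, levels = lv, ordered = TRUE))
    }
    stop_data("factor input must already use levels none/one/poly")
  }
  if (any(is.na(count)) || any(count < 0 | count > 5 | count != round(count))) {
    stop_data("victimization counts must be integers between 0 and 5")
  }
  factor(lv[pmin(count, 2) + 1], levels = lv, ordered = TRUE)
}

#' Derive analysis variables on the post-exclusion sample
#'
#' Adds, in place: natural-log serum CRP (`log_crp`); the winsorized exposure
#' category (`victimization_category`); the high-CRP indicator (`high_crp`),
#' defined as membership in the top tertile of the post-exclusion serum
#' distribution; and mean-imputed `waist_hip_ratio` / `body_temp` (sample-wide
#' means of the observed values). The tertile cut is rank based: rows are
#' ranked by serum CRP with ties broken by stable record order (later rows rank
#' higher), and the top `ceiling(n/3)` ranks are flagged.
#'
#' @param table Post-exclusion cohort tibble with `serum_crp`.
#' @param log_base Base of the CRP log transform (default natural log).
#' @return The input tibble with analysis columns added; row count unchanged.
#' @export
derive_analysis_variables <- function(table, log_base = exp(1)) {
  if (!"serum_crp" %in% names(table)) {
    stop_data("`serum_crp` column is required; run dbs_to_serum() first")
  }
  n <- nrow(table)
  r <- rank(table$serum_crp, ties.method = "first")
  out <- table |>
    dplyr::mutate(
      log_crp = log(.data$serum_crp, base = log_base),
      victimization_category = winsorize_victimization(.data$victimization_count),
      high_crp = r > n - ceiling(n / 3)
    )
  for (col in c("waist_hip_ratio", "body_temp")) {
    if (!col %in% names(out)) next
    x <- out[[col]]
    if (all(is.na(x))) {
      stop_data(sprintf("all `%s` values are missing; no sample mean defined", col))
    }
    x[is.na(x)] <- mean(x, na.rm = TRUE)
    out[[col]] <- x
  }
  out
}

#' Run the full CRP preprocessing chain
#'
#' Convenience wrapper applying, in order: blood-spot to serum conversion,
#' the acute-range exclusion, and derivation of analysis variables.
#'
#' @inheritParams apply_exclusions
#' @inheritParams derive_analysis_variables
#' @param conversion A [conversion_params()] object.
#' @return A list with `table` (analysis-ready tibble) and `report`
#'   (the `exclusion_report`).
#' @export
preprocess_cohort <- function(table, conversion = conversion_params(),
                              threshold = 10, log_base = exp(1)) {
  check_cohort_schema(table)
  table$serum_crp <- dbs_to_serum(table$bloodspot_crp, conversion)
  excl <- apply_exclusions(table, threshold = threshold)
  list(
    table = derive_analysis_variables(excl$table, log_base = log_base),
    report = excl$report
  )
}
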