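#' Pipeline configuration
#'
#' Bundles everything needed for an end-to-end run: either a generator spec
#' or a path to an input cohort CSV (exactly one of the two), the blood-spot
#' conversion, the acute-range exclusion threshold, the model ladder, the
#' strata to fit, and an optional output directory for on-disk artifacts.
#'
#' @param spec A [cohort_spec()], or `NULL` when reading from `input_csv`.
#' @param input_csv Path to a cohort CSV, or `NULL` when generating.
#' @param conversion [conversion_params()].
#' @param exclusion_threshold Serum mg/L (strictly greater-than rule); must
#'   be positive.
#' @param models Character vector of ladder rungs to fit (see
#'   [build_model_design()]).
#' @param strata Strata for the ladder fits (default `"F"`, the stratum in
#'   which the exposure association concentrates; linear-trend fits are always
#'   produced for `all`, `F` and `M`).
#' @param seed Optional integer overriding `spec$seed`.
#' @param output_dir Optional directory; when given, the cohort, analysis
#'   table, report JSON and formatted ladder table are written there.
#' @return A `crp_config` list.
#' @export
pipeline_config <- function(spec = NULL, input_csv = NULL,
                            conversion = conversion_params(),
                            exclusion_threshold = 10,
                            models = c("baseline", "model1", "model2",
                                       "model3", "model4"),
                            strata = "F",
                            seed = NULL,
                            output_dir = NULL) {
  if (is.null(spec) == is.null(input_csv)) {
    stop_config("provide exactly one of `spec` or `input_csv`")
  }
  if (!is.numeric(exclusion_threshold) || exclusion_threshold <= 0) {
    stop_config("invariant violated: `exclusion_threshold` must be positive")
  }
  bad <- setdiff(models, c("baseline", "model1", "model2", "model3", "model4"))
  if (length(bad) > 0) {
    stop_config(sprintf("unknown model id(s): %s", paste(bad, collapse = ", ")))
  }
  if (!is.null(spec)) {
    validate_cohort_spec(spec)
    if (!is.null(seed)) spec$seed <- as.integer(seed)
  }
  structure(
    list(spec = spec, input_csv = input_csv, conversion = conversion,
         exclusion_threshold = exclusion_threshold, models = models,
         strata = strata, output_dir = output_dir),
    class = "crp_config"
  )
}

#' Run the full genetically sensitive analysis pipeline
#'
#' Executes the four-step analysis sequence on a generated or supplied twin
#' cohort: (1) preprocess CRP (conversion, acute-range exclusion, log
#' transform, tertile flag, mean imputation) and test whether victimization
#' predicts log-CRP; (2) stratify by sex, including the exposure-by-sex
#' interaction test; (3) quantify genetic influence (within-pair
#' correlations, ML ACE decomposition, latent-score validation); (4) fit the
#' covariate ladder testing whether the association survives adjustment for
#' the latent genetic score and the other risk factors. Identical config and
#' seed yield an identical report.
#'
#' @param config A [pipeline_config()].
#' @param ace_ci CI method forwarded to [fit_ace()] (`"profile"` by default;
#'   use `"none"` to skip the profile search on very large cohorts).
#' @return A `crp_report` list: `exclusions`, `correlations`, `ace`,
#'   `score_validation`, `linear_fits`, `interaction`, `ladder_fits`,
#'   `table1`, the analysis `table`, record-count bookkeeping and a
#'   `provenance` block (config hash, seed, package version).
#' @export
run_pipeline <- function(config, ace_ci = "profile") {
  if (!inherits(config, "crp_config")) {
    stop_config("`config` must come from pipeline_config()")
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
            class = "twincrp_pipeline_error", parent = e)
    })
  }

  cohort <- stage("input", {
    if (!is.null(config$spec)) {
      generate_cohort(config$spec, conversion = config$conversion)
    } else {
      read_cohort_csv(config$input_csv)
    }
  })

  pre <- stage("preprocess", preprocess_cohort(
    cohort, conversion = config$conversion, threshold = config$exclusion_threshold
  ))
  analysis <- stage("genetic_score", add_cotwin_score(pre$table))
  n_unscored <- sum(is.na(analysis$genetic_score))
  scored <- dplyr::filter(analysis, !is.na(.data$genetic_score))

  correlations <- stage("twin_correlations", within_pair_correlations(analysis))
  ace <- stage("ace", fit_ace(analysis, ci = ace_ci))
  score_val <- stage("score_validation", dplyr::bind_rows(
    dplyr::mutate(score_validation(scored), stratum = "all"),
    dplyr::mutate(score_validation(dplyr::filter(scored, .data$sex == "F")),
                  stratum = "F")
  ))

  linear_fits <- stage("linear_gee", purrr::map(
    setNames(c("all", "F", "M"), c("all", "F", "M")),
    function(s) fit_gee(build_model_design(
      analysis, model_id = "baseline", exposure_coding = "linear", stratum = s
    ))
  ))
  interaction <- stage("sex_interaction", sex_interaction_test(analysis))

  ladder_fits <- stage("ladder", {
    out <- list()
    for (s in config$strata) {
      out[[s]] <- purrr::map(
        setNames(config$models, config$models),
        function(m) fit_gee(build_model_design(
          scored, model_id = m, exposure_coding = "categorical", stratum = s
        ))
      )
    }
    out
  })
  table1 <- purrr::map(ladder_fits, table1_report)

  provenance <- list(
    config_hash = rlang::hash(list(
      spec = config$spec, input_csv = config$input_csv,
      conversion = config$conversion, threshold = config$exclusion_threshold,
      models = config$models, strata = config$strata
    )),
    seed = if (!is.null(config$spec)) config$spec$seed else NA_integer_,
    package_version = as.character(utils::packageVersion("twincrp")),
    r_version = paste(R.version$major, R.version$minor, sep = ".")
  )

  report <- structure(
    list(
      exclusions = pre$report,
      n_unscored = n_unscored,
      correlations = correlations,
      ace = ace,
      score_validation = score_val,
      linear_fits = linear_fits,
      interaction = interaction,
      ladder_fits = ladder_fits,
      table1 = table1,
      table = analysis,
      provenance = provenance
    ),
    class = "crp_report"
  )

  if (!is.null(config$output_dir)) {
    stage("output", write_report_artifacts(report, config))
  }
  report
}

write_report_artifacts <- function(report, config) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$output_dir, f)
  write_cohort_csv(report$table, out("analysis_table.csv"))
  if (!is.null(config$spec)) write_cohort_spec(config$spec, out("cohort_spec.yaml"))
  fit_json <- function(fit) list(
    coefficients = as.list(fit$coefficients),
    robust_se = as.list(fit$robust_se),
    p_values = as.list(fit$p_values),
    working_rho = fit$working_rho,
    n_obs = fit$n_obs, n_clusters = fit$n_clusters,
    converged = fit$converged
  )
  jsonlite::write_json(
    list(
      exclusions = unclass(report$exclusions),
      n_unscored = report$n_unscored,
      correlations = report$correlations,
      ace = unclass(report$ace)[c("a_frac", "c_frac", "e_frac", "ci_a",
                                  "minus2ll", "converged",
                                  "n_mz_pairs", "n_dz_pairs")],
      score_validation = report$score_validation,
      linear_fits = purrr::map(report$linear_fits, fit_json),
      interaction = report$interaction,
      ladder_fits = purrr::map(report$ladder_fits, ~ purrr::map(.x, fit_json)),
      provenance = report$provenance
    ),
    out("report.json"), auto_unbox = TRUE, digits = NA, dataframe = "columns"
  )
  for (s in names(report$table1)) {
    readr::write_csv(report$table1[[s]], out(sprintf("table1_%s.csv", s)))
  }
  invisible(config$output_dir)
}

#' @export
print.crp_report <- function(x, ...) {
  cat("<crp_report> genetically sensitive victimization-CRP analysis\n\n")
  print(x$exclusions)
  cat(sprintf("records without scoreable co-twin: %d\n\n", x$n_unscored))
  cat("within-pair correlations (log-CRP):\n")
  print(x$correlations)
  cat("\n")
  print(x$ace)
  cat("\nlatent-score validation:\n")
  print(x$score_validation)
  cat("\nlinear victimization trend (b, robust SE, p) by stratum:\n")
  for (s in names(x$linear_fits)) {
    td <- tidy(x$linear_fits[[s]])
    row <- td[td$term == "victimization_linear", ]
    cat(sprintf("  %-3s b = %6.3f (SE %.3f), 95%% CI %.3f; %.3f, p = %.3g\n",
                s, row$estimate, row$std.error, row$conf.low, row$conf.high,
                row$p.value))
  }
  cat(sprintf("sex-interaction p-value: %.3g\n", x$interaction$p.value))
  for (s in names(x$table1)) {
    cat(sprintf("\ncovariate ladder (stratum %s):\n", s))
    print(x$table1[[s]], n = Inf)
  }
  invisible(x)
}

#' Publication-style model-ladder table
#'
#' Renders a set of ladder fits as one formatted table: rows for the
#' exposure categories and covariates, one column per model, cells showing
#' the unstandardized coefficient with its 95% confidence interval and a
#' significance marker (`*`) when p < 0.05. A missing fit produces blank
#' cells and a warning rather than silent omission.
#'
#' @param fits Named list of `crp_gee` fits (names `baseline`, `model1`, ...,
#'   `model4`; any subset).
#' @return A tibble with a `term` column and one character column per model.
#' @export
table1_report <- function(fits) {
  model_ids <- c("baseline", "model1", "model2", "model3", "model4")
  labels <- c(baseline = "Baseline", model1 = "Model 1", model2 = "Model 2",
              model3 = "Model 3", model4 = "Model 4")
  rows <- tibble::tribble(
    ~term, ~label,
    "victimization_none", "Victimization: none",
    "victimization_one", "Victimization: 1 type",
    "victimization_poly", "Victimization: 2+ types",
    "genetic_score", "Latent genetic score",
    "ses_high", "SES: high",
    "ses_middle", "SES: middle",
    "ses_low", "SES: low",
    "waist_hip_ratio", "Waist-hip ratio",
    "body_temp", "Body temperature"
  )
  out <- tibble::tibble(term = rows$label)
  for (m in intersect(model_ids, union(names(fits), model_ids))) {
    if (!m %in% names(fits) || is.null(fits[[m]])) {
      if (m %in% names(fits)) {
        warn(sprintf("no fit supplied for %s; column left blank", m))
        out[[labels[[m]]]] <- NA_character_
      }
      next
    }
    td <- tidy(fits[[m]])
    cell <- function(tm) {
      if (tm %in% c("victimization_none", "ses_high")) {
        ref_needed <- if (tm == "victimization_none") "victimization_one" else "ses_middle"
        return(if (ref_needed %in% td$term) "Ref" else NA_character_)
      }
      row <- td[td$term == tm, ]
      if (nrow(row) == 0) return(NA_character_)
      sprintf("%.2f (%.2f; %.2f)%s", row$estimate, row$conf.low, row$conf.high,
              if (row$p.value < 0.05) "*" else "")
    }
    out[[labels[[m]]]] <- unname(vapply(rows$term, cell, character(1)))
  }
  out
}
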