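#' Generate a synthetic same-sex twin cohort
#'
#' Draws a cohort of `2 * n_families` individual records with the latent
#' structure the downstream analysis assumes. Per pair: additive-genetic
#' components are bivariate standard normal with correlation 1 (MZ) or 0.5
#' (DZ); one shared-environment draw is common to the pair; unique-environment
#' draws are independent. Victimization counts are drawn at family level from
#' `exposure_probs`, with the second twin redrawing independently with
#' probability `1 - exposure_concordance`. Composite latent log-CRP adds the
#' sex-specific winsorized-category effect, the SES-tertile shift and centered
#' covariate contributions, with raw ACE variances calibrated so the composite
#' is standardized with within-pair covariance `var_a + var_c` (MZ) and
#' `var_a/2 + var_c` (DZ) -- see [cohort_spec()].
#'
#' Serum CRP is `exp(serum_mu + serum_sigma * latent_log_crp)` mg/L; a
#' `contamination_rate` fraction of individuals has serum resampled from an
#' acute-inflammation distribution strictly above 10 mg/L. The stored
#' blood-spot value inverts the serum conversion
#' (`(serum - intercept) / slope`), floored at a small assay detection limit,
#' and is perturbed by multiplicative lognormal noise with coefficient of
#' variation `measurement_cv`. Identical spec and seed give a byte-identical
#' table.
#'
#' @param spec A validated [cohort_spec()].
#' @param conversion Blood-spot/serum conversion parameters
#'   ([conversion_params()]); the generator inverts this equation when
#'   constructing blood-spot values.
#' @return A tibble with two rows per family (columns `family_id`,
#'   `twin_index`, `zygosity`, `sex`, `victimization_count`, `bloodspot_crp`,
#'   `waist_hip_ratio`, `body_temp`, `ses_tertile`, plus generator-internal
#'   truth columns `latent_log_crp` and `contaminated` retained for testing).
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_families = 5, seed = 1))
#' nrow(cohort) # 10
generate_cohort <- function(spec, conversion = conversion_params()) {
  validate_cohort_spec(spec)
  parts <- latent_variance_parts(spec)
  n <- spec$n_families
  win <- c(1L, 2L, 3L, 3L, 3L, 3L)

  withr::with_seed(spec$seed, {
    zygosity <- ifelse(runif(n) < spec$prop_mz, "MZ", "DZ")
    sex <- ifelse(runif(n) < spec$prop_male, "M", "F")
    ses <- sample(c("low", "middle", "high"), n, replace = TRUE)

    k1 <- sample(0:5, n, replace = TRUE, prob = spec$exposure_probs)
    k_alt <- sample(0:5, n, replace = TRUE, prob = spec$exposure_probs)
    redraw <- runif(n) >= spec$exposure_concordance
    k2 <- ifelse(redraw, k_alt, k1)

    # ACE draws (raw variances from the composite calibration)
    a1 <- rnorm(n)
    a2 <- ifelse(zygosity == "MZ", a1, 0.5 * a1 + sqrt(0.75) * rnorm(n))
    c_fam <- rnorm(n)
    e1 <- rnorm(n)
    e2 <- rnorm(n)

    cov_draw <- function(cp) {
      shared <- rnorm(n)
      list(
        v1 = cp$mean + cp$sd * (sqrt(cp$rho) * shared + sqrt(1 - cp$rho) * rnorm(n)),
        v2 = cp$mean + cp$sd * (sqrt(cp$rho) * shared + sqrt(1 - cp$rho) * rnorm(n))
      )
    }
    whr <- cov_draw(spec$covariate_params$whr)
    tmp <- cov_draw(spec$covariate_params$temp)

    sa <- sqrt(max(parts$var_a_raw, 0))
    sc <- sqrt(max(parts$var_c_raw, 0))
    se <- sqrt(max(parts$var_e_raw, 0))
    s <- spec$serum_sigma

    eff_exp <- function(k) {
      e <- numeric(n)
      f <- sex == "F"
      e[f] <- parts$eff_latent$F[win[k[f] + 1L]]
      e[!f] <- parts$eff_latent$M[win[k[!f] + 1L]]
      e - parts$m_exp
    }
    ses_idx <- match(ses, c("low", "middle", "high"))
    eff_ses <- parts$ses_latent[ses_idx] - parts$m_ses
    eff_cov <- function(x, cp) cp$beta * (x - cp$mean) / s

    latent1 <- sa * a1 + sc * c_fam + se * e1 + eff_exp(k1) + eff_ses +
      eff_cov(whr$v1, spec$covariate_params$whr) +
      eff_cov(tmp$v1, spec$covariate_params$temp)
    latent2 <- sa * a2 + sc * c_fam + se * e2 + eff_exp(k2) + eff_ses +
      eff_cov(whr$v2, spec$covariate_params$whr) +
      eff_cov(tmp$v2, spec$covariate_params$temp)

    serum <- exp(spec$serum_mu + s * interleave(latent1, latent2))
    m <- 2L * n
    contaminated <- runif(m) < spec$contamination_rate
    n_cont <- sum(contaminated)
    if (n_cont > 0) {
      # acute-phase draws strictly above the 10 mg/L exclusion threshold,
      # with margin so assay noise cannot pull converted values back under it
      serum[contaminated] <- 12 + rlnorm(n_cont, meanlog = log(6), sdlog = 0.6)
    }

    bs <- pmax((serum - conversion$intercept) / conversion$slope, 1e-5)
    if (spec$measurement_cv > 0) {
      sdlog <- sqrt(log(1 + spec$measurement_cv^2))
      bs <- bs * rlnorm(m, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    }

    whr_obs <- interleave(whr$v1, whr$v2)
    tmp_obs <- interleave(tmp$v1, tmp$v2)
    whr_obs[runif(m) < spec$missing_rates[["waist_hip_ratio"]]] <- NA_real_
    tmp_obs[runif(m) < spec$missing_rates[["body_temp"]]] <- NA_real_

    tibble::tibble(
      family_id = rep(seq_len(n), each = 2L),
      twin_index = rep(1:2, times = n),
      zygosity = factor(rep(zygosity, each = 2L), levels = c("MZ", "DZ")),
      sex = factor(rep(sex, each = 2L), levels = c("F", "M")),
      victimization_count = interleave(k1, k2),
      bloodspot_crp = bs,
      waist_hip_ratio = whr_obs,
      body_temp = tmp_obs,
      ses_tertile = factor(rep(ses, each = 2L), levels = c("low", "middle", "high")),
      latent_log_crp = interleave(latent1, latent2),
      contaminated = contaminated
    )
  })
}

#' Write or read a cohort table as CSV
#'
#' The on-disk dialect uses a fixed, documented column order (the column order
#' of [generate_cohort()]); `read_cohort_csv()` validates the schema and
#' raises an error naming any missing column.
#'
#' @param table A cohort tibble.
#' @param path CSV file path.
#' @return `write_cohort_csv()` returns `path` invisibly; `read_cohort_csv()`
#'   returns a tibble with factor columns restored.
#' @export
write_cohort_csv <- function(table, path) {
  readr::write_csv(table, path)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_cohort_schema(tab)
  tab |>
    dplyr::mutate(
      zygosity = factor(.data$zygosity, levels = c("MZ", "DZ")),
      sex = factor(.data$sex, levels = c("F", "M")),
      ses_tertile = factor(.data$ses_tertile, levels = c("low", "middle", "high"))
    )
}

cohort_required_columns <- c(
  "family_id", "twin_index", "zygosity", "sex", "victimization_count",
  "bloodspot_crp", "waist_hip_ratio", "body_temp", "ses_tertile"
)

check_cohort_schema <- function(table) {
  missing <- setdiff(cohort_required_columns, names(table))
  if (length(missing) > 0) {
    stop_data(sprintf(
      "cohort table is missing required column%s: %s",
      if (length(missing) > 1) "s" else "", paste(missing, collapse = ", ")
    ))
  }
  invisible(table)
}
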