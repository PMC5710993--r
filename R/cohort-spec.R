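#' Parameterization of a synthetic same-sex twin cohort
#'
#' A `cohort_spec` bundles every parameter of the synthetic cohort generator:
#' cohort composition, the ACE variance fractions of latent log-CRP, the
#' victimization-count distribution, sex-specific exposure effects, covariate
#' and socioeconomic-status (SES) contributions, the serum scale, blood-spot
#' assay noise, acute-inflammation contamination and missingness. All effect
#' sizes (`effect_female`, `effect_male`, `ses_effect` and the covariate
#' `beta`s) are expressed on the log serum-equivalent CRP scale, the scale on
#' which regression coefficients are reported.
#'
#' The ACE fractions describe the *composite* latent log-CRP, i.e. the trait
#' after exposure, SES and covariate contributions are included: the generator
#' internally rescales its raw variance components so that the composite has
#' unit variance, monozygotic (MZ) within-pair covariance `var_a + var_c` and
#' dizygotic (DZ) covariance `var_a / 2 + var_c`. Shared (family-level)
#' exposure and SES effects are thereby absorbed into the C budget and
#' individual covariate noise into the E budget; a spec whose effects exceed
#' those budgets is rejected as infeasible.
#'
#' @param n_families Number of twin pairs (positive integer).
#' @param prop_mz Proportion of monozygotic pairs, in `[0, 1]`.
#' @param prop_male Proportion of male pairs, in `[0, 1]` (pairs are same-sex).
#' @param var_a,var_c,var_e Additive-genetic, shared-environment and
#'   unique-environment variance fractions of composite latent log-CRP;
#'   non-negative, summing to 1.
#' @param exposure_probs Probability vector over victimization-type counts
#'   0--5 (length 6, non-negative, summing to 1).
#' @param exposure_concordance Probability in `[0, 1]` that the second twin
#'   inherits the family-level victimization count rather than drawing an
#'   independent count. The default 1 treats victimization as a household-level
#'   exposure (both twins share the count).
#' @param effect_female,effect_male Length-3 mean shifts of log serum CRP for
#'   the winsorized exposure categories (none, one, poly).
#' @param covariate_params Nested list with elements `whr` and `temp`, each a
#'   list with `mean`, `sd`, `rho` (within-pair correlation, zygosity
#'   independent) and `beta` (log-CRP units per covariate unit). See
#'   [default_covariate_params()].
#' @param ses_effect Named length-3 vector of log-CRP shifts for SES tertiles
#'   `low`, `middle`, `high` (equal tertile probabilities at family level).
#' @param serum_mu,serum_sigma Location and scale of the serum model
#'   `serum = exp(serum_mu + serum_sigma * latent_log_crp)` (mg/L).
#' @param measurement_cv Coefficient of variation of the blood-spot assay
#'   (multiplicative lognormal noise).
#' @param contamination_rate Fraction of individuals whose serum CRP is
#'   resampled from an acute-inflammation distribution above 10 mg/L.
#' @param missing_rates Named fractions of missing `waist_hip_ratio` and
#'   `body_temp` values.
#' @param seed Integer seed; identical spec + seed gives a byte-identical
#'   cohort.
#'
#' @return An object of class `cohort_spec` (a validated named list).
#' @seealso [default_study_preset()], [generate_cohort()]
#' @export
#' @examples
#' spec <- cohort_spec(n_families = 100)
#' spec$var_a + spec$var_c # expected MZ within-pair correlation
cohort_spec <- function(n_families = 1000,
                        prop_mz = 0.56,
                        prop_male = 0.49,
                        var_a = 0.46,
                        var_c = 0.10,
                        var_e = 0.44,
                        exposure_probs = exposure_probs_default(),
                        exposure_concordance = 1,
                        effect_female = c(0, 0.21, 0.56),
                        effect_male = c(0, 0.10, 0.20),
                        covariate_params = default_covariate_params(),
                        ses_effect = c(low = 0.28, middle = 0.09, high = 0),
                        serum_mu = log(0.6),
                        serum_sigma = 0.8,
                        measurement_cv = 0.033,
                        contamination_rate = 0.03,
                        missing_rates = c(waist_hip_ratio = 25 / 888, body_temp = 7 / 888),
                        seed = 1L) {
  spec <- structure(
    list(
      n_families = n_families,
      prop_mz = prop_mz,
      prop_male = prop_male,
      var_a = var_a,
      var_c = var_c,
      var_e = var_e,
      exposure_probs = exposure_probs,
      exposure_concordance = exposure_concordance,
      effect_female = effect_female,
      effect_male = effect_male,
      covariate_params = covariate_params,
      ses_effect = ses_effect,
      serum_mu = serum_mu,
      serum_sigma = serum_sigma,
      measurement_cv = measurement_cv,
      contamination_rate = contamination_rate,
      missing_rates = missing_rates,
      seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
  validate_cohort_spec(spec)
  spec
}

#' Published victimization-count frequencies, normalized
#'
#' The reported percentages for 0--5 victimization types (73.5 / 20.1 / 3.8 /
#' 1.8 / 0.8 / 0.1) sum to 100.1 because of rounding; they are rescaled to
#' sum exactly to 1 so the spec invariant holds while preserving the ratios.
#'
#' @return Length-6 probability vector.
#' @export
exposure_probs_default <- function() {
  p <- c(0.735, 0.201, 0.038, 0.018, 0.008, 0.001)
  p / sum(p)
}

#' Default covariate parameters for the cohort generator
#'
#' Waist--hip ratio (dimensionless) and body temperature (degrees Celsius) at
#' the time of CRP assessment. `rho` is the within-pair correlation of the
#' covariate, modeled as a zygosity-independent household component; `beta` is
#' the generative effect on log serum CRP per covariate unit.
#'
#' @return Nested list with elements `whr` and `temp`.
#' @export
default_covariate_params <- function() {
  list(
    whr = list(mean = 0.80, sd = 0.06, rho = 0.4, beta = 3.82),
    temp = list(mean = 36.8, sd = 0.40, rho = 0.2, beta = 0.19)
  )
}

#' Study-emulation preset for the synthetic cohort
#'
#' Returns the documented preset emulating the structure of a British birth
#' cohort of same-sex twins assessed for CRP at age 18: 56% MZ pairs, 49%
#' male, ACE fractions (0.46, 0.10, 0.44) -- the unique solution of
#' `rMZ = A + C = 0.56` and `rDZ = A/2 + C = 0.33` -- the published
#' victimization-count distribution (73.5% / 20.1% / 3.8% / 1.8% / 0.8% /
#' 0.1% for 0--5 types), female exposure-category effects (0, 0.21, 0.56)
#' and male effects (0, 0.10, 0.20) encoding a linear trend of 0.10 per
#' category, a blood-spot assay CV of 3.3%, a 3% acute-inflammation
#' contamination fraction, and missingness matching the reported covariate
#' missing counts (25/888 and 7/888).
#'
#' @param n_families Number of twin pairs (default 10000).
#' @param seed Integer seed.
#' @param ... Further overrides passed to [cohort_spec()].
#' @return A `cohort_spec`.
#' @export
#' @examples
#' preset <- default_study_preset(n_families = 500, seed = 42)
#' preset$exposure_probs[1] # 0.735
default_study_preset <- function(n_families = 10000, seed = 1L, ...) {
  cohort_spec(n_families = n_families, seed = seed, ...)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec>\n")
  cat(sprintf("  families: %d (MZ %.0f%%, male %.0f%%), seed %d\n",
              x$n_families, 100 * x$prop_mz, 100 * x$prop_male, x$seed))
  cat(sprintf("  ACE fractions: A=%.2f C=%.2f E=%.2f\n", x$var_a, x$var_c, x$var_e))
  cat(sprintf("  exposure probs (0-5 types): %s\n",
              paste(format(x$exposure_probs), collapse = " ")))
  cat(sprintf("  effects (none/one/poly): F %s | M %s\n",
              paste(format(x$effect_female), collapse = "/"),
              paste(format(x$effect_male), collapse = "/")))
  cat(sprintf("  serum scale: mu=%.3f sigma=%.2f; assay CV %.1f%%; contamination %.1f%%\n",
              x$serum_mu, x$serum_sigma, 100 * x$measurement_cv,
              100 * x$contamination_rate))
  invisible(x)
}

#' Validate a cohort specification
#'
#' Checks every `cohort_spec` invariant (probability ranges, unit-sum
#' constraints, ACE feasibility given the effect sizes) and raises a
#' configuration error naming the violated invariant.
#'
#' @param spec A `cohort_spec`.
#' @return `spec`, invisibly, if valid.
#' @export
validate_cohort_spec <- function(spec) {
  if (!inherits(spec, "cohort_spec")) {
    stop_config("`spec` must be a `cohort_spec` object")
  }
  n <- spec$n_families
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n < 1 || n != round(n)) {
    stop_config("invariant violated: `n_families` must be a positive integer")
  }
  for (fld in c("prop_mz", "prop_male", "contamination_rate", "exposure_concordance")) {
    if (!is_scalar_prob(spec[[fld]])) {
      stop_config(sprintf("invariant violated: `%s` must be a single value in [0, 1]", fld))
    }
  }
  vfrac <- c(spec$var_a, spec$var_c, spec$var_e)
  if (any(!is.finite(vfrac)) || any(vfrac < 0)) {
    stop_config("invariant violated: `var_a`, `var_c`, `var_e` must be non-negative")
  }
  if (abs(sum(vfrac) - 1) > 1e-9) {
    stop_config("invariant violated: var_a + var_c + var_e must equal 1 (tolerance 1e-9)")
  }
  ep <- spec$exposure_probs
  if (length(ep) != 6L || any(!is.finite(ep)) || any(ep < 0)) {
    stop_config("invariant violated: `exposure_probs` must be 6 non-negative probabilities")
  }
  if (abs(sum(ep) - 1) > 1e-9) {
    stop_config("invariant violated: `exposure_probs` must sum to 1 (tolerance 1e-9)")
  }
  if (length(spec$effect_female) != 3L || length(spec$effect_male) != 3L) {
    stop_config("invariant violated: effect vectors must have length 3 (none, one, poly)")
  }
  if (length(spec$ses_effect) != 3L) {
    stop_config("invariant violated: `ses_effect` must have length 3 (low, middle, high)")
  }
  mr <- spec$missing_rates
  if (length(mr) != 2L || !all(vapply(mr, is_scalar_prob, logical(1)))) {
    stop_config("invariant violated: `missing_rates` must be two fractions in [0, 1]")
  }
  if (!is.numeric(spec$serum_sigma) || spec$serum_sigma <= 0) {
    stop_config("invariant violated: `serum_sigma` must be positive")
  }
  if (!is_scalar_prob(spec$measurement_cv)) {
    stop_config("invariant violated: `measurement_cv` must be in [0, 1]")
  }
  for (nm in c("whr", "temp")) {
    cp <- spec$covariate_params[[nm]]
    if (is.null(cp) || !all(c("mean", "sd", "rho", "beta") %in% names(cp))) {
      stop_config(sprintf("invariant violated: covariate_params$%s needs mean, sd, rho, beta", nm))
    }
    if (cp$sd < 0 || !is_scalar_prob(cp$rho)) {
      stop_config(sprintf("invariant violated: covariate_params$%s: sd >= 0 and rho in [0, 1]", nm))
    }
  }
  # feasibility of the composite-variance calibration
  parts <- latent_variance_parts(spec)
  if (parts$var_c_raw < -1e-12) {
    stop_config(paste0(
      "invariant violated: shared effect variance (exposure + SES + shared covariate ",
      sprintf("components = %.4f) exceeds the shared-environment budget var_c = %.4f",
              parts$shared_extra, spec$var_c)
    ))
  }
  if (parts$var_e_raw < -1e-12) {
    stop_config(paste0(
      "invariant violated: individual effect variance (unshared covariate components ",
      sprintf("= %.4f) exceeds the unique-environment budget var_e = %.4f",
              parts$unique_extra, spec$var_e)
    ))
  }
  invisible(spec)
}

# Decompose the non-ACE effect contributions into shared (within-pair) and
# unique variance on the standardized latent scale, and solve for the raw ACE
# variances that make the composite latent log-CRP have variance 1, MZ
# covariance var_a + var_c and DZ covariance var_a/2 + var_c.
latent_variance_parts <- function(spec) {
  s <- spec$serum_sigma
  win <- c(1L, 2L, 3L, 3L, 3L, 3L) # count 0..5 -> category index
  p_k <- spec$exposure_probs
  con <- spec$exposure_concordance

  eff <- list(F = spec$effect_female / s, M = spec$effect_male / s)
  p_sex <- c(F = 1 - spec$prop_male, M = spec$prop_male)
  m_sex <- vapply(eff, function(e) sum(p_k * e[win]), numeric(1))
  v_sex <- vapply(eff, function(e) sum(p_k * e[win]^2), numeric(1)) - m_sex^2
  m_exp <- sum(p_sex * m_sex)
  between_sex <- sum(p_sex * m_sex^2) - m_exp^2
  v_exp <- sum(p_sex * v_sex) + between_sex
  s_exp <- con * sum(p_sex * v_sex) + between_sex

  ses <- spec$ses_effect / s
  m_ses <- mean(ses)
  v_ses <- mean(ses^2) - m_ses^2 # family-level, fully shared

  cov_part <- function(cp) {
    v <- (cp$beta * cp$sd / s)^2
    c(shared = cp$rho * v, total = v)
  }
  whr <- cov_part(spec$covariate_params$whr)
  tmp <- cov_part(spec$covariate_params$temp)

  shared_extra <- s_exp + v_ses + whr[["shared"]] + tmp[["shared"]]
  total_extra <- v_exp + v_ses + whr[["total"]] + tmp[["total"]]
  unique_extra <- total_extra - shared_extra

  list(
    var_a_raw = spec$var_a,
    var_c_raw = spec$var_c - shared_extra,
    var_e_raw = spec$var_e - unique_extra,
    shared_extra = shared_extra,
    unique_extra = unique_extra,
    m_exp = m_exp,
    m_ses = m_ses,
    eff_latent = eff,
    ses_latent = ses
  )
}

#' Write or read a cohort specification as YAML or JSON
#'
#' Serializes a `cohort_spec` with field names mirrored one-to-one, so a
#' configuration file can fully reproduce a cohort.
#'
#' @param spec A `cohort_spec`.
#' @param path File path; the extension (`.yaml`/`.yml` or `.json`) selects
#'   the format.
#' @return `write_cohort_spec()` returns `path` invisibly;
#'   `read_cohort_spec()` returns a validated `cohort_spec`.
#' @export
write_cohort_spec <- function(spec, path) {
  validate_cohort_spec(spec)
  fields <- unclass(spec)
  # named atomic vectors become maps on disk so the names survive round trips
  fields$ses_effect <- as.list(fields$ses_effect)
  fields$missing_rates <- as.list(fields$missing_rates)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(fields, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(fields, path, precision = 15)
  }
  invisible(path)
}

#' @rdname write_cohort_spec
#' @export
read_cohort_spec <- function(path) {
  fields <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  fields$missing_rates <- unlist(fields$missing_rates)
  fields$ses_effect <- unlist(fields$ses_effect)
  do.call(cohort_spec, fields)
}
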