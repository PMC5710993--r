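#' Arrange a cohort table into complete twin pairs
#'
#' Internal-facing helper returning one row per family with both twins'
#' values of `value` (`v1`, `v2`) plus zygosity. Families without exactly two
#' non-missing values are dropped.
#'
#' @param table Cohort tibble.
#' @param value Column to pair (default `log_crp`).
#' @return Tibble with `family_id`, `zygosity`, `v1`, `v2`.
#' @export
pair_table <- function(table, value = "log_crp") {
  if (!value %in% names(table)) {
    stop_data(sprintf("column `%s` not found in the cohort table", value))
  }
  table |>
    dplyr::select("family_id", "twin_index", "zygosity", value = dplyr::all_of(value)) |>
    dplyr::filter(!is.na(.data$value)) |>
    tidyr::pivot_wider(
      names_from = "twin_index", values_from = "value", names_prefix = "v"
    ) |>
    dplyr::filter(!is.na(.data$v1), !is.na(.data$v2))
}

#' Within-pair correlations by zygosity
#'
#' Computes the double-entry (order-invariant) intraclass correlation of a
#' trait within MZ and DZ pairs: each pair contributes both orderings
#' `(v1, v2)` and `(v2, v1)`, so the estimate does not depend on the arbitrary
#' twin labelling.
#'
#' @param table Cohort tibble.
#' @param value Trait column (default `log_crp`).
#' @param min_pairs Minimum complete pairs required per zygosity group.
#' @return Tibble with one row per zygosity: `zygosity`, `n_pairs`, `r`.
#' @export
#' @examples
#' cohort <- generate_cohort(default_study_preset(n_families = 2000, seed = 3))
#' within_pair_correlations(cohort, value = "latent_log_crp")
within_pair_correlations <- function(table, value = "log_crp", min_pairs = 3) {
  pairs <- pair_table(table, value)
  purrr::map_dfr(c("MZ", "DZ"), function(z) {
    g <- dplyr::filter(pairs, .data$zygosity == z)
    if (nrow(g) < min_pairs) {
      stop_data(sprintf(
        "fewer than %d complete %s pairs (found %d)", min_pairs, z, nrow(g)
      ))
    }
    tibble::tibble(
      zygosity = z,
      n_pairs = nrow(g),
      r = cor(c(g$v1, g$v2), c(g$v2, g$v1))
    )
  })
}

#' Falconer closed-form ACE estimates
#'
#' The standard twin-study identities `a = 2 (rMZ - rDZ)`,
#' `c = 2 rDZ - rMZ`, `e = 1 - rMZ`. Values are returned unclipped by
#' default; with `clip = TRUE` negative components are set to zero and the
#' fractions renormalized for reporting.
#'
#' @param r_mz,r_dz Within-pair correlations in `[-1, 1]`.
#' @param clip Clip negative components to zero and renormalize?
#' @return Named numeric vector `c(a, c, e)`.
#' @export
#' @examples
#' falconer(0.56, 0.33) # c(0.46, 0.10, 0.44)
falconer <- function(r_mz, r_dz, clip = FALSE) {
  if (any(abs(c(r_mz, r_dz)) > 1)) {
    stop_data("correlations must lie in [-1, 1]")
  }
  est <- c(a = 2 * (r_mz - r_dz), c = 2 * r_dz - r_mz, e = 1 - r_mz)
  if (clip) {
    est <- pmax(est, 0)
    est <- est / sum(est)
  }
  est
}

# -2 log-likelihood of the bivariate-normal twin model from sufficient
# statistics: common mean mu, total variance v, within-pair covariance w
# (w = va + vc for MZ, va/2 + vc for DZ).
ace_suffstats <- function(pairs) {
  lapply(split(pairs, pairs$zygosity), function(g) {
    list(
      n = nrow(g),
      s1 = sum(g$v1 + g$v2),
      s2 = sum(g$v1^2 + g$v2^2),
      s12 = sum(g$v1 * g$v2)
    )
  })
}

ace_neg2ll <- function(mu, va, vc, ve, stats) {
  v <- va + vc + ve
  w <- c(MZ = va + vc, DZ = va / 2 + vc)
  total <- 0
  for (z in names(stats)) {
    st <- stats[[z]]
    det <- v^2 - w[[z]]^2
    if (!is.finite(det) || det <= 0 || v <= 0) {
      return(.Machine$double.xmax)
    }
    sdd <- st$s2 - 2 * mu * st$s1 + 2 * st$n * mu^2
    sd12 <- st$s12 - mu * st$s1 + st$n * mu^2
    total <- total + st$n * (2 * log(2 * pi) + log(det)) +
      (v * sdd - 2 * w[[z]] * sd12) / det
  }
  total
}

#' Maximum-likelihood ACE variance decomposition
#'
#' Fits the univariate twin model by maximizing the bivariate-normal
#' log-likelihood over complete pairs, with expected within-pair covariance
#' `sigma2_A + sigma2_C` for MZ pairs and `sigma2_A / 2 + sigma2_C` for DZ
#' pairs, a common mean and a common total variance. Variance components are
#' bounded below at zero (boundary estimates are reported, not hidden). The
#' confidence interval for the additive-genetic fraction uses the profile
#' likelihood by default, or a family-level nonparametric bootstrap.
#'
#' @param table Cohort tibble with both zygosity groups present.
#' @param value Trait column (default `log_crp`).
#' @param ci One of `"profile"`, `"boot"`, `"none"`.
#' @param conf_level Confidence level (default 0.95).
#' @param n_boot Bootstrap replicates when `ci = "boot"`.
#' @param max_iter Optimizer iteration budget; non-convergence is flagged in
#'   the result, never silently ignored.
#' @return A `crp_ace` object: variance fractions `a_frac`, `c_frac`,
#'   `e_frac`, the fitted mean and total variance, `minus2ll`, `converged`,
#'   `ci_a`, and pair counts. Has [tidy()] and [glance()] methods.
#' @export
fit_ace <- function(table, value = "log_crp",
                    ci = c("profile", "boot", "none"),
                    conf_level = 0.95, n_boot = 200, max_iter = 500) {
  ci <- match.arg(ci)
  pairs <- pair_table(table, value)
  counts <- table(factor(pairs$zygosity, levels = c("MZ", "DZ")))
  if (any(counts < 3)) {
    stop_data(sprintf(
      "both zygosity groups need at least 3 complete pairs (MZ = %d, DZ = %d)",
      counts[["MZ"]], counts[["DZ"]]
    ))
  }
  stats <- ace_suffstats(pairs)

  # moment-based initialization via Falconer on double-entry correlations
  all_v <- c(pairs$v1, pairs$v2)
  v0 <- var(all_v)
  r0 <- vapply(split(pairs, pairs$zygosity), function(g) {
    cor(c(g$v1, g$v2), c(g$v2, g$v1))
  }, numeric(1))
  f0 <- falconer(r0[["MZ"]], r0[["DZ"]], clip = TRUE)
  init <- unname(c(mean(all_v), pmax(f0, 0.02) / sum(pmax(f0, 0.02)) * v0))

  fit <- optim(
    par = init,
    fn = function(p) ace_neg2ll(p[1], p[2], p[3], p[4], stats),
    method = "L-BFGS-B",
    lower = c(-Inf, 0, 0, 1e-8),
    control = list(maxit = max_iter)
  )
  va <- fit$par[2]; vc <- fit$par[3]; ve <- fit$par[4]
  tot <- va + vc + ve
  a_frac <- va / tot

  ci_a <- c(NA_real_, NA_real_)
  if (ci == "profile") {
    ci_a <- ace_profile_ci_a(stats, fit$value, a_frac, init, conf_level, max_iter)
  } else if (ci == "boot") {
    reps <- vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(nrow(pairs), replace = TRUE)
      bstats <- ace_suffstats(pairs[idx, , drop = FALSE])
      if (length(bstats) < 2) return(NA_real_)
      bfit <- optim(
        par = fit$par,
        fn = function(p) ace_neg2ll(p[1], p[2], p[3], p[4], bstats),
        method = "L-BFGS-B", lower = c(-Inf, 0, 0, 1e-8),
        control = list(maxit = max_iter)
      )
      bfit$par[2] / sum(bfit$par[2:4])
    }, numeric(1))
    alpha <- (1 - conf_level) / 2
    ci_a <- unname(quantile(reps, c(alpha, 1 - alpha), na.rm = TRUE))
  }

  structure(
    list(
      a_frac = a_frac,
      c_frac = vc / tot,
      e_frac = ve / tot,
      mu = fit$par[1],
      total_var = tot,
      minus2ll = fit$value,
      converged = fit$convergence == 0,
      ci_a = ci_a,
      conf_level = conf_level,
      ci_method = ci,
      n_mz_pairs = as.integer(counts[["MZ"]]),
      n_dz_pairs = as.integer(counts[["DZ"]])
    ),
    class = "crp_ace"
  )
}

# profile-likelihood CI for the additive-genetic fraction: for fixed a_frac,
# re-maximize over (mu, total variance, C share of the remainder) and find
# where -2LL rises by qchisq(conf, 1).
ace_profile_ci_a <- function(stats, min2ll, a_hat, init, conf_level, max_iter) {
  prof <- function(alpha) {
    inner <- optim(
      par = c(init[1], max(sum(init[2:4]), 1e-4), 0.5),
      fn = function(p) {
        v <- p[2]; t <- p[3]
        va <- alpha * v
        vc <- t * (1 - alpha) * v
        ve <- (1 - t) * (1 - alpha) * v
        ace_neg2ll(p[1], va, vc, max(ve, 1e-10), stats)
      },
      method = "L-BFGS-B",
      lower = c(-Inf, 1e-8, 0), upper = c(Inf, Inf, 1),
      control = list(maxit = max_iter)
    )
    inner$value
  }
  cut <- min2ll + qchisq(conf_level, df = 1)
  eps <- 1e-6
  lo <- if (prof(eps) <= cut) 0 else {
    uniroot(function(a) prof(a) - cut, c(eps, max(a_hat, 2 * eps)), tol = 1e-4)$root
  }
  hi_end <- 1 - eps
  hi <- if (prof(hi_end) <= cut) 1 else {
    uniroot(function(a) prof(a) - cut, c(min(a_hat, hi_end - eps), hi_end), tol = 1e-4)$root
  }
  c(lo, hi)
}

#' @export
print.crp_ace <- function(x, ...) {
  cat("<crp_ace> univariate twin-model variance decomposition\n")
  cat(sprintf(
    "  A = %.3f [%s %.0f%% CI %.3f, %.3f]   C = %.3f   E = %.3f\n",
    x$a_frac, x$ci_method, 100 * x$conf_level, x$ci_a[1], x$ci_a[2],
    x$c_frac, x$e_frac
  ))
  cat(sprintf(
    "  pairs: %d MZ / %d DZ; -2LL = %.2f; converged: %s\n",
    x$n_mz_pairs, x$n_dz_pairs, x$minus2ll, x$converged
  ))
  invisible(x)
}

#' @export
tidy.crp_ace <- function(x, ...) {
  tibble::tibble(
    component = c("A", "C", "E"),
    estimate = c(x$a_frac, x$c_frac, x$e_frac),
    conf.low = c(x$ci_a[1], NA, NA),
    conf.high = c(x$ci_a[2], NA, NA)
  )
}

#' @export
glance.crp_ace <- function(x, ...) {
  tibble::tibble(
    minus2ll = x$minus2ll,
    converged = x$converged,
    n_mz_pairs = x$n_mz_pairs,
    n_dz_pairs = x$n_dz_pairs,
    total_var = x$total_var
  )
}

#' Latent genetic risk score from co-twin status
#'
#' Four-level ordinal code of genetic liability for a binary trait, built
#' from zygosity and whether the co-twin expresses the trait: 0 (lowest risk,
#' MZ co-twin without high CRP), 1 (low, DZ co-twin without), 2 (high, DZ
#' co-twin with), 3 (highest, MZ co-twin with high CRP). Vectorized; missing
#' co-twin flags propagate as `NA`.
#'
#' @param zygosity `"MZ"` or `"DZ"` (character or factor).
#' @param cotwin_high Logical: does the co-twin have high CRP?
#' @return Integer score 0--3.
#' @export
#' @examples
#' latent_genetic_score(c("MZ", "DZ", "DZ", "MZ"), c(FALSE, FALSE, TRUE, TRUE))
latent_genetic_score <- function(zygosity, cotwin_high) {
  z <- as.character(zygosity)
  if (any(!z %in% c("MZ", "DZ") & !is.na(z))) {
    stop_data("zygosity must be MZ or DZ")
  }
  if (!is.logical(cotwin_high)) {
    stop_data("`cotwin_high` must be logical")
  }
  out <- rep(NA_integer_, length(z))
  out[z == "MZ" & !cotwin_high] <- 0L
  out[z == "DZ" & !cotwin_high] <- 1L
  out[z == "DZ" & cotwin_high] <- 2L
  out[z == "MZ" & cotwin_high] <- 3L
  out
}

#' Attach the co-twin latent genetic score to a cohort table
#'
#' Joins each individual's co-twin `high_crp` flag within family and codes
#' the latent genetic score. Individuals whose co-twin is absent (e.g.
#' excluded for acute-range CRP) or lacks the flag receive `NA` and their
#' count is reported via a message; they are excluded from score-based models
#' rather than imputed.
#'
#' @param table Post-derivation cohort tibble with `high_crp`.
#' @return The table with `cotwin_high` and `genetic_score` columns added.
#' @export
add_cotwin_score <- function(table) {
  if (!"high_crp" %in% names(table)) {
    stop_data("`high_crp` column is required; run derive_analysis_variables() first")
  }
  cotwin <- table |>
    dplyr::select("family_id", "twin_index", "high_crp") |>
    dplyr::mutate(twin_index = 3L - .data$twin_index) |>
    dplyr::rename(cotwin_high = "high_crp")
  out <- table |>
    dplyr::left_join(cotwin, by = c("family_id", "twin_index")) |>
    dplyr::mutate(genetic_score = latent_genetic_score(.data$zygosity, .data$cotwin_high))
  n_missing <- sum(is.na(out$genetic_score))
  if (n_missing > 0) {
    inform(sprintf(
      "%d record%s without a scoreable co-twin (genetic_score set to NA)",
      n_missing, if (n_missing > 1) "s" else ""
    ))
  }
  out
}

#' Latent-score validation regression
#'
#' Regresses standardized log-CRP on the 0--3 latent genetic score with
#' family-clustered GEE, reporting both conventions for the published
#' "beta": the per-level coefficient on standardized log-CRP (`beta_level`)
#' and the fully standardized coefficient (`beta_std`, equal to the score/CRP
#' correlation), together with the variance explained `r_squared`.
#'
#' @param table Cohort tibble with `genetic_score` and `log_crp`.
#' @return One-row tibble: `n`, `beta_level`, `se`, `p_value`, `beta_std`,
#'   `r_squared`.
#' @export
score_validation <- function(table) {
  dat <- table |>
    dplyr::filter(!is.na(.data$genetic_score), !is.na(.data$log_crp))
  if (nrow(dat) < 10) {
    stop_data("too few scored records for the validation regression")
  }
  y <- as.numeric(scale(dat$log_crp))
  s <- dat$genetic_score
  design <- new_crp_design(
    X = cbind(`(Intercept)` = 1, genetic_score = s),
    y = y, cluster = dat$family_id,
    model_id = "score_validation", exposure_coding = "linear", stratum = "all"
  )
  fit <- fit_gee(design)
  b <- fit$coefficients[["genetic_score"]]
  tibble::tibble(
    n = length(y),
    beta_level = b,
    se = fit$robust_se[["genetic_score"]],
    p_value = fit$p_values[["genetic_score"]],
    beta_std = b * sd(s) / sd(y),
    r_squared = cor(design$X %*% fit$coefficients, y)[1]^2
  )
}
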