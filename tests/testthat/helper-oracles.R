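# Independent oracles and fixture builders used across the suite.
# These never call the code paths they are used to check.

# Closed-form R^2 of regressing a standardized trait on the 0-3 co-twin
# latent genetic score, under a bivariate-normal twin model with within-pair
# correlations r_mz / r_dz and a "high" flag at the top p_high tail.
# Uses truncated-normal conditional means (Mills ratios).
score_r2_oracle <- function(r_mz = 0.56, r_dz = 0.33, p_mz = 0.56, p_high = 1 / 3) {
  q <- qnorm(1 - p_high)
  lam_hi <- dnorm(q) / p_high        # E[Z | Z > q]
  lam_lo <- -dnorm(q) / (1 - p_high) # E[Z | Z <= q]
  w <- c(p_mz * (1 - p_high), (1 - p_mz) * (1 - p_high),
         (1 - p_mz) * p_high, p_mz * p_high) # score levels 0,1,2,3
  mu <- c(r_mz * lam_lo, r_dz * lam_lo, r_dz * lam_hi, r_mz * lam_hi)
  s <- 0:3
  mean_s <- sum(w * s)
  var_s <- sum(w * s^2) - mean_s^2
  cov_sz <- sum(w * s * mu) - mean_s * sum(w * mu)
  cov_sz^2 / var_s # marginal Var(Z) = 1
}

# Simulate bare twin pairs (one row per twin) with a given ACE structure,
# independently of generate_cohort(): direct bivariate-normal construction.
simulate_ace_pairs <- function(n_pairs, var_a, var_c, var_e,
                               prop_mz = 0.5, seed = 1) {
  withr::with_seed(seed, {
    mz <- runif(n_pairs) < prop_mz
    a1 <- rnorm(n_pairs)
    a2 <- ifelse(mz, a1, 0.5 * a1 + sqrt(0.75) * rnorm(n_pairs))
    cc <- rnorm(n_pairs)
    y1 <- sqrt(var_a) * a1 + sqrt(var_c) * cc + sqrt(var_e) * rnorm(n_pairs)
    y2 <- sqrt(var_a) * a2 + sqrt(var_c) * cc + sqrt(var_e) * rnorm(n_pairs)
    tibble::tibble(
      family_id = rep(seq_len(n_pairs), each = 2),
      twin_index = rep(1:2, n_pairs),
      zygosity = factor(rep(ifelse(mz, "MZ", "DZ"), each = 2),
                        levels = c("MZ", "DZ")),
      value = as.vector(rbind(y1, y2))
    )
  })
}

# Clustered regression data with exchangeable within-family correlation,
# built directly (not via the cohort generator), for GEE checks.
simulate_clustered <- function(n_families, beta = c(0.5, 0.3), rho = 0.5,
                               sigma = 1, seed = 1, family_level_x = FALSE) {
  withr::with_seed(seed, {
    fam <- rep(seq_len(n_families), each = 2)
    x <- if (family_level_x) rep(rnorm(n_families), each = 2) else rnorm(2 * n_families)
    shared <- rep(rnorm(n_families), each = 2)
    eps <- sigma * (sqrt(rho) * shared + sqrt(1 - rho) * rnorm(2 * n_families))
    tibble::tibble(
      family_id = fam,
      x = x,
      y = beta[1] + beta[2] * x + eps
    )
  })
}

# Minimal analysis-ready table for GEE design/interaction tests.
make_analysis_table <- function(n_families = 200, seed = 1,
                                effect_f = c(0, 0.2, 0.4),
                                effect_m = c(0, 0.2, 0.4),
                                rho = 0.4) {
  withr::with_seed(seed, {
    counts <- sample(0:3, n_families, replace = TRUE,
                     prob = c(0.7, 0.2, 0.07, 0.03))
    sexes <- sample(c("F", "M"), n_families, replace = TRUE)
    fam_eff <- rnorm(n_families)
    cat_idx <- pmin(counts, 2) + 1
    tab <- tibble::tibble(
      family_id = rep(seq_len(n_families), each = 2),
      twin_index = rep(1:2, n_families),
      sex = factor(rep(sexes, each = 2), levels = c("F", "M")),
      victimization_count = rep(counts, each = 2),
      zygosity = factor(rep(sample(c("MZ", "DZ"), n_families, TRUE), each = 2),
                        levels = c("MZ", "DZ"))
    )
    eff <- ifelse(tab$sex == "F",
                  effect_f[rep(cat_idx, each = 2)],
                  effect_m[rep(cat_idx, each = 2)])
    tab$log_crp <- eff + sqrt(rho) * rep(fam_eff, each = 2) +
      sqrt(1 - rho) * rnorm(2 * n_families)
    tab$victimization_category <- winsorize_victimization(tab$victimization_count)
    tab
  })
}
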