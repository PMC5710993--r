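test_that("double-entry correlations: concordance, independence, order invariance", {
  pairs <- simulate_ace_pairs(500, var_a = 0.5, var_c = 0.2, var_e = 0.3, seed = 2)

  # perfectly concordant pairs
  same <- dplyr::mutate(pairs,
                        value = withr::with_seed(5, rep(rnorm(500), each = 2)))
  wpc_same <- within_pair_correlations(same, value = "value")
  expect_equal(wpc_same$r, c(1, 1), tolerance = 1e-12)

  # independent co-twins (large n so the null correlation is tight)
  big <- simulate_ace_pairs(5000, var_a = 0.5, var_c = 0.2, var_e = 0.3, seed = 2)
  indep <- dplyr::mutate(big, value = withr::with_seed(6, rnorm(10000)))
  wpc_ind <- within_pair_correlations(indep, value = "value")
  expect_lt(max(abs(wpc_ind$r)), 0.06)

  # estimator does not depend on twin labelling
  swapped <- dplyr::mutate(pairs, twin_index = 3 - twin_index)
  expect_equal(within_pair_correlations(pairs, value = "value")$r,
               within_pair_correlations(swapped, value = "value")$r,
               tolerance = 1e-12)

  few <- dplyr::filter(pairs, zygosity == "DZ" | family_id <= 2)
  expect_error(within_pair_correlations(few, value = "value"), "MZ",
               class = "twincrp_data_error")
})

test_that("falconer closed form reproduces the standard twin identities", {
  expect_equal(unname(falconer(0.56, 0.33)), c(0.46, 0.10, 0.44))
  expect_equal(unname(falconer(0.5, 0.25)), c(0.5, 0, 0.5))
  expect_equal(unname(falconer(0.4, 0.4)), c(0, 0.4, 0.6))
  # unclipped values may leave [0,1]; the clipped variant renormalizes
  raw <- falconer(0.3, 0.4)
  expect_lt(raw[["a"]], 0)
  clipped <- falconer(0.3, 0.4, clip = TRUE)
  expect_true(all(clipped >= 0))
  expect_equal(sum(clipped), 1)
  expect_error(falconer(1.2, 0.3), class = "twincrp_data_error")
})

test_that("ML ACE fit recovers generating variance fractions on average", {
  for (a_true in c(0.2, 0.4, 0.6)) {
    reps <- vapply(1:4, function(r) {
      pairs <- simulate_ace_pairs(4000, var_a = a_true, var_c = 0.2,
                                  var_e = 0.8 - a_true,
                                  seed = round(100 * a_true) + r)
      fit <- fit_ace(pairs, value = "value", ci = "none")
      expect_true(fit$converged)
      expect_equal(fit$a_frac + fit$c_frac + fit$e_frac, 1, tolerance = 1e-6)
      fit$a_frac
    }, numeric(1))
    # mean over replicates within Monte-Carlo error of the generating value
    expect_lt(abs(mean(reps) - a_true), 0.045)
  }
})

test_that("ML ACE fit agrees with the Falconer closed form away from boundaries", {
  pairs <- simulate_ace_pairs(20000, var_a = 0.4, var_c = 0.25, var_e = 0.35,
                              seed = 31)
  wpc <- within_pair_correlations(pairs, value = "value")
  falc <- falconer(wpc$r[wpc$zygosity == "MZ"], wpc$r[wpc$zygosity == "DZ"])
  fit <- fit_ace(pairs, value = "value", ci = "none")
  expect_lt(abs(fit$a_frac - falc[["a"]]), 0.025)
  expect_lt(abs(fit$c_frac - falc[["c"]]), 0.025)
  expect_lt(abs(fit$e_frac - falc[["e"]]), 0.025)
})

test_that("ACE fit hits the A = 0 boundary when rMZ equals rDZ", {
  # shared environment only: expected correlations equal across zygosity
  pairs <- simulate_ace_pairs(4000, var_a = 0, var_c = 0.4, var_e = 0.6, seed = 7)
  fit <- fit_ace(pairs, value = "value", ci = "none")
  expect_lt(fit$a_frac, 0.06)
})

test_that("profile CI for the heritability fraction brackets the estimate", {
  pairs <- simulate_ace_pairs(3000, var_a = 0.45, var_c = 0.15, var_e = 0.4,
                              seed = 12)
  fit <- fit_ace(pairs, value = "value", ci = "profile")
  expect_lt(fit$ci_a[1], fit$a_frac)
  expect_gt(fit$ci_a[2], fit$a_frac)
  expect_gt(fit$ci_a[2] - fit$ci_a[1], 0.02)
  td <- tidy(fit)
  expect_equal(td$estimate, c(fit$a_frac, fit$c_frac, fit$e_frac))
  expect_equal(td$conf.low[1], fit$ci_a[1])
  gl <- glance(fit)
  expect_true(gl$converged)
  expect_equal(gl$n_mz_pairs + gl$n_dz_pairs, 3000L)
})

test_that("the latent genetic score mapping is total and injective on its domain", {
  grid <- expand.grid(zygosity = c("MZ", "DZ"), cotwin = c(FALSE, TRUE))
  scores <- latent_genetic_score(grid$zygosity, grid$cotwin)
  expect_equal(
    scores[order(grid$zygosity, grid$cotwin)],
    c(0L, 3L, 1L, 2L) # MZ/no, MZ/yes, DZ/no, DZ/yes
  )
  expect_equal(sort(scores), 0:3) # injective: all four levels hit once
  expect_equal(latent_genetic_score("MZ", NA), NA_integer_)
  expect_error(latent_genetic_score("XX", TRUE), class = "twincrp_data_error")
  expect_error(latent_genetic_score("MZ", 1), class = "twincrp_data_error")
})

test_that("co-twin scoring drops unpaired records with a reported count", {
  cohort <- generate_cohort(default_study_preset(n_families = 400, seed = 6))
  tab <- preprocess_cohort(cohort)$table
  n_excluded_partners <- sum(!table(tab$family_id) == 2)
  expect_message(
    scored <- add_cotwin_score(tab),
    "without a scoreable co-twin"
  )
  expect_equal(sum(is.na(scored$genetic_score)), n_excluded_partners)
  complete <- dplyr::filter(scored, !is.na(genetic_score))
  # spot-check the coding against the co-twin's flag
  check <- complete |>
    dplyr::group_by(family_id) |>
    dplyr::filter(dplyr::n() == 2) |>
    dplyr::mutate(expected = latent_genetic_score(zygosity, rev(high_crp)))
  expect_equal(check$genetic_score, check$expected)
})

test_that("score validation reports both beta conventions and R^2", {
  cohort <- generate_cohort(default_study_preset(n_families = 3000, seed = 14))
  tab <- add_cotwin_score(preprocess_cohort(cohort)$table)
  scored <- dplyr::filter(tab, !is.na(genetic_score))
  sv <- score_validation(scored)
  expect_lt(abs(sv$r_squared - score_r2_oracle()), 0.035)
  # r_squared is the squared score/trait correlation (coefficient free)
  expect_equal(sv$r_squared, cor(scored$genetic_score, scored$log_crp)^2,
               tolerance = 1e-10)
  # the two published-beta conventions are close but not identical: the
  # GEE-weighted standardized slope differs from the plain correlation
  expect_lt(abs(sv$beta_std - sqrt(sv$r_squared)), 0.06)
  expect_lt(sv$p_value, 1e-10)
})
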