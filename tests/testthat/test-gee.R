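test_that("GEE reduces exactly to OLS for singleton clusters", {
  withr::local_seed(1)
  n <- 120
  tab <- tibble::tibble(
    family_id = seq_len(n), x = rnorm(n),
    y = 1 + 0.4 * x + rnorm(n)
  )
  design <- twincrp:::new_crp_design(
    X = cbind(`(Intercept)` = 1, x = tab$x), y = tab$y,
    cluster = tab$family_id, model_id = "test", exposure_coding = "linear",
    stratum = "all"
  )
  fit <- fit_gee(design)
  ols <- lm(y ~ x, data = tab)
  expect_equal(unname(fit$coefficients), unname(coef(ols)), tolerance = 1e-10)
  expect_equal(fit$working_rho, 0)
  # model-based variance equals the classical OLS covariance
  expect_equal(unname(fit$vcov_model), unname(vcov(ols)), tolerance = 1e-10)
})

test_that("independence working correlation matches lm + cluster sandwich", {
  skip_if_not_installed("sandwich")
  dat <- simulate_clustered(150, beta = c(0.2, 0.5), rho = 0.5, seed = 3)
  design <- twincrp:::new_crp_design(
    X = cbind(`(Intercept)` = 1, x = dat$x), y = dat$y,
    cluster = dat$family_id, model_id = "test", exposure_coding = "linear",
    stratum = "all"
  )
  fit <- fit_gee(design, working = "independence")
  ols <- lm(y ~ x, data = dat)
  expect_equal(unname(fit$coefficients), unname(coef(ols)), tolerance = 1e-10)
  vc <- sandwich::vcovCL(ols, cluster = dat$family_id, type = "HC0",
                         cadjust = FALSE)
  expect_equal(unname(fit$vcov_robust), unname(vc), tolerance = 1e-8)
})

test_that("the moment estimator recovers the exchangeable correlation", {
  dat <- simulate_clustered(2000, beta = c(0, 0.3), rho = 0.5, seed = 9)
  design <- twincrp:::new_crp_design(
    X = cbind(`(Intercept)` = 1, x = dat$x), y = dat$y,
    cluster = dat$family_id, model_id = "test", exposure_coding = "linear",
    stratum = "all"
  )
  fit <- fit_gee(design)
  expect_true(fit$converged)
  expect_equal(fit$working_rho, 0.5, tolerance = 0.05)
})

test_that("sandwich SEs agree with a nonparametric cluster bootstrap", {
  n_fam <- 200
  dat <- simulate_clustered(n_fam, beta = c(0.2, 0.5), rho = 0.5, seed = 5,
                            family_level_x = TRUE)
  make_design <- function(d) twincrp:::new_crp_design(
    X = cbind(`(Intercept)` = 1, x = d$x), y = d$y, cluster = d$family_id,
    model_id = "test", exposure_coding = "linear", stratum = "all"
  )
  fit <- fit_gee(make_design(dat))
  boot <- withr::with_seed(42, {
    vapply(seq_len(400), function(i) {
      fams <- sample.int(n_fam, replace = TRUE)
      d <- purrr::map_dfr(seq_along(fams), function(j) {
        rows <- dat[dat$family_id == fams[j], ]
        rows$family_id <- j
        rows
      })
      fit_gee(make_design(d))$coefficients[["x"]]
    }, numeric(1))
  })
  expect_equal(fit$robust_se[["x"]], sd(boot), tolerance = 0.15 * sd(boot))
})

test_that("estimates are invariant to cluster order and twin swapping", {
  tab <- make_analysis_table(150, seed = 11)
  base <- fit_gee(build_model_design(tab, "baseline", "categorical", "all"))
  shuffled <- withr::with_seed(2, tab[sample.int(nrow(tab)), ])
  fit_s <- fit_gee(build_model_design(shuffled, "baseline", "categorical", "all"))
  expect_equal(base$coefficients, fit_s$coefficients, tolerance = 1e-7)
  expect_equal(base$robust_se, fit_s$robust_se, tolerance = 1e-7)
})

test_that("noise-free category effects reproduce the closed-form trend slope", {
  expect_lt(abs(linear_trend_oracle(c(0, 0.21, 0.56), c(0.726, 0.210, 0.064)) -
                  0.252), 5e-4)
  expect_equal(linear_trend_oracle(c(0, 0.3, 0.6), c(0.5, 0.3, 0.2)), 0.3)
  expect_equal(linear_trend_oracle(c(0, 0, 0), c(0.7, 0.2, 0.1)), 0)
  expect_error(linear_trend_oracle(c(0, 1, 2), c(1, 0, 0)), "degenerate",
               class = "twincrp_data_error")
  expect_error(linear_trend_oracle(c(0, 1, 2), c(0.5, 0.2, 0.2)),
               class = "twincrp_data_error")

  # deterministic fixture in exact proportions: GEE slope must match the
  # oracle to within 1e-3 (here: exactly, the oracle is the OLS slope)
  counts <- c(rep(0L, 726), rep(1L, 210), rep(2L, 64))
  eff <- c(0, 0.21, 0.56)[counts + 1]
  tab <- tibble::tibble(
    family_id = seq_along(counts), sex = factor("F", levels = c("F", "M")),
    victimization_count = counts, log_crp = eff,
    victimization_category = winsorize_victimization(counts)
  )
  fit <- fit_gee(build_model_design(tab, "baseline", "linear", "all"))
  oracle <- linear_trend_oracle(c(0, 0.21, 0.56), c(0.726, 0.210, 0.064))
  expect_equal(fit$coefficients[["victimization_linear"]], oracle,
               tolerance = 1e-9)
})

test_that("model designs carry the documented covariate sets and strata", {
  tab <- make_analysis_table(100, seed = 21) |>
    dplyr::mutate(
      ses_tertile = factor(rep_len(c("low", "middle", "high"), dplyr::n()),
                           levels = c("low", "middle", "high")),
      waist_hip_ratio = 0.8 + rnorm(dplyr::n(), sd = 0.05),
      body_temp = 36.8 + rnorm(dplyr::n(), sd = 0.4),
      genetic_score = rep_len(0:3, dplyr::n())
    )
  d_base <- build_model_design(tab, "baseline", "categorical", "F")
  expect_equal(d_base$terms,
               c("(Intercept)", "victimization_one", "victimization_poly"))
  expect_true(all(tab$sex[tab$family_id %in% d_base$cluster] == "F"))

  d_lin <- build_model_design(tab, "baseline", "linear", "all")
  expect_true(all(d_lin$X[, "victimization_linear"] %in% 0:2))

  d4 <- build_model_design(tab, "model4", "categorical", "F")
  expect_setequal(d4$terms, c("(Intercept)", "victimization_one",
                              "victimization_poly", "genetic_score",
                              "ses_middle", "ses_low", "waist_hip_ratio",
                              "body_temp"))

  tab_na <- tab
  tab_na$genetic_score[c(1, 5, 9)] <- NA
  expect_error(build_model_design(tab_na, "model1", "categorical", "all"),
               "3 record", class = "twincrp_data_error")

  # no exposed individuals in the stratum: dummies are all-zero, collinear
  tab0 <- dplyr::mutate(tab, victimization_count = 0L,
                        victimization_category = winsorize_victimization(0L))
  expect_error(build_model_design(tab0, "baseline", "categorical", "all"),
               "collinear", class = "twincrp_data_error")
})

test_that("non-convergence within the iteration budget is flagged, not hidden", {
  dat <- simulate_clustered(300, beta = c(0.2, 0.5), rho = 0.6, seed = 6,
                            family_level_x = FALSE)
  design <- twincrp:::new_crp_design(
    X = cbind(`(Intercept)` = 1, x = dat$x), y = dat$y,
    cluster = dat$family_id, model_id = "test", exposure_coding = "linear",
    stratum = "all"
  )
  strict <- fit_gee(design, tol = 1e-14, max_iter = 1)
  expect_false(strict$converged)
  expect_equal(strict$iterations, 1L)
  relaxed <- fit_gee(design)
  expect_true(relaxed$converged)
})

test_that("sex-interaction Wald test is calibrated under the null and powered", {
  # type-I calibration: identical effects in both sexes
  pvals <- vapply(1:60, function(i) {
    tab <- make_analysis_table(150, seed = 1000 + i,
                               effect_f = c(0, 0.2, 0.4),
                               effect_m = c(0, 0.2, 0.4))
    sex_interaction_test(tab)$p.value
  }, numeric(1))
  expect_lt(mean(pvals < 0.05), 0.15) # near-nominal level at alpha = 0.05
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)

  # power in the extreme: large female effect, none in males
  tab_alt <- make_analysis_table(2500, seed = 99,
                                 effect_f = c(0, 0.5, 1.0),
                                 effect_m = c(0, 0, 0))
  expect_lt(sex_interaction_test(tab_alt)$p.value, 0.001)

  # single-sex table is an error
  tab_f <- dplyr::filter(make_analysis_table(100, seed = 3), sex == "F")
  expect_error(sex_interaction_test(tab_f), "both sexes",
               class = "twincrp_data_error")
})

test_that("tidy and glance expose coefficients, robust CIs and fit metadata", {
  tab <- make_analysis_table(200, seed = 8)
  fit <- fit_gee(build_model_design(tab, "baseline", "categorical", "all"))
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error", "statistic", "p.value",
                     "conf.low", "conf.high"))
  expect_equal(td$conf.high - td$estimate, 1.959964 * td$std.error,
               tolerance = 1e-6)
  gl <- glance(fit)
  expect_equal(gl$n_obs, 400L)
  expect_equal(gl$n_clusters, 200L)
  expect_true(gl$converged)
})
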