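#' Construct a GEE model design for the covariate ladder
#'
#' Builds the design matrix for one rung of the model ladder used to test
#' whether victimization predicts log-CRP independently of genetic and
#' lifestyle confounders:
#' \describe{
#'   \item{baseline}{exposure only}
#'   \item{model1}{exposure + latent genetic score}
#'   \item{model2}{exposure + SES tertile dummies (reference: high)}
#'   \item{model3}{exposure + waist--hip ratio + body temperature}
#'   \item{model4}{exposure + all covariates simultaneously}
#' }
#' The exposure enters either as two dummies (`one`, `poly`; reference
#' `none`) or as a linear trend scored 0/1/2. `stratum` filters rows before
#' the design is constructed. Models that include the latent genetic score
#' require a complete `genetic_score` for every retained row and raise an
#' error counting the offending records otherwise.
#'
#' @param table Analysis-ready cohort tibble (see
#'   [derive_analysis_variables()], [add_cotwin_score()]).
#' @param model_id One of `"baseline"`, `"model1"`, ..., `"model4"`.
#' @param exposure_coding `"categorical"` or `"linear"`.
#' @param stratum `"all"`, `"F"` or `"M"`.
#' @return A `crp_design` with the numeric design matrix `X`, outcome `y`
#'   (log-CRP), family `cluster` ids and metadata.
#' @export
build_model_design <- function(table,
                               model_id = c("baseline", "model1", "model2",
                                            "model3", "model4"),
                               exposure_coding = c("categorical", "linear"),
                               stratum = c("all", "F", "M")) {
  model_id <- match.arg(model_id)
  exposure_coding <- match.arg(exposure_coding)
  stratum <- match.arg(stratum)

  needed <- c("log_crp", "victimization_category", "family_id", "sex")
  if (model_id %in% c("model1", "model4")) needed <- c(needed, "genetic_score")
  if (model_id %in% c("model2", "model4")) needed <- c(needed, "ses_tertile")
  if (model_id %in% c("model3", "model4")) needed <- c(needed, "waist_hip_ratio", "body_temp")
  missing_cols <- setdiff(needed, names(table))
  if (length(missing_cols) > 0) {
    stop_data(sprintf("analysis table lacks column(s): %s",
                      paste(missing_cols, collapse = ", ")))
  }

  dat <- if (stratum == "all") table else dplyr::filter(table, .data$sex == stratum)
  if (nrow(dat) == 0) {
    stop_data(sprintf("no rows left after restricting to stratum '%s'", stratum))
  }
  if ("genetic_score" %in% needed) {
    n_bad <- sum(is.na(dat$genetic_score))
    if (n_bad > 0) {
      stop_data(sprintf(
        "%d record(s) lack co-twin data for the latent genetic score; drop them before building %s",
        n_bad, model_id
      ))
    }
  }

  cat3 <- winsorize_victimization(dat$victimization_category)
  X <- cbind(`(Intercept)` = rep(1, nrow(dat)))
  if (exposure_coding == "categorical") {
    X <- cbind(X,
               victimization_one = as.numeric(cat3 == "one"),
               victimization_poly = as.numeric(cat3 == "poly"))
  } else {
    X <- cbind(X, victimization_linear = as.numeric(cat3) - 1)
  }
  if (model_id %in% c("model1", "model4")) {
    X <- cbind(X, genetic_score = as.numeric(dat$genetic_score))
  }
  if (model_id %in% c("model2", "model4")) {
    X <- cbind(X,
               ses_middle = as.numeric(dat$ses_tertile == "middle"),
               ses_low = as.numeric(dat$ses_tertile == "low"))
  }
  if (model_id %in% c("model3", "model4")) {
    X <- cbind(X,
               waist_hip_ratio = dat$waist_hip_ratio,
               body_temp = dat$body_temp)
  }

  new_crp_design(X = X, y = dat$log_crp, cluster = dat$family_id,
                 model_id = model_id, exposure_coding = exposure_coding,
                 stratum = stratum)
}

new_crp_design <- function(X, y, cluster, model_id, exposure_coding, stratum) {
  if (anyNA(X) || anyNA(y)) {
    stop_data("design matrix and outcome must be complete (no missing values)")
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop_data(sprintf("design matrix is rank deficient; collinear column(s): %s",
                      paste(dropped, collapse = ", ")))
  }
  structure(
    list(X = X, y = y, cluster = cluster, terms = colnames(X),
         model_id = model_id, exposure_coding = exposure_coding,
         stratum = stratum),
    class = "crp_design"
  )
}

#' @export
print.crp_design <- function(x, ...) {
  cat(sprintf("<crp_design> %s (%s exposure, stratum %s): %d obs, %d clusters, terms: %s\n",
              x$model_id, x$exposure_coding, x$stratum, length(x$y),
              length(unique(x$cluster)), paste(x$terms, collapse = ", ")))
  invisible(x)
}

#' Fit a linear GEE with exchangeable working correlation
#'
#' From-scratch generalized-estimating-equations estimator for a Gaussian
#' outcome with identity link, clustered on family. Iterates (i) the weighted
#' estimating-equation solve for the coefficients given the working
#' correlation and (ii) a moment update of the exchangeable correlation from
#' standardized residuals (with the usual small-sample denominator
#' correction, subtracting the number of regression parameters), until the
#' maximum coefficient change falls below `tol`. Standard errors are
#' cluster-robust: the sandwich estimator aggregates per-cluster score outer
#' products, so they remain valid if the working correlation is
#' misspecified. With singleton clusters (or `working = "independence"`) the
#' coefficient estimates and the model-based variance reduce exactly to
#' ordinary least squares.
#'
#' @param design A `crp_design` from [build_model_design()].
#' @param tol Convergence threshold on the maximum coefficient change.
#' @param max_iter Iteration budget; exceeding it yields a fit flagged
#'   `converged = FALSE`, not a silent success.
#' @param working `"exchangeable"` (default) or `"independence"` (working
#'   correlation fixed at 0).
#' @return A `crp_gee` object: `coefficients`, `robust_se`, `p_values`,
#'   robust and model-based covariance matrices, `working_rho`, `sigma2`,
#'   counts and convergence metadata. Has [tidy()] and [glance()] methods
#'   and an [autoplot()] forest plot.
#' @export
fit_gee <- function(design, tol = 1e-8, max_iter = 100,
                    working = c("exchangeable", "independence")) {
  working <- match.arg(working)
  X <- design$X
  y <- design$y
  cl <- factor(design$cluster, levels = unique(design$cluster))
  n <- length(y)
  p <- ncol(X)
  n_c <- as.integer(table(cl))
  n_clusters <- length(n_c)
  n_pairs <- sum(n_c * (n_c - 1) / 2)
  cl_of_row <- as.integer(cl)

  beta <- qr.solve(X, y)
  rho <- 0
  iterations <- 0L
  converged <- FALSE
  # rho bounded inside the positive-definite region of the exchangeable
  # correlation; the upper cap guards cluster-constant (zero within-cluster
  # residual variance) degeneracies where the estimate is invariant to rho
  rho_lo <- if (max(n_c) > 1) -0.995 / (max(n_c) - 1) else 0
  rho_hi <- 0.995

  for (it in seq_len(max_iter)) {
    iterations <- it
    e <- y - drop(X %*% beta)
    sigma2 <- sum(e^2) / (n - p)
    if (working == "exchangeable" && n_pairs > 0 && sigma2 > 0) {
      cs_e <- rowsum(e, cl)
      sp <- sum((cs_e^2 - rowsum(e^2, cl)) / 2)
      rho <- sp / sigma2 / max(n_pairs - p, 1)
      rho <- min(max(rho, rho_lo), rho_hi)
    } else {
      rho <- 0
    }
    w_c <- rho / (1 + (n_c - 1) * rho)
    SX <- rowsum(X, cl)
    Sy <- rowsum(y, cl)
    A <- crossprod(X) - t(SX) %*% (SX * w_c)
    b <- drop(crossprod(X, y)) - drop(t(SX) %*% (Sy * w_c))
    beta_new <- solve(A, b)
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }

  e <- y - drop(X %*% beta)
  sigma2 <- sum(e^2) / (n - p)
  w_c <- rho / (1 + (n_c - 1) * rho)
  SX <- rowsum(X, cl)
  A <- crossprod(X) - t(SX) %*% (SX * w_c)
  # per-cluster scores; the (1 - rho) * sigma2 scale cancels in the sandwich
  Se <- rowsum(e, cl)
  G <- rowsum(X * e, cl) - SX * (w_c * drop(Se))
  A_inv <- solve(A)
  vcov_robust <- A_inv %*% crossprod(G) %*% A_inv
  vcov_model <- (1 - rho) * sigma2 * A_inv
  dimnames(vcov_robust) <- dimnames(vcov_model) <- list(design$terms, design$terms)

  beta <- setNames(drop(beta), design$terms)
  robust_se <- sqrt(diag(vcov_robust))
  z <- beta / robust_se
  structure(
    list(
      coefficients = beta,
      robust_se = robust_se,
      p_values = 2 * pnorm(-abs(z)),
      vcov_robust = vcov_robust,
      vcov_model = vcov_model,
      working = working,
      working_rho = rho,
      sigma2 = sigma2,
      n_obs = n,
      n_clusters = n_clusters,
      converged = converged,
      iterations = iterations,
      design_meta = design[c("model_id", "exposure_coding", "stratum", "terms")]
    ),
    class = "crp_gee"
  )
}

#' @export
print.crp_gee <- function(x, ...) {
  cat(sprintf("<crp_gee> %s (%s exposure, stratum %s)\n",
              x$design_meta$model_id, x$design_meta$exposure_coding,
              x$design_meta$stratum))
  print(tidy(x), n = Inf)
  cat(sprintf("  %d obs in %d clusters; working rho = %.3f; converged: %s (%d iter)\n",
              x$n_obs, x$n_clusters, x$working_rho, x$converged, x$iterations))
  invisible(x)
}

#' @export
tidy.crp_gee <- function(x, conf_level = 0.95, ...) {
  zq <- qnorm(1 - (1 - conf_level) / 2)
  tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(x$robust_se),
    statistic = unname(x$coefficients / x$robust_se),
    p.value = unname(x$p_values),
    conf.low = unname(x$coefficients - zq * x$robust_se),
    conf.high = unname(x$coefficients + zq * x$robust_se)
  )
}

#' @export
glance.crp_gee <- function(x, ...) {
  tibble::tibble(
    n_obs = x$n_obs,
    n_clusters = x$n_clusters,
    working_rho = x$working_rho,
    sigma2 = x$sigma2,
    converged = x$converged,
    iterations = x$iterations
  )
}

#' Closed-form linear-trend slope over exposure categories
#'
#' Population regression slope of category mean effects on the 0/1/2
#' category score: `Cov(effect, score) / Var(score)` under the given
#' category proportions. Serves as an independent oracle for the linear-trend
#' GEE coefficient.
#'
#' @param category_effects Length-3 mean outcomes for (none, one, poly).
#' @param category_props Length-3 proportions summing to 1.
#' @return The implied linear-trend slope.
#' @export
#' @examples
#' linear_trend_oracle(c(0, 0.21, 0.56), c(0.726, 0.210, 0.064)) # ~0.252
linear_trend_oracle <- function(category_effects, category_props) {
  if (length(category_effects) != 3L || length(category_props) != 3L) {
    stop_data("effects and proportions must both have length 3")
  }
  if (abs(sum(category_props) - 1) > 1e-8 || any(category_props < 0)) {
    stop_data("category proportions must be non-negative and sum to 1")
  }
  score <- 0:2
  mean_s <- sum(category_props * score)
  var_s <- sum(category_props * score^2) - mean_s^2
  if (var_s <= .Machine$double.eps) {
    stop_data("degenerate category distribution: the score has zero variance")
  }
  mean_f <- sum(category_props * category_effects)
  cov_sf <- sum(category_props * score * category_effects) - mean_s * mean_f
  cov_sf / var_s
}

#' Wald test of the victimization-by-sex interaction
#'
#' Fits the pooled GEE `log_crp ~ exposure + sex + exposure:sex` with the
#' linear 0/1/2 exposure trend and tests the product term with the robust
#' (sandwich) variance.
#'
#' @param table Analysis-ready cohort tibble with both sexes present.
#' @param ... Passed to [fit_gee()].
#' @return One-row tibble: `estimate`, `std.error`, `statistic`, `p.value`.
#' @export
sex_interaction_test <- function(table, ...) {
  if (length(unique(as.character(table$sex))) < 2) {
    stop_data("both sexes must be present to test the exposure-by-sex interaction")
  }
  cat3 <- winsorize_victimization(table$victimization_category)
  trend <- as.numeric(cat3) - 1
  male <- as.numeric(table$sex == "M")
  design <- new_crp_design(
    X = cbind(`(Intercept)` = 1, victimization_linear = trend,
              sex_male = male, victimization_x_male = trend * male),
    y = table$log_crp, cluster = table$family_id,
    model_id = "sex_interaction", exposure_coding = "linear", stratum = "all"
  )
  fit <- fit_gee(design, ...)
  tidy(fit) |> dplyr::filter(.data$term == "victimization_x_male")
}
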