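#' @importFrom rlang abort warn inform %||% .data
#' @importFrom stats rnorm runif qnorm dnorm pnorm cor sd var optim uniroot
#'   qchisq rgamma rlnorm complete.cases setNames coef lm quantile
NULL

# internal error helpers: every user-facing failure carries a subclass so
# callers (and the pipeline) can distinguish configuration, data and
# convergence problems.
stop_config <- function(msg, ...) {
  abort(msg, class = "twincrp_config_error", ...)
}

stop_data <- function(msg, ...) {
  abort(msg, class = "twincrp_data_error", ...)
}

# interleave two equal-length vectors a1 b1 a2 b2 ...
interleave <- function(a, b) {
  stopifnot(length(a) == length(b))
  out <- vector(mode = class(c(a[0], b[0]))[1], length = 2L * length(a))
  idx <- seq_along(a)
  out[2L * idx - 1L] <- a
  out[2L * idx] <- b
  out
}

is_scalar_prob <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
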