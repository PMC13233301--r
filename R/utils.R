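#' @importFrom rlang .data abort warn inform %||%
#' @importFrom stats qnorm pnorm qchisq pbinom pt rnorm runif rbinom rexp
#'   rlnorm prcomp sd median setNames
NULL

# beta values are clipped into the open unit interval before logit so that
# fully (un)methylated calls do not map to +/-Inf on the M scale
BETA_EPS <- 1e-6

clip_beta <- function(b, eps = BETA_EPS) {
  pmin(pmax(b, eps), 1 - eps)
}

#' Convert methylation beta values to M-values
#'
#' Applies the logit2 transform \eqn{M = \log_2(\beta / (1 - \beta))} after
#' clipping beta into \eqn{[10^{-6}, 1 - 10^{-6}]}. M-values are the usual
#' scale for linear modelling of array methylation because their variance is
#' closer to constant across the methylation range.
#'
#' @param beta Numeric vector or matrix of beta values in \eqn{[0, 1]}.
#' @return Object of the same shape on the M scale.
#' @examples
#' beta_to_m(c(0.2, 0.5, 0.8))
#' @export
beta_to_m <- function(beta) {
  if (any(beta < 0 | beta > 1, na.rm = TRUE)) {
    abort("beta values must lie in [0, 1]")
  }
  b <- clip_beta(beta)
  log2(b / (1 - b))
}

#' Convert M-values back to beta values
#'
#' Inverse of [beta_to_m()]: \eqn{\beta = 2^M / (1 + 2^M)}.
#'
#' @param m Numeric vector or matrix of M-values.
#' @return Beta values in \eqn{(0, 1)}.
#' @export
m_to_beta <- function(m) {
  e <- 2^m
  e / (1 + e)
}

# p-values must stay inside (0, 1) before qnorm; 0 would give an infinite
# z-score and 1 exactly would lose the sign information
clip_p <- function(p, lo = 1e-300, hi = 1 - 1e-16) {
  pmin(pmax(p, lo), hi)
}

check_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != round(x)) {
    abort(sprintf("`%s` must be a single integer >= %d", name, min))
  }
  as.integer(x)
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single value in [0, 1]", name))
  }
  as.numeric(x)
}
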