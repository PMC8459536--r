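#' Tidy a quasibinomial barrier fit
#'
#' One row per coefficient, broom-style: `term`, `estimate` (logit scale),
#' `std.error` (scaled by the Pearson dispersion), `statistic` (t value)
#' and `p.value` (t distribution on the residual df).
#'
#' @param x A `barrier_glm` fit.
#' @param ... Unused.
#' @export
tidy.barrier_glm <- function(x, ...) {
  tibble(
    term = names(x$beta),
    estimate = unname(x$beta),
    std.error = unname(x$se),
    statistic = unname(x$t),
    p.value = unname(x$p_value)
  )
}

#' One-row model summary of a quasibinomial barrier fit
#'
#' @param x A `barrier_glm` fit.
#' @param ... Unused.
#' @export
glance.barrier_glm <- function(x, ...) {
  tibble(
    dispersion = x$dispersion,
    deviance = x$deviance,
    null.deviance = x$null_deviance,
    df.residual = x$df_residual,
    nobs = x$n_obs,
    converged = x$converged,
    iterations = x$iterations
  )
}

#' Observation-level results for a quasibinomial barrier fit
#'
#' Appends `.fitted` (fitted proportion) and `.resid` (Pearson residual,
#' unscaled by the dispersion) to the training data.
#'
#' @param x A `barrier_glm` fit.
#' @param ... Unused.
#' @export
augment.barrier_glm <- function(x, ...) {
  mu <- x$fitted
  d <- x$data
  mutate(d,
         .fitted = mu,
         .resid = (d$k / d$n - mu) / sqrt(mu * (1 - mu) / d$n))
}
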