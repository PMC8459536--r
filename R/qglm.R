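#' Quasibinomial logistic regression of barrier strength on genetic distance
#'
#' Fits the binomial logit model by iteratively reweighted least squares
#' (IRLS) with each observation entering as `k` successes of `n` trials,
#' then estimates a free dispersion parameter `phi` from the Pearson
#' statistic, `phi = X^2 / df_residual`. The dispersion scales the
#' coefficient covariance (`phi * (X'WX)^-1`) and hence the standard
#' errors, t values and quasi-F tests, but never the coefficient estimates
#' themselves — with `phi` forced to 1 the fit is an ordinary binomial
#' GLM.
#'
#' Model terms are drawn from `"gd"` (genetic distance slope), `"female"`
#' (female-population or dam factor) and `"gd:female"` (their
#' interaction); the intercept is always present. A `female` factor with a
#' single level is dropped automatically (with any interaction), so
#' degenerate single-population inputs reduce to a distance-only fit.
#'
#' @param observations A tibble of barrier observations with columns `k`,
#'   `n`, `gd` and (if used) `female`, as produced by
#'   [barrier_observations()].
#' @param terms Character vector of model terms beyond the intercept.
#' @param max_iter,tol IRLS control: stop when the relative deviance
#'   change drops below `tol` (default `1e-10`) or after `max_iter`
#'   iterations (then the fit is flagged non-converged with a warning).
#' @return An object of class `barrier_glm`: coefficients, scaled
#'   covariance, dispersion, deviance, degrees of freedom, convergence
#'   state. Methods: [tidy()], [glance()], [augment()], `predict()`,
#'   `print()`, [autoplot()].
#' @examples
#' obs <- barrier_observations(simulate_study(sim_config(seed = 1)))
#' fit_barrier_glm(dplyr::filter(obs, barrier == "inviability"), terms = "gd")
#' @export
fit_barrier_glm <- function(observations, terms = c("gd", "female"),
                            max_iter = 50, tol = 1e-10) {
  design <- build_design(observations, terms)
  fit <- qglm_irls(design$X, observations$k, observations$n,
                   max_iter = max_iter, tol = tol)
  fit$terms <- design$terms
  fit$term_assign <- design$assign
  fit$xlevels <- design$xlevels
  fit$data <- as_tibble(observations)
  class(fit) <- "barrier_glm"
  fit
}

#' Distance-only quasibinomial fit for one barrier
#'
#' The reduced model (intercept + genetic distance) used to estimate
#' barrier-completeness thresholds; equivalent to
#' `fit_barrier_glm(observations, terms = "gd")`.
#'
#' @inheritParams fit_barrier_glm
#' @return A `barrier_glm` object.
#' @export
gd_only_fit <- function(observations, max_iter = 50, tol = 1e-10) {
  fit_barrier_glm(observations, terms = "gd", max_iter = max_iter, tol = tol)
}

# Model-matrix construction for the restricted term vocabulary.
build_design <- function(observations, terms) {
  stopifnot(all(c("k", "n", "gd") %in% names(observations)))
  if (any(observations$n < 1) || any(observations$k < 0) ||
      any(observations$k > observations$n)) {
    abort("observations need 0 <= k <= n and n >= 1")
  }
  terms <- unique(terms)
  allowed <- c("gd", "female", "gd:female")
  if (length(setdiff(terms, allowed)) > 0) {
    abort(paste0("unknown model term(s): ",
                 paste(setdiff(terms, allowed), collapse = ", ")))
  }
  if ("gd:female" %in% terms && !all(c("gd", "female") %in% terms)) {
    abort("the gd:female interaction requires both main effects")
  }
  xlevels <- NULL
  if (any(c("female", "gd:female") %in% terms)) {
    if (!"female" %in% names(observations)) {
      abort("terms involve 'female' but observations have no female column")
    }
    fem <- factor(observations$female)
    xlevels <- levels(fem)
    if (length(xlevels) < 2) {
      terms <- setdiff(terms, c("female", "gd:female"))
      xlevels <- NULL
    }
  }
  df <- tibble(gd = observations$gd)
  if (!is.null(xlevels)) df$female <- factor(observations$female, xlevels)
  ff <- stats::reformulate(if (length(terms) == 0) "1" else terms)
  X <- model.matrix(ff, data = df)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[seq(qrX$rank + 1, ncol(X))]]
    abort(paste0("design matrix is rank deficient; aliased term(s): ",
                 paste(aliased, collapse = ", ")))
  }
  list(X = X, terms = terms, assign = attr(X, "assign"), xlevels = xlevels)
}

# Binomial IRLS with logit link; k successes of n trials per row.
# Start at the Haldane-corrected empirical logits.
qglm_irls <- function(X, k, n, max_iter = 50, tol = 1e-10) {
  p_obs <- k / n
  eta <- qlogis((k + 0.5) / (n + 1))
  dev_old <- Inf
  beta <- NULL
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    mu <- plogis(eta)
    w <- n * mu * (1 - mu)
    z <- eta + (p_obs - mu) / (mu * (1 - mu))
    wls <- lm.wfit(X, z, w)
    beta <- wls$coefficients
    eta <- drop(X %*% beta)
    dev <- binom_deviance(k, n, plogis(eta))
    if (is.finite(dev_old) &&
        abs(dev - dev_old) / (abs(dev) + 0.1) < tol) {
      converged <- TRUE
      break
    }
    dev_old <- dev
  }
  if (!converged) {
    warn(sprintf("IRLS did not converge in %d iterations", max_iter))
  }
  if (any(abs(eta) > 30)) {
    warn("fitted probabilities numerically 0 or 1: possible complete separation")
  }
  mu <- plogis(eta)
  pearson <- sum(n * (p_obs - mu)^2 / (mu * (1 - mu)))
  df_residual <- length(k) - ncol(X)
  dispersion <- if (df_residual > 0) pearson / df_residual else NA_real_
  xtwx <- crossprod(X * sqrt(n * mu * (1 - mu)))
  cov_unscaled <- chol2inv(chol(xtwx))
  dimnames(cov_unscaled) <- list(colnames(X), colnames(X))
  se <- sqrt(dispersion * diag(cov_unscaled))
  tval <- beta / se
  list(
    beta = beta, se = se, t = tval,
    p_value = 2 * stats::pt(abs(tval), df_residual, lower.tail = FALSE),
    cov_unscaled = cov_unscaled,
    dispersion = dispersion,
    deviance = binom_deviance(k, n, mu),
    null_deviance = binom_deviance(k, n, sum(k) / sum(n)),
    pearson = pearson,
    df_residual = df_residual,
    n_obs = length(k),
    fitted = unname(mu),
    converged = converged,
    iterations = iter
  )
}

# Binomial deviance with the 0*log(0) = 0 convention.
binom_deviance <- function(k, n, mu) {
  xlogy <- function(x, y) ifelse(x == 0, 0, x * log(x / y))
  2 * sum(xlogy(k, n * mu) + xlogy(n - k, n * (1 - mu)))
}

#' @export
print.barrier_glm <- function(x, ...) {
  cat("Quasibinomial logit fit (", paste(c("1", x$terms), collapse = " + "),
      ")\n", sep = "")
  print(tidy(x), ...)
  cat(sprintf("dispersion %.4g on %d residual df; deviance %.4g%s\n",
              x$dispersion, x$df_residual, x$deviance,
              if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' Predict barrier strength from a fitted model
#'
#' @param object A `barrier_glm` fit.
#' @param newdata Tibble with a `gd` column (and `female` when the model
#'   uses it); defaults to the training data.
#' @param type `"response"` (probability) or `"link"` (logit).
#' @param ... Unused.
#' @export
predict.barrier_glm <- function(object, newdata = NULL,
                                type = c("response", "link"), ...) {
  type <- arg_match(type)
  if (is.null(newdata)) newdata <- object$data
  df <- tibble(gd = newdata$gd)
  if (!is.null(object$xlevels)) {
    df$female <- factor(newdata$female, object$xlevels)
  }
  ff <- stats::reformulate(if (length(object$terms) == 0) "1" else object$terms)
  X <- model.matrix(ff, data = df)
  eta <- unname(drop(X %*% object$beta[colnames(X)]))
  if (type == "link") eta else plogis(eta)
}

#' Sequential (type-I) quasi-F tests along a nested term sequence
#'
#' Adds terms in the stated order, forming for each addition
#' `F = (deviance reduction / df gained) / phi`, where `phi` is the
#' Pearson dispersion of the largest model in the sequence; p-values come
#' from the F distribution with (df gained, residual df of the largest
#' model). This is the analysis-of-deviance convention matching
#' `anova.glm(..., test = "F")` for a quasibinomial fit.
#'
#' @inheritParams fit_barrier_glm
#' @param terms Terms added sequentially after the intercept, in order.
#' @return A tibble: `term`, `df1`, `df2`, `deviance`, `f`, `p_value`,
#'   with the full-model dispersion as attribute `"dispersion"`.
#' @examples
#' obs <- barrier_observations(simulate_study(sim_config(seed = 1)))
#' sequential_f_tests(dplyr::filter(obs, barrier == "prezygotic"),
#'                    terms = c("gd", "female", "gd:female"))
#' @export
sequential_f_tests <- function(observations,
                               terms = c("gd", "female", "gd:female"),
                               max_iter = 50, tol = 1e-10) {
  fits <- vector("list", length(terms) + 1)
  fits[[1]] <- fit_barrier_glm(observations, terms = character(0),
                               max_iter = max_iter, tol = tol)
  kept <- character(0)
  used <- logical(length(terms))
  for (i in seq_along(terms)) {
    kept <- c(kept, terms[i])
    fits[[i + 1]] <- fit_barrier_glm(observations, terms = kept,
                                     max_iter = max_iter, tol = tol)
    used[i] <- fits[[i + 1]]$df_residual < fits[[i]]$df_residual
  }
  full <- fits[[length(fits)]]
  phi <- full$dispersion
  df2 <- full$df_residual
  dd <- -diff(vapply(fits, `[[`, numeric(1), "deviance"))
  df1 <- -diff(vapply(fits, `[[`, numeric(1), "df_residual"))
  keep <- df1 > 0
  f <- pmax(0, dd[keep] / df1[keep]) / phi
  out <- tibble(
    term = terms[keep], df1 = df1[keep], df2 = df2,
    deviance = dd[keep], f = f,
    p_value = pf(f, df1[keep], df2, lower.tail = FALSE)
  )
  attr(out, "dispersion") <- phi
  attr(out, "full_fit") <- full
  out
}

#' Interaction-guided model simplification and refitting
#'
#' Implements the published decision rule for each barrier model. The full
#' model (distance, female population, interaction) is fitted and the
#' interaction tested sequentially at level `alpha`:
#'
#' * interaction significant — the distance effect is re-analysed within
#'   each female population separately, with a distance-only fit and its
#'   own quasi-F test per population (subsets with fewer than `min_obs`
#'   observations are skipped with a warning);
#' * interaction not significant — the interaction is dropped and the
#'   main-effects model refitted, reporting sequential tests for distance
#'   and female population.
#'
#' Inputs with a single female population skip the factor terms entirely
#' and return a distance-only fit.
#'
#' @inheritParams fit_barrier_glm
#' @param alpha Significance level for the interaction decision (0.05, as
#'   in the published analysis).
#' @param min_obs Minimum observations for a per-population refit.
#' @return A `barrier_analysis` object: `route` (one of
#'   `"per_population"`, `"main_effects"`, `"gd_only"`),
#'   `interaction_test`, `tests`, `fits`, and the full-model fit.
#' @examples
#' obs <- barrier_observations(simulate_study(sim_config(seed = 1)))
#' simplify_barrier_model(dplyr::filter(obs, barrier == "inviability"))
#' @export
simplify_barrier_model <- function(observations, alpha = 0.05, min_obs = 3,
                                   max_iter = 50, tol = 1e-10) {
  obs <- as_tibble(observations)
  n_pops <- if ("female" %in% names(obs)) length(unique(obs$female)) else 1L
  if (n_pops < 2) {
    fit <- gd_only_fit(obs, max_iter = max_iter, tol = tol)
    res <- list(route = "gd_only", interaction_test = NULL,
                tests = sequential_f_tests(obs, "gd"),
                fits = list(gd_only = fit), full_fit = fit)
    return(structure(res, class = "barrier_analysis"))
  }
  full_tests <- sequential_f_tests(obs, c("gd", "female", "gd:female"),
                                   max_iter = max_iter, tol = tol)
  inter <- filter(full_tests, .data$term == "gd:female")
  if (nrow(inter) == 1 && inter$p_value < alpha) {
    pops <- sort(unique(obs$female))
    fits <- list()
    tests <- list()
    for (pop in pops) {
      sub <- filter(obs, .data$female == pop)
      if (nrow(sub) < min_obs) {
        warn(sprintf("female group '%s' skipped: only %d observation(s)",
                     pop, nrow(sub)))
        next
      }
      tst <- sequential_f_tests(sub, "gd", max_iter = max_iter, tol = tol)
      fits[[pop]] <- attr(tst, "full_fit")
      tests[[pop]] <- mutate(tst, female = pop, .before = 1)
    }
    res <- list(route = "per_population", interaction_test = inter,
                tests = bind_rows(tests), fits = fits,
                full_fit = attr(full_tests, "full_fit"))
  } else {
    main_tests <- sequential_f_tests(obs, c("gd", "female"),
                                     max_iter = max_iter, tol = tol)
    res <- list(route = "main_effects", interaction_test = inter,
                tests = main_tests,
                fits = list(main_effects = attr(main_tests, "full_fit")),
                full_fit = attr(full_tests, "full_fit"))
  }
  structure(res, class = "barrier_analysis")
}

#' @export
print.barrier_analysis <- function(x, ...) {
  if (!is.null(x$interaction_test)) {
    it <- x$interaction_test
    cat(sprintf("gd x female interaction: F(%d,%d) = %.3f, p = %.4g\n",
                it$df1, it$df2, it$f, it$p_value))
  }
  cat("route:", x$route, "\n")
  print(x$tests, ...)
  invisible(x)
}
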