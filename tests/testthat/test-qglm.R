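test_that("closed-form cases: intercept-only and saturated two-point fits", {
  f0 <- fit_barrier_glm(tibble::tibble(k = 30, n = 100, gd = 0),
                        terms = character(0))
  expect_equal(unname(f0$beta), qlogis(0.30), tolerance = 1e-8)

  d2 <- tibble::tibble(k = c(10, 90), n = c(100, 100), gd = c(0, 0.1))
  f2 <- gd_only_fit(d2)
  expect_equal(unname(f2$fitted), c(0.10, 0.90), tolerance = 1e-8)
  expect_equal(f2$df_residual, 0)
})

test_that("IRLS matches the reference quasibinomial GLM", {
  set.seed(301)
  for (i in 1:8) {
    d <- random_glm_data(sample(10:30, 1))
    f <- fit_barrier_glm(d, c("gd", "female"))
    g <- stats::glm(cbind(k, n - k) ~ gd + female,
                    family = stats::quasibinomial(), data = d,
                    control = stats::glm.control(epsilon = 1e-12))
    sg <- summary(g)
    expect_equal(unname(f$beta), unname(coef(g)), tolerance = 1e-6)
    expect_equal(unname(f$se), unname(sg$coefficients[, 2]),
                 tolerance = 1e-6)
    expect_equal(f$dispersion, sg$dispersion, tolerance = 1e-6)
    expect_equal(f$deviance, stats::deviance(g), tolerance = 1e-8)
  }
})

test_that("sequential quasi-F tests match the reference analysis of deviance", {
  set.seed(302)
  d <- random_glm_data(28)
  ft <- sequential_f_tests(d, c("gd", "female", "gd:female"))
  g <- stats::glm(cbind(k, n - k) ~ gd * female,
                  family = stats::quasibinomial(), data = d,
                    control = stats::glm.control(epsilon = 1e-12))
  a <- stats::anova(g, test = "F")
  expect_equal(ft$f, a$F[-1], tolerance = 1e-6)
  expect_equal(ft$p_value, a$`Pr(>F)`[-1], tolerance = 1e-6)
  expect_equal(ft$df1, a$Df[-1])
  expect_equal(unique(ft$df2), g$df.residual)
  # deviance reductions are non-negative along the nested sequence
  expect_true(all(ft$deviance >= -1e-8))
})

test_that("a term adding no information gives F = 0, p = 1", {
  d <- tibble::tibble(k = c(10, 20, 30, 40), n = rep(100, 4),
                      gd = c(0, 0, 0.05, 0.05),
                      female = c("A", "A", "A", "A"))
  # female has one level: term dropped, fit reduces to gd-only
  f <- fit_barrier_glm(d, c("gd", "female"))
  expect_equal(f$terms, "gd")
  # two female groups with identical data: by symmetry the group effect is
  # exactly zero, so adding it reduces the deviance by nothing
  d2 <- tibble::tibble(gd = rep(c(0, 0.05, 0.1), 2),
                       k = rep(c(10, 60, 90), 2), n = 100,
                       female = rep(c("A", "B"), each = 3))
  ft <- sequential_f_tests(d2, c("gd", "female"))
  expect_equal(ft$f[ft$term == "female"], 0, tolerance = 1e-5)
  expect_equal(ft$p_value[ft$term == "female"], 1, tolerance = 1e-5)
})

test_that("dispersion scales uncertainty but never the coefficients", {
  set.seed(303)
  d <- random_glm_data(24)
  f <- fit_barrier_glm(d, c("gd", "female"))
  g_binom <- stats::glm(cbind(k, n - k) ~ gd + female,
                        family = stats::binomial(), data = d)
  expect_equal(unname(f$beta), unname(coef(g_binom)), tolerance = 1e-6)
  sg <- summary(g_binom)
  expect_equal(unname(f$se),
               unname(sg$coefficients[, 2]) * sqrt(f$dispersion),
               tolerance = 1e-6)
})

test_that("coefficients are invariant to disaggregating observations", {
  set.seed(304)
  d <- random_glm_data(15)
  halves <- dplyr::bind_rows(
    dplyr::mutate(d, k = floor(k / 2), n = floor(n / 2)),
    dplyr::mutate(d, k = k - floor(k / 2), n = n - floor(n / 2))
  )
  f1 <- fit_barrier_glm(d, c("gd", "female"))
  f2 <- fit_barrier_glm(halves, c("gd", "female"))
  expect_equal(f1$beta, f2$beta, tolerance = 1e-8)
})

test_that("the IRLS fixed point satisfies the score equations", {
  set.seed(305)
  d <- random_glm_data(20)
  f <- fit_barrier_glm(d, c("gd", "female"))
  X <- stats::model.matrix(~ gd + female, d)
  score <- drop(t(X) %*% (d$k - d$n * f$fitted))
  expect_lt(max(abs(score)), 1e-8)
})

test_that("degenerate designs are reported: aliasing and separation", {
  d <- tibble::tibble(k = c(5, 10, 15), n = rep(50, 3), gd = 0)
  expect_error(gd_only_fit(d), "aliased.*gd")
  sep <- tibble::tibble(k = c(0, 0, 200, 200), n = rep(200, 4),
                        gd = c(0, 0.01, 0.06, 0.07))
  expect_warning(gd_only_fit(sep), "separation")
})

test_that("simplification routes by the interaction test as specified", {
  # heterogeneous slopes across female groups -> per-population refits
  set.seed(306)
  mk <- function(slopes, n_per = 7) {
    purrr::imap_dfr(slopes, function(b, fem) {
      gd <- c(0, runif(n_per - 1, 0.01, 0.075))
      n <- rpois(n_per, 400) + 50
      tibble::tibble(female = fem, gd = gd, n = n,
                     k = rbinom(n_per, n, plogis(-1.5 + b * gd +
                                                   rnorm(n_per, 0, 0.3))))
    })
  }
  het <- mk(c(A = 0, B = 0, C = 60, D = 60))
  a_het <- simplify_barrier_model(het)
  expect_equal(a_het$route, "per_population")
  expect_true(all(c("A", "B", "C", "D") %in% names(a_het$fits)))
  # groups simulated with zero slope stay non-significant
  expect_true(all(a_het$tests$p_value[a_het$tests$female %in% c("A", "B")] >
                    0.05))
  expect_true(all(a_het$tests$p_value[a_het$tests$female %in% c("C", "D")] <
                    0.05))

  hom <- mk(c(A = 40, B = 40, C = 40, D = 40))
  a_hom <- simplify_barrier_model(hom)
  expect_equal(a_hom$route, "main_effects")
  expect_equal(a_hom$tests$term, c("gd", "female"))

  # single population: factor terms dropped automatically
  single <- dplyr::filter(het, female == "C")
  a_one <- simplify_barrier_model(single)
  expect_equal(a_one$route, "gd_only")
  expect_equal(a_one$fits$gd_only$terms, "gd")

  # undersized subsets are skipped with a warning on the per-population route
  small <- dplyr::bind_rows(het,
                            tibble::tibble(female = "E", gd = c(0.02, 0.05),
                                           n = 100, k = c(30, 90)))
  expect_warning(a_sm <- simplify_barrier_model(small), "skipped")
  expect_false("E" %in% names(a_sm$fits))
})

test_that("the gd quasi-F test keeps its size under the null and has power", {
  cfg_null <- sim_config(
    barrier_params = list(prezygotic = c(a = qlogis(0.25), b = 0),
                          inviability = c(a = qlogis(0.2), b = 0),
                          sterility = c(a = qlogis(0.2), b = 0)),
    backcross_dams = character(0))
  set.seed(307)
  R <- 300
  rej <- 0
  for (r in seq_len(R)) {
    obs <- barrier_observations(simulate_study(cfg_null),
                                barriers = "prezygotic")
    rej <- rej + (sequential_f_tests(obs, "gd")$p_value[1] < 0.05)
  }
  # 99% binomial bounds around 0.05 at R = 300
  bounds <- qbinom(c(0.005, 0.995), R, 0.05) / R
  expect_gte(rej / R, bounds[1])
  expect_lte(rej / R, bounds[2])

  # strong effect (slope ~40, the study layout): near-certain rejection
  cfg_eff <- sim_config(backcross_dams = character(0))
  rej <- 0
  for (r in seq_len(100)) {
    obs <- suppressWarnings(
      barrier_observations(simulate_study(cfg_eff), barriers = "inviability"))
    rej <- rej + (sequential_f_tests(obs, "gd")$p_value[1] < 0.05)
  }
  expect_gt(rej / 100, 0.9)
})

test_that("tidy, glance and augment expose the fit in broom shape", {
  set.seed(308)
  d <- random_glm_data(18)
  f <- fit_barrier_glm(d, c("gd", "female"))
  td <- tidy(f)
  expect_named(td, c("term", "estimate", "std.error", "statistic", "p.value"))
  expect_equal(nrow(td), length(f$beta))
  gl <- glance(f)
  expect_equal(gl$nobs, 18)
  expect_true(gl$converged)
  expect_gt(gl$dispersion, 0)
  expect_equal(gl$df.residual, 18 - length(f$beta))
  au <- augment(f)
  expect_equal(au$.fitted, unname(f$fitted))
  expect_equal(nrow(au), 18)
})
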