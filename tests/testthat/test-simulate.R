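test_that("the default study layout has 49 parental and 16 backcross records", {
  crosses <- simulate_study(sim_config(seed = 1))
  counts <- table(crosses$cross_class)
  expect_equal(unname(counts["interpopulation"]), 42L)
  expect_equal(unname(counts["control"]), 7L)
  expect_equal(unname(counts["backcross"]), 16L)
  expect_silent(validate_crosses(crosses))
})

test_that("identical seed and config give byte-identical datasets", {
  cfg <- sim_config(seed = 77)
  expect_identical(simulate_study(cfg), simulate_study(cfg))
  # and a different seed gives a different dataset
  expect_false(identical(simulate_study(sim_config(seed = 78)),
                         simulate_study(cfg)))
})

test_that("every simulated record satisfies the accounting identity", {
  for (seed in 1:5) {
    cfg <- sim_config(seed = seed, rho = runif(1, 0, 0.4),
                      fecundity_mean = runif(1, 5, 80),
                      n_pairs = sample(5:30, 1))
    crosses <- simulate_study(cfg)
    expect_silent(validate_crosses(crosses))
    expect_true(all(crosses$eggs == crosses$sons + crosses$daughters +
                      crosses$unhatched + crosses$dead_juv))
  }
})

test_that("control crosses realise the configured background son fraction", {
  cfg <- sim_config(
    barrier_params = list(prezygotic = c(a = qlogis(0.25), b = 12.728),
                          inviability = c(a = -1.337, b = 39.450),
                          sterility = c(a = -1.308, b = 54.552)),
    n_pairs = 30)
  set.seed(9)
  rec <- simulate_cross("J", "J", 0, cfg)
  frac <- rec$sons / rec$eggs
  # beta-binomial SE with inflation 1 + (m-1)rho at m ~ 40 eggs/female
  se <- sqrt(0.25 * 0.75 * (1 + 39 * cfg$rho) / rec$eggs)
  expect_lt(abs(frac - 0.25), 3 * se)
})

test_that("a steep prezygotic slope saturates the brood with males", {
  cfg <- sim_config(
    barrier_params = list(prezygotic = c(a = 0, b = 1e3),
                          inviability = c(a = -1.337, b = 39.450),
                          sterility = c(a = -1.308, b = 54.552)))
  set.seed(10)
  rec <- simulate_cross("F", "J", 0.1, cfg)
  expect_gt(rec$sons / rec$eggs, 0.99)
})

test_that("beta-binomial sampling has the advertised variance inflation", {
  set.seed(11)
  m <- 50L
  p <- 0.3
  draws0 <- isomite:::rbetabinom(rep(m, 4000), p, 0)
  draws3 <- isomite:::rbetabinom(rep(m, 4000), p, 0.3)
  v_binom <- m * p * (1 - p)
  expect_equal(var(draws0), v_binom, tolerance = 0.1)
  expect_equal(var(draws3), v_binom * (1 + (m - 1) * 0.3), tolerance = 0.1)
  # degenerate probabilities are deterministic
  expect_equal(isomite:::rbetabinom(c(5L, 9L), 0, 0.3), c(0L, 0L))
  expect_equal(isomite:::rbetabinom(c(5L, 9L), 1, 0.3), c(5L, 9L))
})

test_that("backcross sterility hits its boundary and background levels", {
  # death probability ~1: no viable offspring at all
  cfg1 <- sim_config(
    barrier_params = list(prezygotic = c(a = -1.453, b = 12.728),
                          inviability = c(a = -1.337, b = 39.450),
                          sterility = c(a = 50, b = 0)))
  set.seed(12)
  rec <- simulate_backcross("IT", avien_distances()["I", "T"], cfg1)
  expect_equal(rec$daughters + rec$sons, 0)
  expect_equal((rec$unhatched + rec$dead_juv) / rec$eggs, 1)

  # zero-distance dams (CIM/CN/K-like) show only background mortality
  cfg2 <- sim_config(
    barrier_params = list(prezygotic = c(a = -1.453, b = 12.728),
                          inviability = c(a = -1.337, b = 39.450),
                          sterility = c(a = qlogis(0.05), b = 54.552)),
    n_pairs = 30)
  rec0 <- simulate_backcross("CNK", 0, cfg2)
  ster <- (rec0$unhatched + rec0$dead_juv) / rec0$eggs
  se <- sqrt(0.05 * 0.95 * (1 + 39 * cfg2$rho) / rec0$eggs)
  expect_lt(abs(ster - 0.05), 3 * se)
  # zero-distance dams produce viable sons; diverged dams do not
  expect_gt(rec0$sons, 0)
  expect_equal(rec$sons, 0)
})

test_that("the generator and the index module are mutually consistent", {
  cfg <- sim_config()
  gd <- 0.05
  set.seed(13)
  reps <- purrr::map_dfr(1:40, ~ simulate_cross("F", "I", gd, cfg))
  obs <- barrier_observations(reps, barriers = "prezygotic")
  p_true <- plogis(-1.453 + 12.728 * gd)
  pooled <- sum(obs$k) / sum(obs$n)
  se <- sqrt(p_true * (1 - p_true) * (1 + 39 * cfg$rho) / sum(obs$n))
  expect_lt(abs(pooled - p_true), 3 * se)
})

test_that("simulated data recover the generating model parameters", {
  cfg <- sim_config(seed = 14, backcross_dams = character(0))
  obs <- suppressWarnings(
    barrier_observations(simulate_study(cfg), barriers = "inviability"))
  f <- gd_only_fit(obs)
  expect_lt(abs(unname(f$beta["gd"]) - 39.450), 3 * f$se["gd"])
  expect_lt(abs(unname(f$beta[1]) + 1.337), 3 * f$se[1])
})

test_that("K2P pair evolution matches its closed-form site expectations", {
  set.seed(15)
  p0 <- evolve_k2p_pair(500, 1, 0.5, 0)
  expect_identical(unname(p0[1]), unname(p0[2]))
  set.seed(16)
  alpha <- 1; beta <- 0.25; t <- 0.08
  pair <- evolve_k2p_pair(2e5, alpha, beta, t)
  part <- k2p_site_partition(pair[1], pair[2])
  P_exp <- 0.25 + 0.25 * exp(-4 * beta * t) - 0.5 * exp(-2 * (alpha + beta) * t)
  Q_exp <- 2 * (0.25 - 0.25 * exp(-4 * beta * t))
  expect_lt(abs(part$P - P_exp), 3 * sqrt(P_exp * (1 - P_exp) / 2e5))
  expect_lt(abs(part$Q - Q_exp), 3 * sqrt(Q_exp * (1 - Q_exp) / 2e5))
})

test_that("configuration validation rejects out-of-range parameters", {
  expect_error(sim_config(rho = 1), "rho")
  expect_error(sim_config(fecundity_mean = 0))
  expect_error(sim_config(n_pairs = 0))
  expect_error(sim_config(unhatched_frac = 1.2))
})
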