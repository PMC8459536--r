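# Random valid cross records: the four offspring classes are drawn by
# multinomial split of the egg total, so the accounting identity holds by
# construction.
random_cross_records <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  eggs <- sample(20:400, n, replace = TRUE)
  probs <- t(vapply(seq_len(n), function(i) {
    p <- rgamma(4, shape = c(2, 3, 1, 1))
    p / sum(p)
  }, numeric(4)))
  split <- t(vapply(seq_len(n), function(i) {
    drop(rmultinom(1, eggs[i], probs[i, ]))
  }, numeric(4)))
  tibble::tibble(
    female_pop = sample(c("F", "T", "I", "CIM", "CN", "K", "J"), n, TRUE),
    male_pop = sample(c("F", "T", "I", "CIM", "CN", "K", "J"), n, TRUE),
    cross_class = ifelse(female_pop == male_pop, "control", "interpopulation"),
    dam_code = "",
    n_pairs = sample(12:30, n, TRUE),
    eggs = eggs,
    sons = split[, 1], daughters = split[, 2],
    unhatched = split[, 3], dead_juv = split[, 4]
  )
}

# Single hand-built record for the worked examples.
one_record <- function(eggs, sons, daughters, unhatched, dead_juv,
                       female_pop = "F", male_pop = "T",
                       cross_class = "interpopulation", dam_code = "") {
  tibble::tibble(
    female_pop = female_pop, male_pop = male_pop, cross_class = cross_class,
    dam_code = dam_code, n_pairs = 1L, eggs = eggs, sons = sons,
    daughters = daughters, unhatched = unhatched, dead_juv = dead_juv
  )
}

# Overdispersed random fitting datasets for oracle comparisons.
random_glm_data <- function(n_obs, n_groups = 4) {
  gd <- runif(n_obs, 0, 0.08)
  tibble::tibble(
    gd = gd,
    female = sample(LETTERS[seq_len(n_groups)], n_obs, replace = TRUE),
    n = rpois(n_obs, 150) + 10
  ) |>
    dplyr::mutate(k = rbinom(n_obs, n, plogis(-1 + 30 * gd +
                                                rnorm(n_obs, 0, 0.5))))
}
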