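#' Configuration for the synthetic crossing experiment
#'
#' Bundles the parameters of the beta-binomial cross simulator. Defaults
#' reproduce the published seven-population study design: the distance
#' matrix and the distance-response of each barrier default to the
#' published values ([avien_distances()], [avien_barrier_coefs()]), with
#' 20 replicate pairs per combination (the study used 12-30) and a mean
#' fecundity of 40 eggs per female over the five-day oviposition window
#' (roughly 8 eggs/day, typical for tetranychid mites; combination totals
#' land in the hundreds of eggs).
#'
#' Per replicate female the mechanism is arrhenotokous: the egg count is
#' Poisson; each egg stays unfertilized — and so develops into a son —
#' with probability `logit^-1(a_pre + b_pre * gd)`; each fertilized
#' (female-destined) egg dies before adulthood with probability
#' `logit^-1(a_inv + b_inv * gd)`. Within-female probabilities are drawn
#' from a beta distribution with correlation `rho`, making counts
#' beta-binomial with variance inflation `1 + (m - 1) * rho` for brood
#' size `m` — the overdispersion the quasibinomial models estimate.
#' Diploid deaths are recorded as unhatched eggs with probability
#' `unhatched_frac`, else as dead juveniles (only their sum enters any
#' index; the split is cosmetic).
#'
#' @param distances Labelled symmetric distance matrix.
#' @param barrier_params Named list with numeric `c(a, b)` logit
#'   intercept/slope pairs for `prezygotic`, `inviability` and
#'   `sterility`.
#' @param rho Beta-binomial intra-female correlation in `[0, 1)`; `0`
#'   gives plain binomial sampling.
#' @param fecundity_mean Expected eggs per female over the oviposition
#'   window.
#' @param n_pairs Replicate pairs per cross combination.
#' @param unhatched_frac Fraction of diploid deaths recorded as unhatched
#'   eggs (arbitrary bookkeeping split, default 0.7).
#' @param son_viability Viability of haploid sons of hybrid dams with
#'   nonzero parental distance (default 0: hybrid males are inviable, as
#'   observed; sons of genetically identical parents are fully viable).
#' @param backcross_dams Dam codes of the backcross series.
#' @param seed Integer seed applied by [simulate_study()]; `NULL` leaves
#'   the RNG state alone.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(distances = avien_distances(),
                       barrier_params = list(
                         prezygotic  = c(a = -1.453, b = 12.728),
                         inviability = c(a = -1.337, b = 39.450),
                         sterility   = c(a = -1.308, b = 54.552)
                       ),
                       rho = 0.1,
                       fecundity_mean = 40,
                       n_pairs = 20,
                       unhatched_frac = 0.7,
                       son_viability = 0,
                       backcross_dams = avien_backcross_dams(),
                       seed = NULL) {
  check_distance_matrix(distances)
  stopifnot(
    all(c("prezygotic", "inviability", "sterility") %in% names(barrier_params)),
    all(vapply(barrier_params, length, 1L) == 2),
    rho >= 0, rho < 1,
    fecundity_mean > 0, n_pairs >= 1,
    unhatched_frac >= 0, unhatched_frac <= 1,
    son_viability >= 0, son_viability <= 1
  )
  structure(
    list(distances = distances, barrier_params = barrier_params, rho = rho,
         fecundity_mean = fecundity_mean, n_pairs = n_pairs,
         unhatched_frac = unhatched_frac, son_viability = son_viability,
         backcross_dams = backcross_dams, seed = seed),
    class = "sim_config")
}

# Beta-binomial draws: one brood-level probability per draw, correlated
# within brood by rho. rho = 0 degenerates to binomial.
rbetabinom <- function(size, prob, rho) {
  n <- length(size)
  if (prob <= 0) return(rep(0L, n))
  if (prob >= 1) return(as.integer(size))
  if (rho == 0) return(rbinom(n, size, prob))
  shape <- (1 - rho) / rho
  p <- rbeta(n, prob * shape, (1 - prob) * shape)
  rbinom(n, size, p)
}

# Non-degenerate Poisson brood sizes: resample until at least one egg in
# the combination total (all-zero totals are astronomically rare at the
# default fecundity but would break the accounting precondition).
draw_eggs <- function(n_pairs, fecundity_mean) {
  repeat {
    eggs <- rpois(n_pairs, fecundity_mean)
    if (sum(eggs) >= 1) return(eggs)
  }
}

barrier_prob <- function(params, gd) plogis(params[["a"]] + params[["b"]] * gd)

#' Simulate one parental cross combination
#'
#' Draws `n_pairs` replicate females for the combination and aggregates
#' their broods to a single cross record (see [sim_config()] for the
#' generating mechanism). Uses the current RNG state; seed control lives
#' in [simulate_study()].
#'
#' @param female_pop,male_pop Population labels.
#' @param gd Genetic distance between the two populations.
#' @param cfg A [sim_config()].
#' @return A one-row cross-record tibble satisfying the accounting
#'   identity by construction.
#' @export
simulate_cross <- function(female_pop, male_pop, gd, cfg) {
  eggs <- draw_eggs(cfg$n_pairs, cfg$fecundity_mean)
  m <- barrier_prob(cfg$barrier_params$prezygotic, gd)
  v <- barrier_prob(cfg$barrier_params$inviability, gd)
  sons <- rbetabinom(eggs, m, cfg$rho)
  deaths <- rbetabinom(eggs - sons, v, cfg$rho)
  unhatched <- rbinom(length(deaths), deaths, cfg$unhatched_frac)
  daughters <- eggs - sons - deaths
  tibble(
    female_pop = female_pop, male_pop = male_pop,
    cross_class = if (identical(female_pop, male_pop)) "control"
                  else "interpopulation",
    dam_code = "",
    n_pairs = cfg$n_pairs,
    eggs = sum(eggs), sons = sum(sons),
    daughters = sum(daughters),
    unhatched = sum(unhatched), dead_juv = sum(deaths) - sum(unhatched)
  )
}

#' Simulate one backcross combination
#'
#' A hybrid dam (identified by `dam_code`) crossed to a male of her
#' maternal population. Each egg dies with probability
#' `logit^-1(a_ster + b_ster * gd)` (recorded as unhatched or dead
#' juvenile), where `gd` is the distance between the dam's two parental
#' populations. Among the surviving eggs, the unfertilized fraction (the
#' control-level fertilization-failure rate `logit^-1(a_pre)`) is
#' male-destined; those sons survive only with probability
#' `son_viability` when `gd > 0` (hybrid males are hardly viable),
#' non-survivors being recorded as dead juveniles.
#'
#' @param dam_code Hybrid dam code, mother's population first.
#' @param gd Genetic distance between the dam's parental populations.
#' @param cfg A [sim_config()].
#' @return A one-row cross-record tibble.
#' @export
simulate_backcross <- function(dam_code, gd, cfg) {
  parents <- parse_dam_code(dam_code, rownames(cfg$distances))
  eggs <- draw_eggs(cfg$n_pairs, cfg$fecundity_mean)
  s <- barrier_prob(cfg$barrier_params$sterility, gd)
  m0 <- plogis(cfg$barrier_params$prezygotic[["a"]])
  viab <- if (gd > 0) cfg$son_viability else 1
  deaths <- rbetabinom(eggs, s, cfg$rho)
  unhatched <- rbinom(length(deaths), deaths, cfg$unhatched_frac)
  survivors <- eggs - deaths
  unfert <- rbetabinom(survivors, m0, cfg$rho)
  sons <- rbinom(length(unfert), unfert, viab)
  daughters <- survivors - unfert
  dead_juv <- sum(deaths) - sum(unhatched) + sum(unfert) - sum(sons)
  tibble(
    female_pop = dam_code, male_pop = parents$mother,
    cross_class = "backcross", dam_code = dam_code,
    n_pairs = cfg$n_pairs,
    eggs = sum(eggs), sons = sum(sons),
    daughters = sum(daughters),
    unhatched = sum(unhatched),
    dead_juv = dead_juv
  )
}

#' Simulate the full crossing study
#'
#' Emulates the published design on the configured populations: all
#' ordered interpopulation combinations (42 for seven populations), one
#' intra-population control per population (7), and the configured
#' backcross series (16 hybrid-dam types by default). Setting
#' `cfg$seed` makes the dataset reproducible.
#'
#' @param cfg A [sim_config()].
#' @return A validated cross-record tibble, one row per combination
#'   (49 parental + 16 backcross rows under the defaults).
#' @examples
#' crosses <- simulate_study(sim_config(seed = 42))
#' dplyr::count(crosses, cross_class)
#' @export
simulate_study <- function(cfg = sim_config()) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  labels <- rownames(cfg$distances)
  combos <- expand.grid(female_pop = labels, male_pop = labels,
                        stringsAsFactors = FALSE)
  parental <- purrr::pmap(combos, function(female_pop, male_pop) {
    simulate_cross(female_pop, male_pop,
                   cfg$distances[female_pop, male_pop], cfg)
  })
  backcross <- purrr::map(cfg$backcross_dams, function(code) {
    parents <- parse_dam_code(code, labels)
    simulate_backcross(code, cfg$distances[parents$mother, parents$father],
                       cfg)
  })
  validate_crosses(bind_rows(c(parental, backcross)))
}

#' Evolve a sequence pair under the Kimura two-parameter process
#'
#' Draws an ancestral sequence uniform over A/C/G/T and substitutes each
#' site independently over total divergence time `t` with transition rate
#' `alpha_ts` and per-pathway transversion rate `beta_tv`, using the
#' closed-form K2P transition probabilities. The expected K2P distance
#' between the pair is `(alpha_ts + 2 * beta_tv) * t`.
#'
#' @param length Number of sites.
#' @param alpha_ts Transition rate.
#' @param beta_tv Rate of each of the two transversion pathways.
#' @param t Total divergence time separating the pair.
#' @return A named character vector of two aligned sequences.
#' @examples
#' pair <- evolve_k2p_pair(1000, alpha_ts = 1, beta_tv = 0.5, t = 0.05)
#' k2p_distance(k2p_site_partition(pair[1], pair[2]))
#' @export
evolve_k2p_pair <- function(length, alpha_ts = 1, beta_tv = 0.5, t) {
  stopifnot(length >= 1, alpha_ts >= 0, beta_tv >= 0, t >= 0)
  e4b <- exp(-4 * beta_tv * t)
  e2ab <- exp(-2 * (alpha_ts + beta_tv) * t)
  probs <- c(same = 0.25 + 0.25 * e4b + 0.5 * e2ab,
             ts   = 0.25 + 0.25 * e4b - 0.5 * e2ab,
             tv1  = 0.25 - 0.25 * e4b,
             tv2  = 0.25 - 0.25 * e4b)
  bases <- c("A", "C", "G", "T")
  # per starting base: result under same / transition / transversion 1 / 2
  endpoint <- rbind(A = c("A", "G", "C", "T"),
                    C = c("C", "T", "A", "G"),
                    G = c("G", "A", "C", "T"),
                    T = c("T", "C", "A", "G"))
  anc <- sample(bases, length, replace = TRUE)
  cat <- sample.int(4, length, replace = TRUE, prob = probs)
  der <- endpoint[cbind(match(anc, bases), cat)]
  c(a = paste(anc, collapse = ""), b = paste(der, collapse = ""))
}
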