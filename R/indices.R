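#' Reproductive-isolation indices from offspring counts
#'
#' Arrhenotoky makes each barrier directly countable. For parental crosses
#' (controls and interpopulation crosses):
#'
#' * `prezygotic` — lack of fertilization, `sons / eggs`: unfertilized
#'   (haploid) eggs develop into sons, so fertilization failure inflates
#'   the male share of the brood.
#' * `inviability` — mortality among the fertilized, female-destined
#'   offspring, `(unhatched + dead_juv) / (eggs - sons)`. Undefined for
#'   all-male broods (`eggs == sons`); such records are excluded from the
#'   inviability model with a warning rather than imputed.
#' * `total` — total isolation, `1 - daughters / eggs`, which under the
#'   accounting identity equals
#'   `prezygotic + (1 - prezygotic) * inviability` exactly.
#'
#' For backcrosses (and, following the study design, intra-population
#' controls):
#'
#' * `sterility` — dead offspring per egg laid by the hybrid dam,
#'   `(unhatched + dead_juv) / eggs`. This slightly overestimates true
#'   sterility because of background mortality (typically < 5% in
#'   controls); set `correct_background` to subtract a background rate —
#'   an extension beyond the published analysis, off by default.
#'
#' Each observation carries the genetic distance `gd` between the two
#' populations crossed — for backcrosses, between the hybrid dam's two
#' parental populations (controls have `gd = 0`) — and a `female` label
#' (the female population for parental crosses, the dam code for
#' backcrosses) used as the grouping factor in the models.
#'
#' @param crosses A validated cross table (see [cross_schema]), normally
#'   aggregated to one row per combination.
#' @param distances Symmetric labelled distance matrix covering every
#'   population label in `crosses` (default: the published COI matrix).
#' @param barriers Subset of
#'   `c("prezygotic", "inviability", "total", "sterility")`.
#' @param sterility_controls Include intra-population control crosses in
#'   the sterility observations (default `TRUE`, as in the published
#'   analysis).
#' @param correct_background Background mortality rate subtracted from the
#'   sterility proportion (numerator shrunk by `round(background * eggs)`).
#'   `0` (default) reproduces the published, uncorrected measure.
#' @return A tibble with one row per (combination, barrier): `barrier`,
#'   `female`, `female_pop`, `male_pop`, `gd`, `k`, `n`, `proportion`.
#' @examples
#' crosses <- simulate_study(sim_config(seed = 1))
#' barrier_observations(crosses)
#' @export
barrier_observations <- function(crosses,
                                 distances = avien_distances(),
                                 barriers = c("prezygotic", "inviability",
                                              "total", "sterility"),
                                 sterility_controls = TRUE,
                                 correct_background = 0) {
  crosses <- validate_crosses(crosses)
  check_distance_matrix(distances)
  barriers <- arg_match(barriers, multiple = TRUE)
  labels <- rownames(distances)

  parental <- filter(crosses, .data$cross_class != "backcross")
  backcross <- filter(crosses, .data$cross_class == "backcross")
  unknown <- setdiff(unique(c(parental$female_pop, parental$male_pop)), labels)
  if (length(unknown) > 0) {
    abort(paste0("population label(s) not in the distance matrix: ",
                 paste(unknown, collapse = ", ")))
  }

  out <- list()
  if (any(barriers != "sterility") && nrow(parental) > 0) {
    gd <- distances[cbind(parental$female_pop, parental$male_pop)]
    base <- tibble(
      female = parental$female_pop,
      female_pop = parental$female_pop,
      male_pop = parental$male_pop,
      gd = gd
    )
    if ("prezygotic" %in% barriers) {
      out$prezygotic <- mutate(base, barrier = "prezygotic",
                               k = parental$sons, n = parental$eggs)
    }
    if ("inviability" %in% barriers) {
      inv <- mutate(base, barrier = "inviability",
                    k = parental$unhatched + parental$dead_juv,
                    n = parental$eggs - parental$sons)
      undef <- inv$n == 0
      if (any(undef)) {
        warn(sprintf(
          "%d all-male brood(s) excluded from the inviability index (0/0): %s",
          sum(undef),
          paste(inv$female_pop[undef], inv$male_pop[undef], sep = "x",
                collapse = ", ")))
        inv <- inv[!undef, ]
      }
      out$inviability <- inv
    }
    if ("total" %in% barriers) {
      out$total <- mutate(base, barrier = "total",
                          k = parental$eggs - parental$daughters,
                          n = parental$eggs)
    }
  }
  if ("sterility" %in% barriers) {
    ster <- backcross
    if (sterility_controls) {
      ster <- bind_rows(ster, filter(parental, .data$cross_class == "control"))
    }
    if (nrow(ster) > 0) {
      is_bc <- ster$cross_class == "backcross"
      gd <- numeric(nrow(ster))
      if (any(is_bc)) {
        parents <- parse_dam_code(ster$dam_code[is_bc], labels)
        gd[is_bc] <- distances[cbind(parents$mother, parents$father)]
      }
      k <- ster$unhatched + ster$dead_juv
      if (correct_background > 0) {
        k <- pmax(0L, k - as.integer(round(correct_background * ster$eggs)))
      }
      out$sterility <- tibble(
        female = ifelse(is_bc, ster$dam_code, ster$female_pop),
        female_pop = ster$female_pop,
        male_pop = ster$male_pop,
        gd = gd, barrier = "sterility", k = k, n = ster$eggs
      )
    }
  }

  bind_rows(out) %>%
    mutate(proportion = .data$k / .data$n) %>%
    select("barrier", "female", "female_pop", "male_pop",
           "gd", "k", "n", "proportion") %>%
    arrange(factor(.data$barrier, levels = barriers))
}
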