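#' Genetic distance at which a barrier reaches a stated completeness
#'
#' Inverts a distance-only logit model analytically:
#' `gd_star = (logit(p) - b0) / b1`. Defined only for a positive distance
#' slope (`b1 > 0`); a non-positive slope means the barrier does not
#' increase with distance and no finite completeness threshold exists.
#'
#' When the threshold exceeds `gd_max` (the largest observed distance, if
#' supplied or recoverable from a fit) the estimate is an extrapolation
#' beyond the data and is flagged as such in the `extrapolated` column —
#' the published thresholds themselves extrapolate this way.
#'
#' @param fit A `barrier_glm` with exactly the intercept and `gd` terms,
#'   or a numeric intercept `b0` (then `slope` must be given).
#' @param p Completeness level(s) in (0, 1), e.g. `c(0.99, 0.999)`.
#' @param slope Distance slope `b1` when `fit` is a numeric intercept.
#' @param gd_max Largest observed genetic distance, for the extrapolation
#'   flag; taken from the fit's data when available.
#' @return A tibble: `p`, `gd_star`, `extrapolated`.
#' @examples
#' invert_threshold(-1.337, c(0.99, 0.999), slope = 39.450)
#' @export
invert_threshold <- function(fit, p = c(0.99, 0.999), slope = NULL,
                             gd_max = NULL) {
  if (inherits(fit, "barrier_glm")) {
    if (!identical(fit$terms, "gd")) {
      abort("threshold inversion needs a distance-only fit (terms = 'gd')")
    }
    b0 <- unname(fit$beta[1])
    b1 <- unname(fit$beta["gd"])
    if (is.null(gd_max) && !is.null(fit$data$gd)) gd_max <- max(fit$data$gd)
  } else {
    stopifnot(is.numeric(fit), length(fit) == 1)
    if (is.null(slope)) abort("supply 'slope' with a numeric intercept")
    b0 <- fit
    b1 <- slope
  }
  if (any(p <= 0 | p >= 1)) abort("completeness levels must lie in (0, 1)")
  if (!is.finite(b1) || b1 <= 0) {
    abort("barrier does not increase with distance; no finite completeness threshold")
  }
  gd_star <- (qlogis(p) - b0) / b1
  tibble(
    p = p,
    gd_star = gd_star,
    extrapolated = if (is.null(gd_max)) NA else gd_star > gd_max
  )
}

#' Completeness-threshold table across barriers
#'
#' Given one distance-only fit (or published coefficient pair) per
#' barrier, tabulates the genetic distance at which each barrier reaches
#' each completeness level, alongside the coefficient estimates. With the
#' published coefficients this reproduces the reported threshold table;
#' with `barrier_glm` fits it reports the refitted one.
#'
#' @param fits Either a named list of distance-only `barrier_glm` fits
#'   (names are barrier labels) or a tibble of coefficients with columns
#'   `barrier`, `intercept`, `slope` (e.g. [avien_barrier_coefs()]).
#' @param levels Completeness levels (default 99.0% and 99.9%).
#' @param digits Rounding applied to the reported thresholds (3, the
#'   conventional reporting precision; `NULL` for full precision).
#' @return A tibble: `barrier`, `intercept`, `slope`, then one `gd_star`
#'   column per level, plus the unrounded values in
#'   `attr(, "full_precision")`.
#' @examples
#' threshold_table(avien_barrier_coefs())
#' @export
threshold_table <- function(fits, levels = c(0.99, 0.999), digits = 3) {
  if (inherits(fits, "data.frame")) {
    stopifnot(all(c("barrier", "intercept", "slope") %in% names(fits)))
    coefs <- as_tibble(fits)[c("barrier", "intercept", "slope")]
    gd_max <- rep(list(NULL), nrow(coefs))
  } else {
    stopifnot(is.list(fits), !is.null(names(fits)))
    coefs <- tibble(
      barrier = names(fits),
      intercept = vapply(fits, function(f) unname(f$beta[1]), numeric(1)),
      slope = vapply(fits, function(f) unname(f$beta["gd"]), numeric(1))
    )
    gd_max <- lapply(fits, function(f) max(f$data$gd))
  }
  rows <- purrr::pmap(
    list(coefs$barrier, coefs$intercept, coefs$slope, gd_max),
    function(barrier, b0, b1, gmax) {
      th <- invert_threshold(b0, levels, slope = b1, gd_max = gmax)
      wide <- setNames(as.list(th$gd_star),
                       sprintf("gd_star_%g", 100 * levels))
      as_tibble(c(list(barrier = barrier, intercept = b0, slope = b1), wide))
    })
  out <- bind_rows(rows)
  full <- out
  if (!is.null(digits)) {
    gd_cols <- grep("^gd_star_", names(out), value = TRUE)
    out <- mutate(out, across(all_of(gd_cols), ~ round(.x, digits)))
  }
  attr(out, "full_precision") <- full
  out
}
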