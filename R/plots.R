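#' Plot barrier observations against genetic distance
#'
#' One panel per barrier: the observed proportion for each cross
#' combination (point area proportional to the denominator) against
#' genetic distance, optionally overlaid with the distance-only logistic
#' fit for each barrier.
#'
#' @param observations Barrier observations from [barrier_observations()].
#' @param fits Optional named list of distance-only `barrier_glm` fits
#'   (names matching barrier labels), e.g. from [run_pipeline()].
#' @return A ggplot object.
#' @export
plot_barriers <- function(observations, fits = NULL) {
  p <- ggplot2::ggplot(observations,
                       ggplot2::aes(x = .data$gd, y = .data$proportion)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n), alpha = 0.6) +
    ggplot2::scale_size_area(max_size = 4) +
    ggplot2::facet_wrap(~barrier) +
    ggplot2::labs(x = "K2P genetic distance (substitutions/site)",
                  y = "barrier strength (proportion)", size = "trials") +
    ggplot2::theme_minimal()
  if (!is.null(fits)) {
    grid <- bind_rows(purrr::imap(fits, function(f, bar) {
      gd <- seq(0, max(f$data$gd), length.out = 101)
      tibble(barrier = bar, gd = gd,
             proportion = plogis(f$beta[1] + f$beta["gd"] * gd))
    }))
    p <- p + ggplot2::geom_line(data = grid, linewidth = 0.8,
                                colour = "black")
  }
  p
}

#' @describeIn fit_barrier_glm Plot a fitted barrier model: observed
#'   proportions against distance with the fitted logistic curve
#'   (distance-only fits draw a single curve; factor models one curve per
#'   female group).
#' @param object A `barrier_glm` fit.
#' @param ... Unused.
#' @export
autoplot.barrier_glm <- function(object, ...) {
  d <- object$data
  gd <- seq(min(d$gd), max(d$gd), length.out = 101)
  if (is.null(object$xlevels)) {
    grid <- tibble(gd = gd)
    mapping <- ggplot2::aes(x = .data$gd, y = .data$proportion)
  } else {
    grid <- tidyr::expand_grid(gd = gd, female = object$xlevels)
    mapping <- ggplot2::aes(x = .data$gd, y = .data$proportion,
                            colour = .data$female)
  }
  grid$proportion <- predict(object, grid)
  ggplot2::ggplot(mutate(d, proportion = .data$k / .data$n), mapping) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n), alpha = 0.6) +
    ggplot2::scale_size_area(max_size = 4) +
    ggplot2::geom_line(data = grid) +
    ggplot2::labs(x = "K2P genetic distance (substitutions/site)",
                  y = "barrier strength (proportion)", size = "trials") +
    ggplot2::theme_minimal()
}
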