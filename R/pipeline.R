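#' Run the full barrier-vs-distance analysis pipeline
#'
#' End-to-end orchestration: resolve the genetic-distance source, validate
#' and aggregate the cross table, compute the four barrier indices, run
#' the interaction-guided model simplification per barrier, refit
#' distance-only models, and invert them to completeness thresholds. All
#' artifacts are written under `outdir`:
#'
#' * `distances.csv`, `distances.phy` — the distance matrix used;
#' * `indices.csv` — tidy barrier observations;
#' * `models.json`, `models.txt` — per-barrier simplification route,
#'   sequential quasi-F tests and distance-only coefficient tables (full
#'   precision in JSON, 3 decimals in the text report);
#' * `thresholds.tsv`, `thresholds.json` — the completeness-threshold
#'   table.
#'
#' Every model decision (interaction kept or dropped, excluded
#' observations, extrapolation flags) is logged to stderr unless `quiet`.
#'
#' @param crosses Cross table: tibble or CSV path ([read_cross_table()]).
#' @param distances Distance source — exactly one of: a labelled matrix or
#'   square-CSV path, `fasta` (aligned FASTA path, distances computed with
#'   [k2p_matrix()]), or neither (the published COI matrix).
#' @param fasta Optional aligned FASTA path.
#' @param outdir Output directory, created if needed.
#' @param levels Completeness levels for the threshold table.
#' @param alpha Significance level for the simplification decision.
#' @param seed Optional integer seed (only the fitting is deterministic
#'   anyway; the seed is recorded for provenance).
#' @param quiet Suppress progress logging.
#' @return Invisibly, a list with `distances`, `crosses`, `indices`,
#'   `analyses`, `fits`, `thresholds` and the written `paths`.
#' @export
run_pipeline <- function(crosses, distances = NULL, fasta = NULL,
                         outdir = "isomite-out", levels = c(0.99, 0.999),
                         alpha = 0.05, seed = NULL, quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("[stage %s] %s", name, conditionMessage(e)))
    })
  }
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(distances) && !is.null(fasta)) {
    abort("supply exactly one distance source (matrix/CSV, FASTA, or neither)")
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  d <- stage("distances", {
    if (!is.null(fasta)) {
      say("computing K2P distances from %s", fasta)
      k2p_matrix(fasta)
    } else if (is.null(distances)) {
      say("using the published COI distance matrix")
      avien_distances()
    } else if (is.matrix(distances)) {
      check_distance_matrix(distances)
    } else {
      say("reading distance matrix from %s", distances)
      read_distance_matrix(distances)
    }
  })
  paths <- list(
    distances_csv = file.path(outdir, "distances.csv"),
    distances_phy = file.path(outdir, "distances.phy"),
    indices = file.path(outdir, "indices.csv"),
    models_json = file.path(outdir, "models.json"),
    models_txt = file.path(outdir, "models.txt"),
    thresholds_tsv = file.path(outdir, "thresholds.tsv"),
    thresholds_json = file.path(outdir, "thresholds.json")
  )
  write_distance_matrix(d, paths$distances_csv, "csv")
  write_distance_matrix(d, paths$distances_phy, "phylip")

  crosses <- stage("crosses", {
    if (is.character(crosses)) {
      say("reading cross table from %s", crosses)
      read_cross_table(crosses)
    } else {
      aggregate_crosses(crosses)
    }
  })
  say("%d cross combinations (%d parental, %d backcross)",
      nrow(crosses), sum(crosses$cross_class != "backcross"),
      sum(crosses$cross_class == "backcross"))

  indices <- stage("indices", barrier_observations(crosses, d))
  readr::write_csv(indices, paths$indices, progress = FALSE)

  barriers <- unique(indices$barrier)
  analyses <- list()
  fits <- list()
  for (bar in barriers) {
    obs <- filter(indices, .data$barrier == bar)
    analyses[[bar]] <- stage(paste0("model/", bar), {
      # the sterility model regresses on distance only: each hybrid-dam
      # type contributes a single observation, so a dam factor (and the
      # interaction decision rule) is not estimable for this barrier
      a <- if (bar == "sterility") {
        simplify_barrier_model(select(obs, -"female"), alpha = alpha)
      } else {
        simplify_barrier_model(obs, alpha = alpha)
      }
      say("%s: %s route%s", bar, a$route,
          if (is.null(a$interaction_test)) "" else
            sprintf(" (interaction p = %.4g)", a$interaction_test$p_value))
      a
    })
    fits[[bar]] <- stage(paste0("gd_only/", bar), gd_only_fit(obs))
  }

  thresholds <- stage("thresholds", threshold_table(fits, levels = levels))
  if (!quiet) {
    full <- attr(thresholds, "full_precision")
    gd_cols <- grep("^gd_star_", names(full), value = TRUE)
    for (i in seq_len(nrow(full))) {
      over <- vapply(gd_cols, function(cc) {
        full[[cc]][i] > max(fits[[full$barrier[i]]]$data$gd)
      }, logical(1))
      if (any(over)) {
        say("%s: threshold(s) %s extrapolate beyond the observed distance range",
            full$barrier[i], paste(gd_cols[over], collapse = ", "))
      }
    }
  }

  report <- purrr::map(barriers, function(bar) {
    a <- analyses[[bar]]
    list(
      barrier = bar,
      route = a$route,
      interaction = if (is.null(a$interaction_test)) NULL else
        as.list(a$interaction_test),
      tests = a$tests,
      gd_only = list(coefficients = tidy(fits[[bar]]),
                     dispersion = fits[[bar]]$dispersion,
                     df_residual = fits[[bar]]$df_residual)
    )
  })
  report <- purrr::map(report, function(x) x[!vapply(x, is.null, TRUE)])
  jsonlite::write_json(
    list(alpha = alpha, seed = seed, models = report,
         thresholds = attr(thresholds, "full_precision")),
    paths$models_json, auto_unbox = TRUE, digits = NA, null = "null")

  txt <- c("Barrier models and completeness thresholds", "")
  for (bar in barriers) {
    txt <- c(txt, sprintf("== %s ==", bar),
             utils::capture.output(print(analyses[[bar]])),
             utils::capture.output(print(fits[[bar]])), "")
  }
  txt <- c(txt, "== thresholds ==",
           utils::capture.output(print(as.data.frame(thresholds))))
  writeLines(txt, paths$models_txt)

  readr::write_tsv(thresholds, paths$thresholds_tsv, progress = FALSE)
  jsonlite::write_json(attr(thresholds, "full_precision"),
                       paths$thresholds_json, auto_unbox = TRUE, digits = NA)
  say("wrote %d artifacts to %s", length(paths), outdir)
  invisible(list(distances = d, crosses = crosses, indices = indices,
                 analyses = analyses, fits = fits, thresholds = thresholds,
                 paths = paths))
}
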