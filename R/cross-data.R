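#' Column schema for cross-experiment count tables
#'
#' One row describes one cross combination (or one replicate pair of it):
#' a female from `female_pop` mated to a male from `male_pop`, with the
#' offspring of `n_pairs` replicate pairs counted over the oviposition
#' window. Because the mites are arrhenotokous, sons develop from
#' unfertilized eggs and daughters from fertilized eggs, so the egg total
#' decomposes exactly as
#' `eggs = sons + daughters + unhatched + dead_juv`.
#'
#' `cross_class` is one of `"control"` (intra-population,
#' `female_pop == male_pop`), `"interpopulation"`, or `"backcross"` (an F1
#' hybrid female crossed to a parental-population male). For backcrosses
#' `dam_code` gives the hybrid dam's parentage, mother's population label
#' first, e.g. `"TF"` for a dam from a Turkey female x France male cross;
#' it must be empty otherwise.
#'
#' @name cross_schema
#' @keywords internal
NULL

cross_cols <- c("female_pop", "male_pop", "cross_class", "dam_code",
                "n_pairs", "eggs", "sons", "daughters", "unhatched", "dead_juv")
count_cols <- c("n_pairs", "eggs", "sons", "daughters", "unhatched", "dead_juv")
cross_classes <- c("control", "interpopulation", "backcross")

#' Validate a cross-experiment count table
#'
#' Checks the accounting identity `eggs = sons + daughters + unhatched +
#' dead_juv` on every row, non-negativity of all counts, the
#' control/interpopulation labelling rule, and the backcross/dam-code
#' correspondence. Errors name the offending row.
#'
#' @param crosses A data frame with the columns described in
#'   [cross_schema].
#' @return The validated table as a tibble, invisibly unchanged.
#' @export
validate_crosses <- function(crosses) {
  crosses <- as_tibble(crosses)
  missing <- setdiff(cross_cols, names(crosses))
  if (length(missing) > 0) {
    abort(paste0("missing column(s): ", paste(missing, collapse = ", ")))
  }
  crosses$dam_code <- dplyr::coalesce(as.character(crosses$dam_code), "")
  for (col in count_cols) {
    bad <- which(is.na(crosses[[col]]) | crosses[[col]] < 0)
    if (length(bad) > 0) {
      abort(sprintf("negative or missing count in column '%s' at row %d",
                    col, bad[1]))
    }
  }
  bad <- which(!crosses$cross_class %in% cross_classes)
  if (length(bad) > 0) {
    abort(sprintf("unknown cross_class '%s' at row %d",
                  crosses$cross_class[bad[1]], bad[1]))
  }
  tot <- crosses$sons + crosses$daughters + crosses$unhatched + crosses$dead_juv
  bad <- which(crosses$eggs != tot)
  if (length(bad) > 0) {
    abort(sprintf(
      paste0("accounting identity violated at row %d: eggs = %d but ",
             "sons + daughters + unhatched + dead_juv = %d"),
      bad[1], crosses$eggs[bad[1]], tot[bad[1]]))
  }
  bad <- which(crosses$eggs < 1)
  if (length(bad) > 0) {
    abort(sprintf("row %d has zero eggs; records entering analysis need eggs >= 1",
                  bad[1]))
  }
  nb <- crosses$cross_class != "backcross"
  bad <- which(nb & ((crosses$cross_class == "control") !=
                       (crosses$female_pop == crosses$male_pop)))
  if (length(bad) > 0) {
    abort(sprintf(
      "row %d: cross_class 'control' requires female_pop == male_pop (and vice versa)",
      bad[1]))
  }
  bad <- which((crosses$dam_code != "") != (crosses$cross_class == "backcross"))
  if (length(bad) > 0) {
    abort(sprintf("row %d: dam_code must be set exactly for backcross rows",
                  bad[1]))
  }
  crosses
}

#' Read a cross-experiment count table from CSV
#'
#' Comma-delimited UTF-8 with a header naming the columns of
#' [cross_schema]. Population labels are free strings, matched
#' case-sensitively against distance-matrix labels downstream. Replicate
#' rows sharing the same cross combination are kept as-is; use
#' [aggregate_crosses()] (the default analysis unit) to pool them.
#'
#' @param path Path to a CSV file.
#' @param aggregate If `TRUE` (default), pool replicate rows per
#'   combination by summation before returning.
#' @return A validated tibble of cross records.
#' @export
read_cross_table <- function(path, aggregate = TRUE) {
  crosses <- readr::read_csv(
    path,
    col_types = readr::cols(
      female_pop = readr::col_character(),
      male_pop = readr::col_character(),
      cross_class = readr::col_character(),
      dam_code = readr::col_character(),
      .default = readr::col_integer()
    ),
    progress = FALSE
  )
  crosses <- validate_crosses(crosses)
  if (aggregate) aggregate_crosses(crosses) else crosses
}

#' Write a cross-experiment count table to CSV
#'
#' @param crosses A validated cross table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cross_table <- function(crosses, path) {
  crosses <- validate_crosses(crosses)
  readr::write_csv(crosses[cross_cols], path, progress = FALSE)
  invisible(path)
}

#' Pool replicate rows into one record per cross combination
#'
#' The analysis unit throughout is the cross combination: counts are summed
#' over replicate pairs sharing `(female_pop, male_pop, cross_class,
#' dam_code)`. The residual degrees of freedom of the fitted models (49
#' parental combinations for the parental-cross barriers) presuppose this
#' unit.
#'
#' @param crosses A validated cross table, possibly with several rows per
#'   combination.
#' @return A tibble with one row per combination.
#' @export
aggregate_crosses <- function(crosses) {
  crosses <- validate_crosses(crosses)
  crosses %>%
    group_by(.data$female_pop, .data$male_pop, .data$cross_class,
             .data$dam_code) %>%
    summarise(across(all_of(count_cols), sum), .groups = "drop") %>%
    select(all_of(cross_cols))
}

#' Write a labelled distance matrix
#'
#' `format = "csv"` writes a square matrix with a header row and a label
#' column; `format = "phylip"` writes the relaxed PHYLIP distance format
#' (taxon count on the first line, then `label d1 d2 ...`).
#'
#' @param d Symmetric numeric matrix with population labels as dimnames.
#' @param path Output path.
#' @param format `"csv"` or `"phylip"`.
#' @param digits Decimal places written (3 matches the conventional
#'   reporting precision; full precision is retained in memory).
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(d, path, format = c("csv", "phylip"),
                                  digits = 3) {
  format <- arg_match(format)
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  labels <- rownames(d)
  if (format == "csv") {
    out <- as_tibble(round(d, digits))
    out <- dplyr::bind_cols(tibble(population = labels), out)
    readr::write_csv(out, path, progress = FALSE)
  } else {
    lines <- c(
      sprintf("%d", nrow(d)),
      vapply(seq_len(nrow(d)), function(i) {
        paste(c(labels[i], sprintf(paste0("%.", digits, "f"), d[i, ])),
              collapse = " ")
      }, character(1))
    )
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read a square labelled distance matrix from CSV
#'
#' Inverse of [write_distance_matrix()] with `format = "csv"`.
#'
#' @param path Path to a square distance CSV with a `population` column.
#' @return A symmetric numeric matrix with labels as dimnames.
#' @export
read_distance_matrix <- function(path) {
  tbl <- readr::read_csv(path, col_types = readr::cols(
    population = readr::col_character(), .default = readr::col_double()),
    progress = FALSE)
  labels <- tbl$population
  d <- as.matrix(tbl[setdiff(names(tbl), "population")])
  dimnames(d) <- list(labels, labels)
  check_distance_matrix(d)
  d
}

check_distance_matrix <- function(d) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (is.null(rownames(d))) abort("distance matrix needs population labels")
  if (any(!is.finite(d)) || any(d < 0)) {
    abort("distance matrix entries must be finite and non-negative")
  }
  if (any(abs(d - t(d)) > 1e-12)) abort("distance matrix must be symmetric")
  if (any(diag(d) != 0)) abort("distance matrix diagonal must be zero")
  invisible(d)
}
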