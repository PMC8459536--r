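#' Published COI K2P distances among the seven study populations
#'
#' Kimura 2-parameter distances in the mitochondrial COI gene among the
#' seven Palaearctic populations of the hawthorn spider mite used in the
#' crossing experiments: France (F), Turkey (T), Iran (I), Inner Mongolia
#' (CIM), Eastern China (CN), Korea (K) and Japan (J), as reported in the
#' study that generated the crossing data. Distances range from 0 (the
#' CIM/CN/K triplet shares a haplotype) to 0.075 (Japan vs Iran).
#'
#' @return A symmetric 7x7 numeric matrix (substitutions/site) with zero
#'   diagonal and population labels as dimnames.
#' @examples
#' avien_distances()["F", "T"]
#' @export
avien_distances <- function() {
  labels <- c("F", "T", "I", "CIM", "CN", "K", "J")
  lower <- list(
    T   = c(F = 0.018),
    I   = c(F = 0.061, T = 0.057),
    CIM = c(F = 0.050, T = 0.057, I = 0.063),
    CN  = c(F = 0.050, T = 0.057, I = 0.063, CIM = 0.000),
    K   = c(F = 0.050, T = 0.057, I = 0.063, CIM = 0.000, CN = 0.000),
    J   = c(F = 0.059, T = 0.063, I = 0.075, CIM = 0.068, CN = 0.068, K = 0.068)
  )
  d <- matrix(0, 7, 7, dimnames = list(labels, labels))
  for (row in names(lower)) {
    d[row, names(lower[[row]])] <- lower[[row]]
    d[names(lower[[row]]), row] <- lower[[row]]
  }
  check_distance_matrix(d)
}

#' Published distance-only logit coefficients for the four barriers
#'
#' Intercept and genetic-distance slope of the quasibinomial logistic
#' models (logit scale) fitted to the full rearing data of the
#' seven-population crossing experiment, one model per reproductive
#' barrier: lack of fertilization (`prezygotic`), hybrid female
#' inviability (`inviability`), total isolation in parental crosses
#' (`total`), and hybrid female sterility scored in backcrosses
#' (`sterility`). These are the reference values used to reproduce the
#' published completeness thresholds via [invert_threshold()]; refitting
#' the models needs the raw per-cross counts, which [simulate_study()]
#' emulates.
#'
#' @return A tibble with columns `barrier`, `intercept`, `slope`,
#'   `intercept_se`, `slope_se`.
#' @examples
#' threshold_table(avien_barrier_coefs())
#' @export
avien_barrier_coefs <- function() {
  tibble(
    barrier      = c("prezygotic", "inviability", "total", "sterility"),
    intercept    = c(-1.453, -1.337, -0.594, -1.308),
    slope        = c(12.728, 39.450, 35.768, 54.552),
    intercept_se = c(0.255, 0.426, 0.346, 0.203),
    slope_se     = c(4.716, 8.580, 7.490, 5.819)
  )
}

#' The sixteen hybrid-dam types used in the backcross experiments
#'
#' Dam codes follow the mother-first convention (`"TF"` = dam from a
#' Turkey female x France male cross). Only these 16 F1 crosses yielded
#' enough hybrid females to backcross.
#'
#' @return A character vector of 16 dam codes.
#' @keywords internal
avien_backcross_dams <- function() {
  c("FT", "FI", "FJ", "TF", "TI", "IF", "IT",
    "CIMCN", "CIMK", "CNCIM", "CNK", "KCIM", "KCN",
    "JF", "JCIM", "JCN")
}

#' Split a hybrid-dam code into its parental population labels
#'
#' Codes concatenate the maternal then paternal population label
#' (mother first). Parsing is unambiguous against a supplied label set by
#' longest-prefix match.
#'
#' @param dam_code Character vector of dam codes.
#' @param labels Population labels to match against (default: the seven
#'   study populations).
#' @return A tibble with columns `dam_code`, `mother`, `father`.
#' @export
parse_dam_code <- function(dam_code, labels = rownames(avien_distances())) {
  labels <- labels[order(nchar(labels), decreasing = TRUE)]
  parse1 <- function(code) {
    for (m in labels) {
      if (startsWith(code, m)) {
        f <- substring(code, nchar(m) + 1L)
        if (f %in% labels) return(c(m, f))
      }
    }
    abort(sprintf("cannot parse dam code '%s' against labels %s",
                  code, paste(sort(labels), collapse = ", ")))
  }
  parts <- vapply(dam_code, parse1, character(2))
  tibble(dam_code = dam_code,
         mother = unname(parts[1, ]), father = unname(parts[2, ]))
}
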