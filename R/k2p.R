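#' Transition/transversion site partition of an aligned sequence pair
#'
#' Compares two equal-length aligned nucleotide strings site by site under
#' pairwise deletion: any site where either residue is a gap (`-`) or not
#' one of `A`, `C`, `G`, `T` (so `N` and all IUPAC ambiguity codes) is
#' excluded from the comparison. Among the usable sites, differences are
#' classified as transitions (A<->G, C<->T) or transversions (all other
#' mismatches), and returned as per-usable-site proportions.
#'
#' @param seq_a,seq_b Aligned nucleotide strings of equal length
#'   (case-insensitive).
#' @return A list with `usable_sites`, `P` (transition proportion) and
#'   `Q` (transversion proportion).
#' @examples
#' k2p_site_partition("AAAAAAAAAA", "GAAAAAAAAT")
#' @export
k2p_site_partition <- function(seq_a, seq_b) {
  a <- toupper(unlist(strsplit(seq_a, "", fixed = TRUE)))
  b <- toupper(unlist(strsplit(seq_b, "", fixed = TRUE)))
  if (length(a) != length(b)) {
    abort("aligned sequences must have equal length")
  }
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  a <- a[ok]; b <- b[ok]
  usable <- length(a)
  if (usable == 0) abort("no comparable sites (all gapped or ambiguous)")
  diff <- a != b
  purine <- function(x) x %in% c("A", "G")
  ts <- diff & (purine(a) == purine(b))
  list(usable_sites = usable,
       P = sum(ts) / usable,
       Q = sum(diff & !ts) / usable)
}

#' Kimura two-parameter distance from a site partition
#'
#' The K2P distance corrects the observed transition proportion `P` and
#' transversion proportion `Q` separately for multiple hits:
#' `d = -1/2 * log((1 - 2P - Q) * sqrt(1 - 2Q))`. The correction breaks
#' down (saturation) when `1 - 2P - Q <= 0` or `1 - 2Q <= 0`.
#'
#' @param P Transition-differing site proportion, or a partition list from
#'   [k2p_site_partition()] (in which case `Q` is ignored).
#' @param Q Transversion-differing site proportion.
#' @param pair Optional label used in the saturation error message.
#' @return The distance in substitutions/site (`>= 0`; `0` iff
#'   `P == Q == 0`).
#' @examples
#' k2p_distance(0.10, 0.05)
#' @export
k2p_distance <- function(P, Q = NULL, pair = NULL) {
  if (is.list(P)) {
    Q <- P$Q
    P <- P$P
  }
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) {
    abort(sprintf(
      "saturated divergence%s: P = %.4g, Q = %.4g put the K2P correction out of domain",
      if (is.null(pair)) "" else paste0(" for pair ", pair), P, Q))
  }
  -0.5 * log(w1 * sqrt(w2))
}

#' Pairwise K2P distance matrix from an alignment
#'
#' One representative (aligned) sequence per population; every pair is
#' compared with [k2p_site_partition()] and [k2p_distance()] under
#' pairwise deletion. Saturation or zero-usable-site errors name the
#' offending pair.
#'
#' @param aln Named character vector of equal-length aligned sequences, a
#'   `Biostrings::DNAStringSet`, or a path to a FASTA file (read with
#'   `Biostrings::readDNAStringSet()`).
#' @param pop_map Optional named character vector mapping sequence names
#'   to population labels (e.g. accession -> population).
#' @return A symmetric labelled distance matrix with zero diagonal.
#' @examples
#' k2p_matrix(c(x = "ACGTACGT", y = "ACGTACGA", z = "ACGTACGT"))
#' @export
k2p_matrix <- function(aln, pop_map = NULL) {
  if (is.character(aln) && length(aln) == 1 && file.exists(aln)) {
    if (!requireNamespace("Biostrings", quietly = TRUE)) {
      abort("reading FASTA needs the Biostrings package")
    }
    aln <- Biostrings::readDNAStringSet(aln)
  }
  if (inherits(aln, "XStringSet")) {
    aln <- setNames(as.character(aln), names(aln))
  }
  if (length(aln) < 2) abort("need at least two sequences")
  if (is.null(names(aln)) || anyDuplicated(names(aln))) {
    abort("sequences need unique names")
  }
  if (length(unique(nchar(aln))) != 1) {
    abort("sequences are not aligned: unequal lengths")
  }
  if (!is.null(pop_map)) names(aln) <- unname(pop_map[names(aln)])
  labels <- names(aln)
  m <- length(aln)
  d <- matrix(0, m, m, dimnames = list(labels, labels))
  for (i in seq_len(m - 1)) {
    for (j in seq(i + 1, m)) {
      part <- k2p_site_partition(aln[[i]], aln[[j]])
      d[i, j] <- d[j, i] <- k2p_distance(
        part, pair = paste(labels[i], labels[j], sep = "/"))
    }
  }
  d
}
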