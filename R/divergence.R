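# Pairwise divergence: Nei-Gojobori (1986) synonymous/non-synonymous
# counting with Jukes-Cantor correction, amino-acid p-distances, and the
# clock-like (UPGMA) tree used for lineage ages.

#' Jukes-Cantor correction of a p-distance
#'
#' `d = -(3/4) * log(1 - (4/3) * p)`; defined for `p < 0.75`.
#'
#' @param p Proportion of differing sites.
#' @return Corrected distance; `NA` where `p >= 0.75` (saturated).
#' @export
jc_correct <- function(p) {
  out <- ifelse(p < 0.75, -0.75 * log(1 - 4 * p / 3), NA_real_)
  out[p == 0] <- 0
  out
}

#' Pairwise Ka/Ks by Nei-Gojobori counting with Jukes-Cantor correction
#'
#' Synonymous and non-synonymous sites are counted per codon (fraction of
#' non-stop single-nucleotide changes that are synonymous) and averaged
#' over the two sequences; differences at multi-hit codons are resolved by
#' equal-weight averaging over all minimal mutational pathways, excluding
#' pathways through stop codons. Codons containing gaps, `N`, or stops in
#' either sequence are skipped pairwise. Proportions are corrected for
#' multiple hits with [jc_correct()]; a proportion at or above 0.75 is
#' flagged saturated and the corresponding rate is `NA`.
#'
#' @param seq1,seq2 Aligned nucleotide sequences (character scalars of
#'   equal length divisible by 3), or a [codon_alignment()] row.
#' @return An object of class `pair_divergence`: list with `ka`, `ks`,
#'   `pn`, `ps`, site counts `N`, `S`, difference counts `Nd`, `Sd`,
#'   amino-acid p-distance `p_aa`, `n_aa_diffs`, `n_codons_compared`, and
#'   the `saturated` flag.
#' @examples
#' kaks_pair("TTTGGGCCCAAA", "TTCGGGCCCAAA")
#' @export
kaks_pair <- function(seq1, seq2) {
  s1 <- .as_codon_vector(seq1)
  s2 <- .as_codon_vector(seq2)
  if (length(s1) != length(s2))
    stop("sequences differ in length")
  ok <- vapply(seq_along(s1), function(j) {
    .codon_ok(s1[j]) && .codon_ok(s2[j])
  }, logical(1))
  if (!any(ok)) stop("no comparable codons between the two sequences")
  c1 <- s1[ok]; c2 <- s2[ok]
  S <- (sum(syn_sites(c1)) + sum(syn_sites(c2))) / 2
  N <- 3 * length(c1) - S
  Sd <- 0; Nd <- 0; n_aa <- 0L
  for (j in seq_along(c1)) {
    if (c1[j] == c2[j]) next
    d <- codon_diff_counts(c1[j], c2[j])
    Sd <- Sd + d[["syn"]]
    Nd <- Nd + d[["nonsyn"]]
    if (translate_codon(c1[j]) != translate_codon(c2[j])) n_aa <- n_aa + 1L
  }
  ps <- if (S > 0) Sd / S else 0
  pn <- if (N > 0) Nd / N else 0
  structure(list(
    ka = jc_correct(pn), ks = jc_correct(ps), pn = pn, ps = ps,
    N = N, S = S, Nd = Nd, Sd = Sd,
    p_aa = n_aa / length(c1), n_aa_diffs = n_aa,
    n_codons_compared = length(c1),
    saturated = ps >= 0.75 || pn >= 0.75), class = "pair_divergence")
}

#' @export
print.pair_divergence <- function(x, ...) {
  cat(sprintf("Ka = %s  Ks = %s  (N = %.2f, S = %.2f, Nd = %.2f, Sd = %.2f)\n",
              format(x$ka, digits = 4), format(x$ks, digits = 4),
              x$N, x$S, x$Nd, x$Sd))
  cat(sprintf("aa p-distance = %.4f (%d diffs over %d codons)%s\n",
              x$p_aa, x$n_aa_diffs, x$n_codons_compared,
              if (x$saturated) "  [saturated]" else ""))
  invisible(x)
}

.as_codon_vector <- function(x) {
  if (inherits(x, "codon_alignment")) stop("pass a single sequence row")
  if (length(x) == 1L && nchar(x) > 3L) {
    x <- toupper(x)
    if (nchar(x) %% 3L != 0L) stop("sequence length not divisible by 3")
    substring(x, seq(1L, nchar(x), 3L), seq(3L, nchar(x), 3L))
  } else as.character(x)
}

#' Pairwise Ka/Ks table for all sequence pairs of an alignment
#'
#' One row per unordered pair, in the schema of a per-pair divergence
#' supplement: `id1`, `id2`, `ka`, `ks`, `p_aa`, `n_aa_diffs`,
#' `n_codons_compared`, `saturated`.
#'
#' @param alignment A [codon_alignment()].
#' @return Data frame with `choose(n, 2)` rows.
#' @export
kaks_table <- function(alignment) {
  ids <- alignment$ids
  cm <- .codon_matrix(alignment)
  pairs <- utils::combn(length(ids), 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    d <- kaks_pair(cm[i, ], cm[j, ])
    data.frame(id1 = ids[i], id2 = ids[j], ka = d$ka, ks = d$ks,
               p_aa = d$p_aa, n_aa_diffs = d$n_aa_diffs,
               n_codons_compared = d$n_codons_compared,
               saturated = d$saturated, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Amino-acid p-distance matrix
#'
#' Sequences are translated with the standard genetic code; per pair, the
#' proportion of differing residues over pairwise-ungapped, unambiguous
#' columns. Columns with internal stop codons are skipped with a warning.
#'
#' @param alignment A [codon_alignment()].
#' @return Symmetric numeric matrix with zero diagonal, dimnames = ids.
#' @export
aa_distance_matrix <- function(alignment) {
  aa <- translate_alignment(alignment)
  if (any(aa == "*"))
    warning("internal stop codons found; those columns are skipped pairwise")
  aa[aa %in% c("-", "X", "*")] <- NA_character_
  n <- nrow(aa)
  D <- matrix(0, n, n, dimnames = list(alignment$ids, alignment$ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- !is.na(aa[i, ]) & !is.na(aa[j, ])
      nc <- sum(ok)
      D[i, j] <- D[j, i] <-
        if (nc == 0L) NA_real_ else sum(aa[i, ok] != aa[j, ok]) / nc
    }
  }
  D
}

#' Clock-like (linearized) tree from a distance matrix
#'
#' Average-linkage (UPGMA) ultrametric tree; node heights are half the
#' merge distance, so leaf-to-leaf path lengths reproduce ultrametric
#' input distances exactly. Rows are ordered lexicographically by
#' identifier before clustering so that ties are broken deterministically.
#'
#' @param matrix Symmetric distance matrix with dimnames.
#' @return An ultrametric [ape::phylo] tree.
#' @export
linearized_tree <- function(matrix) {
  if (nrow(matrix) < 2L) stop("need at least 2 leaves")
  ord <- order(rownames(matrix))
  m <- matrix[ord, ord, drop = FALSE]
  hc <- stats::hclust(stats::as.dist(m), method = "average")
  ape::as.phylo(hc)
}
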