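# Parsimony networks of closely related sequences and the independent
# replacement mutations they imply at positively selected sites, with
# conservative/non-conservative classification of amino-acid changes.

# Amino-acid groups defined on charge, volume and polarity; changes within
# a group are conservative.
.AA_GROUPS <- list(c("R", "H", "K"), c("D", "E"), c("N", "Q"), "C",
                   c("A", "G", "P", "S", "T"), c("I", "L", "M", "V"),
                   c("F", "W", "Y"))

.aa_group <- function(aa) {
  for (g in seq_along(.AA_GROUPS)) if (aa %in% .AA_GROUPS[[g]]) return(g)
  NA_integer_
}

#' Amino-acid groups used for conservative/non-conservative classification
#'
#' The partition of the 20 standard residues on charge, volume and
#' polarity: RHK, DE, NQ, C, AGPST, ILMV, FWY.
#'
#' @return List of character vectors.
#' @export
aa_groups <- function() .AA_GROUPS

#' Classify an amino-acid change as conservative or non-conservative
#'
#' A change is conservative when both residues belong to the same group of
#' [aa_groups()]. The classification is symmetric in its arguments.
#'
#' @param from_aa,to_aa Distinct standard one-letter residues.
#' @return `TRUE` for conservative, `FALSE` for non-conservative.
#' @examples
#' classify_change("K", "R")  # TRUE (both in RHK)
#' classify_change("D", "K")  # FALSE
#' @export
classify_change <- function(from_aa, to_aa) {
  g1 <- .aa_group(from_aa)
  g2 <- .aa_group(to_aa)
  if (is.na(g1) || is.na(g2))
    stop("nonstandard residue: ", from_aa, " or ", to_aa)
  if (from_aa == to_aa) stop("identical residues are not a change")
  g1 == g2
}

#' Build a parsimony network of closely related sequences
#'
#' Pairs differing at no more than `connection_limit` pairwise-ungapped
#' nucleotide positions are connected; within each connected component a
#' minimum spanning forest is built on the difference counts (Kruskal,
#' ties broken by lexicographic edge ids) so that every change is counted
#' once per component.
#'
#' @param alignment A [codon_alignment()].
#' @param connection_limit Maximum nucleotide differences for a connection
#'   (default 15).
#' @return An object of class `parsimony_network`: list with `nodes`,
#'   `edges` (all connections with `diffs`), `forest` (spanning edges) and
#'   `component` (per-node component index).
#' @export
build_network <- function(alignment, connection_limit = 15) {
  if (connection_limit < 1) stop("connection_limit must be >= 1")
  ids <- alignment$ids
  mat <- alignment$seqs
  nt <- mat %in% c("A", "C", "G", "T")
  dim(nt) <- dim(mat)
  n <- length(ids)
  edges <- list()
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- nt[i, ] & nt[j, ]
      d <- sum(mat[i, ok] != mat[j, ok])
      if (d <= connection_limit) {
        a <- sort(c(ids[i], ids[j]))
        edges[[length(edges) + 1L]] <-
          data.frame(id1 = a[1L], id2 = a[2L], diffs = d,
                     stringsAsFactors = FALSE)
      }
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(id1 = character(), id2 = character(), diffs = integer(),
               stringsAsFactors = FALSE)
  # Kruskal with deterministic tie-break on (weight, id1, id2)
  ord <- order(edges$diffs, edges$id1, edges$id2)
  parent <- stats::setNames(ids, ids)
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  forest_rows <- integer()
  for (k in ord) {
    r1 <- find(edges$id1[k]); r2 <- find(edges$id2[k])
    if (r1 != r2) {
      parent[[r2]] <- r1
      forest_rows <- c(forest_rows, k)
    }
  }
  roots <- vapply(ids, find, character(1))
  component <- match(roots, unique(roots))
  names(component) <- ids
  structure(list(nodes = ids,
                 edges = edges,
                 forest = edges[sort(forest_rows), , drop = FALSE],
                 component = component),
            class = "parsimony_network")
}

#' @export
print.parsimony_network <- function(x, ...) {
  cat("parsimony network: ", length(x$nodes), " sequences, ",
      nrow(x$edges), " connections, ", length(unique(x$component)),
      " components, ", nrow(x$forest), " spanning edges\n", sep = "")
  invisible(x)
}

#' Enumerate independent replacement mutations on a parsimony network
#'
#' Per spanning-forest edge and codon, amino-acid differences are recorded
#' as one replacement each; codons differing at several positions are
#' decomposed into single-nucleotide steps along a deterministic minimal
#' stop-avoiding pathway, and each amino-acid-changing step is one
#' replacement. Changes are flagged as falling at positively selected
#' sites and classified with [classify_change()]. The count of changes at
#' PSS is the "independent replacement mutations" statistic.
#'
#' @param network A `parsimony_network` over the alignment ids.
#' @param alignment The [codon_alignment()].
#' @param pss A `site_selection_profile` or integer vector of PSS codon
#'   indices.
#' @return Data frame: `id1`, `id2`, `codon`, `from_aa`, `to_aa`,
#'   `at_pss`, `conservative`.
#' @export
enumerate_replacements <- function(network, alignment, pss) {
  if (inherits(pss, "site_selection_profile")) pss <- attr(pss, "pss_set")
  if (!all(network$nodes %in% alignment$ids))
    stop("network nodes not found in alignment")
  cm <- .codon_matrix(alignment)
  rows <- list()
  forest <- network$forest
  for (k in seq_len(nrow(forest))) {
    i <- forest$id1[k]; j <- forest$id2[k]
    for (cd in seq_len(ncol(cm))) {
      a <- cm[i, cd]; b <- cm[j, cd]
      if (a == b) next
      if (!.codon_ok(a) || !.codon_ok(b)) next
      steps <- .codon_path_steps(a, b)
      if (is.null(steps)) next
      repl <- steps[!steps$syn, , drop = FALSE]
      if (nrow(repl) == 0L) next
      for (s in seq_len(nrow(repl))) {
        rows[[length(rows) + 1L]] <- data.frame(
          id1 = i, id2 = j, codon = cd,
          from_aa = repl$from_aa[s], to_aa = repl$to_aa[s],
          at_pss = cd %in% pss,
          conservative = classify_change(repl$from_aa[s], repl$to_aa[s]),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L)
    return(data.frame(id1 = character(), id2 = character(),
                      codon = integer(), from_aa = character(),
                      to_aa = character(), at_pss = logical(),
                      conservative = logical(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Summary of conservative changes at positively selected sites
#'
#' The fraction of conservative changes among replacement mutations at
#' positively selected sites, with a two-sided exact binomial test against
#' a baseline expectation (doubled smaller tail, capped at 1).
#'
#' @param changes Data frame from [enumerate_replacements()].
#' @param baseline Expected conservative fraction (default 0.35, the
#'   empirical proportion over a large protein survey).
#' @return List with `n_changes`, `n_conservative`, `fraction` and
#'   `p_value`.
#' @export
conservative_summary <- function(changes, baseline = 0.35) {
  sel <- changes[changes$at_pss, , drop = FALSE]
  n <- nrow(sel)
  if (n == 0L) stop("no replacement changes at positively selected sites")
  k <- sum(sel$conservative)
  lower <- stats::pbinom(k, n, baseline)
  upper <- stats::pbinom(k - 1L, n, baseline, lower.tail = FALSE)
  p <- min(1, 2 * min(lower, upper))
  list(n_changes = n, n_conservative = k, fraction = k / n, p_value = p)
}
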