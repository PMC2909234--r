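# Per-codon positive-selection scoring and the dual-method PSS calling
# rule. Two desk-scale counting detectors are provided: a phylogenetic one
# (Fitch parsimony changes on a clock-like tree, binomial tail per codon)
# and a population-genetics one (aggregated differences over close pairs).
# Posterior-probability tracks from external tools can be supplied instead
# via read_probability_track().

# ---- Fitch parsimony machinery (shared with the recombination module) ----

# Fitch parsimony state assignment for a set of alignment columns.
# States are bitmasks A=1, C=2, G=4, T=8; N and gap are the full set.
# Ties are resolved deterministically towards the alphabetically first
# nucleotide (lowest set bit).
.fitch_states <- function(alignment, tree, cols) {
  if (!setequal(tree$tip.label, alignment$ids))
    stop("tree tip labels do not match alignment identifiers")
  nt2bit <- c(A = 1L, C = 2L, G = 4L, T = 8L, N = 15L, "-" = 15L)
  ntip <- length(tree$tip.label)
  tot <- ntip + tree$Nnode
  S <- matrix(0L, tot, length(cols))
  tipidx <- match(tree$tip.label, alignment$ids)
  for (i in seq_len(ntip))
    S[i, ] <- unname(nt2bit[alignment$seqs[tipidx[i], cols]])
  tr <- ape::reorder.phylo(tree, "postorder")
  E <- tr$edge
  seen <- logical(tot)
  for (k in seq_len(nrow(E))) {
    p <- E[k, 1L]; ch <- E[k, 2L]
    if (!seen[p]) {
      S[p, ] <- S[ch, ]
      seen[p] <- TRUE
    } else {
      I <- bitwAnd(S[p, ], S[ch, ])
      z <- I == 0L
      S[p, ] <- ifelse(z, bitwOr(S[p, ], S[ch, ]), I)
    }
  }
  lowbit <- function(x) bitwAnd(x, -x)
  A <- matrix(0L, tot, length(cols))
  root <- ntip + 1L
  A[root, ] <- lowbit(S[root, ])
  for (k in rev(seq_len(nrow(E)))) {
    p <- E[k, 1L]; ch <- E[k, 2L]
    keep <- bitwAnd(S[ch, ], A[p, ]) > 0L
    A[ch, ] <- ifelse(keep, A[p, ], lowbit(S[ch, ]))
  }
  list(assign = A, edge = E, ntip = ntip)
}

# Per-codon synonymous/non-synonymous change counts implied by Fitch
# parsimony over the tree. Codons with alignment gaps are excluded (their
# counts stay 0 and they are flagged gapped). Multi-hit codons on one edge
# are decomposed by minimal-pathway averaging.
.parsimony_codon_counts <- function(alignment, tree) {
  gapped <- .gapped_codons(alignment)
  codons <- which(!gapped)
  n <- alignment$n_codons
  syn <- numeric(n); nonsyn <- numeric(n)
  if (length(codons) > 0L) {
    cols <- as.vector(rbind(3L * codons - 2L, 3L * codons - 1L, 3L * codons))
    fs <- .fitch_states(alignment, tree, cols)
    A <- fs$assign
    ntchar <- character(8L)
    ntchar[c(1L, 2L, 4L, 8L)] <- c("A", "C", "G", "T")
    for (k in seq_len(nrow(fs$edge))) {
      p <- fs$edge[k, 1L]; ch <- fs$edge[k, 2L]
      dcols <- which(A[p, ] != A[ch, ])
      if (length(dcols) == 0L) next
      for (ci in unique((dcols + 2L) %/% 3L)) {
        sel <- (3L * ci - 2L):(3L * ci)
        pc <- paste(ntchar[A[p, sel]], collapse = "")
        cc <- paste(ntchar[A[ch, sel]], collapse = "")
        d <- codon_diff_counts(pc, cc)
        syn[codons[ci]] <- syn[codons[ci]] + d[["syn"]]
        nonsyn[codons[ci]] <- nonsyn[codons[ci]] + d[["nonsyn"]]
      }
    }
  }
  list(syn = syn, nonsyn = nonsyn, gapped = gapped)
}

# per-codon expected non-synonymous fraction pN = N/(N+S) from the site
# fractions of the codons observed in that column (mean over sequences)
.codon_pn <- function(alignment) {
  cm <- .codon_matrix(alignment)
  vapply(seq_len(ncol(cm)), function(j) {
    s <- syn_sites(cm[, j])
    s <- s[!is.na(s)]
    if (length(s) == 0L) return(0.75)
    (3 - mean(s)) / 3
  }, numeric(1))
}

# one-sided binomial tail score: 1 - P(X >= nonsyn | n = syn+nonsyn, pN)
.binom_selection_prob <- function(nonsyn, syn, pn) {
  k <- round(nonsyn)
  n <- round(nonsyn + syn)
  k <- pmin(k, n)
  pv <- ifelse(n == 0L, 1,
               stats::pbinom(k - 1L, n, pn, lower.tail = FALSE))
  1 - pv
}

#' Phylogenetic positive-selection detector (parsimony counting)
#'
#' Desk-scale counting detector standing in for a codon-model phylogenetic
#' method: ancestral nucleotides are reconstructed per column by Fitch
#' parsimony on a clock-like tree (ties towards the alphabetically first
#' nucleotide), each inferred change is classified
#' synonymous/non-synonymous in its reconstructed codon context, and each
#' codon is scored with a one-sided binomial tail
#' `P(X >= n_obs | n_obs + s_obs, pN)` where `pN = N/(N+S)` comes from the
#' codon's site fractions. The reported probability is one minus that
#' tail. Codons with alignment gaps are excluded (probability 0, flagged
#' gapped).
#'
#' @param alignment A [codon_alignment()] with at least 4 sequences.
#' @param tree Optional ultrametric [ape::phylo]; defaults to
#'   [linearized_tree()] on the amino-acid distance matrix.
#' @return A numeric vector `prob_a` (one per codon) with attribute
#'   `gapped`.
#' @export
detector_phylo <- function(alignment, tree = NULL) {
  if (length(alignment$ids) < 4L)
    stop("detector_phylo needs at least 4 sequences")
  if (is.null(tree))
    tree <- linearized_tree(aa_distance_matrix(alignment))
  counts <- .parsimony_codon_counts(alignment, tree)
  pn <- .codon_pn(alignment)
  prob <- .binom_selection_prob(counts$nonsyn, counts$syn, pn)
  prob[counts$gapped] <- 0
  attr(prob, "gapped") <- counts$gapped
  prob
}

#' Population-genetics positive-selection detector (close-pair counting)
#'
#' Desk-scale counting detector standing in for a population-genetics
#' method: synonymous/non-synonymous differences are aggregated per codon
#' over all sequence pairs with amino-acid p-distance below
#' `close_threshold` (close pairs, minimizing multiple hits), then scored
#' with the same binomial tail as [detector_phylo()]. Pairs are not
#' independent, so the aggregated counts are an approximation; gapped
#' codons are scored from the pairs in which they are ungapped.
#'
#' @param alignment A [codon_alignment()] with at least 4 sequences.
#' @param close_threshold Amino-acid p-distance bound for close pairs
#'   (default 0.05).
#' @return A numeric vector `prob_b` (one per codon) with attribute
#'   `gapped`.
#' @export
detector_popgen <- function(alignment, close_threshold = 0.05) {
  if (length(alignment$ids) < 4L)
    stop("detector_popgen needs at least 4 sequences")
  D <- aa_distance_matrix(alignment)
  n <- alignment$n_codons
  idx <- which(upper.tri(D) & D < close_threshold, arr.ind = TRUE)
  gapped <- .gapped_codons(alignment)
  if (nrow(idx) == 0L) {
    warning("no close pairs below threshold ", close_threshold,
            "; returning an all-zero track")
    prob <- rep(0, n)
    attr(prob, "gapped") <- gapped
    return(prob)
  }
  cm <- .codon_matrix(alignment)
  syn <- numeric(n); nonsyn <- numeric(n)
  for (k in seq_len(nrow(idx))) {
    i <- idx[k, 1L]; j <- idx[k, 2L]
    for (cd in seq_len(n)) {
      a <- cm[i, cd]; b <- cm[j, cd]
      if (a == b) next
      if (!.codon_ok(a) || !.codon_ok(b)) next
      d <- codon_diff_counts(a, b)
      syn[cd] <- syn[cd] + d[["syn"]]
      nonsyn[cd] <- nonsyn[cd] + d[["nonsyn"]]
    }
  }
  pn <- .codon_pn(alignment)
  prob <- .binom_selection_prob(nonsyn, syn, pn)
  attr(prob, "gapped") <- gapped
  prob
}

#' Call positively selected sites from a dual-method probability track
#'
#' An ungapped codon is called positively selected when one method
#' supports it with probability above 0.95 and the other above 0.50
#' (strict inequalities); a gapped codon, which the phylogenetic method
#' cannot analyse, is called when the population-genetics probability
#' alone exceeds 0.95.
#'
#' @param track A `probability_track` (see [probability_track()]).
#' @return A `site_selection_profile`: the track data frame with an
#'   `is_pss` column, plus attributes `pss_set` (called codon indices) and
#'   `counts` (`n_ungapped_pss`, `n_gapped_pss`).
#' @examples
#' call_pss(probability_track(c(0.96, 0.96), c(0.60, 0.40), c(FALSE, FALSE)))
#' @export
call_pss <- function(track) {
  hi <- pmax(track$prob_a, track$prob_b)
  lo <- pmin(track$prob_a, track$prob_b)
  is_pss <- ifelse(track$gapped,
                   track$prob_b > 0.95,
                   hi > 0.95 & lo > 0.50)
  out <- track
  out$is_pss <- is_pss
  class(out) <- c("site_selection_profile", "data.frame")
  attr(out, "pss_set") <- which(is_pss)
  attr(out, "counts") <- c(n_ungapped_pss = sum(is_pss & !track$gapped),
                           n_gapped_pss = sum(is_pss & track$gapped))
  out
}

#' @export
print.site_selection_profile <- function(x, ...) {
  ct <- attr(x, "counts")
  cat("site selection profile: ", nrow(x), " codons; ",
      ct[["n_ungapped_pss"]], " ungapped + ", ct[["n_gapped_pss"]],
      " gapped positively selected sites\n", sep = "")
  invisible(x)
}

#' Run both detectors and call positively selected sites
#'
#' Convenience wrapper: [detector_phylo()] + [detector_popgen()] +
#' [call_pss()], or [call_pss()] on an externally supplied track.
#'
#' @param alignment A [codon_alignment()].
#' @param tree Optional tree for the phylogenetic detector.
#' @param track Optional externally supplied `probability_track`; when
#'   given, the detectors are skipped.
#' @param close_threshold Close-pair bound for [detector_popgen()].
#' @return A `site_selection_profile`.
#' @export
selection_profile <- function(alignment, tree = NULL, track = NULL,
                              close_threshold = 0.05) {
  if (is.null(track)) {
    pa <- detector_phylo(alignment, tree)
    pb <- detector_popgen(alignment, close_threshold)
    track <- probability_track(as.numeric(pa), as.numeric(pb),
                               attr(pa, "gapped"))
  }
  call_pss(track)
}
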