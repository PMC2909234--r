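# Gene-conversion/recombination detection: a MaxChi-style pairwise
# permutation scan, consolidation of overlapping signals into independent
# events, parsimony counting of synonymous mutations, and the
# events-per-synonymous-mutation ratio. Externally produced event tables
# (e.g. from multi-method recombination-detection suites) can be fed to
# consolidate_events() directly.

# max chi-square over candidate breakpoints for a 0/1 mismatch vector x.
# Window: the `w` nearest polymorphic sites each side, truncated at the
# ends. Returns list(chi2, index) where index i means the break falls
# between sites i and i+1.
.maxchi_stat <- function(x, w) {
  m <- length(x)
  if (m < 2L) return(list(chi2 = 0, index = NA_integer_))
  cs <- c(0, cumsum(x))
  i <- seq_len(m - 1L)
  l0 <- pmax(0L, i - w)
  r1 <- pmin(m, i + w)
  a <- cs[i + 1L] - cs[l0 + 1L]      # mismatches left
  cc <- cs[r1 + 1L] - cs[i + 1L]     # mismatches right
  nl <- i - l0
  nr <- r1 - i
  b <- nl - a
  d <- nr - cc
  n <- nl + nr
  num <- n * (a * d - b * cc)^2
  den <- (a + b) * (cc + d) * (a + cc) * (b + d)
  chi2 <- ifelse(den > 0, num / den, 0)
  best <- which.max(chi2)
  list(chi2 = chi2[best], index = best)
}

#' MaxChi-style scan for recombination signals
#'
#' For each unordered sequence pair, pairwise-ungapped columns that are
#' polymorphic in the alignment are classified match/mismatch; for every
#' candidate breakpoint a 2x2 chi-square (no continuity correction) of
#' mismatch counts left/right is computed within a window of the `window`
#' nearest such sites on each side (truncated at the ends). The maximum
#' chi-square is compared against a null obtained by permuting column
#' order (seeded); pairs with permutation `p < alpha` yield an event.
#'
#' @param alignment A [codon_alignment()].
#' @param n_permutations Number of column-order permutations per pair
#'   (default 1000, minimum 100). The permutation loop stops early once a
#'   pair can no longer reach significance.
#' @param seed Integer seed for the permutation null.
#' @param alpha Significance threshold (default 0.05).
#' @param window Number of polymorphic sites per side (default 20).
#' @return Data frame of events: `seq1`, `seq2`, `breakpoint` (1-based
#'   alignment column of the first site right of the break), `chi2`,
#'   `p_value`. Zero rows when no pair is significant.
#' @export
maxchi_scan <- function(alignment, n_permutations = 1000, seed = 1,
                        alpha = 0.05, window = 20) {
  if (n_permutations < 100) stop("n_permutations must be at least 100")
  set.seed(seed)
  mat <- alignment$seqs
  ids <- alignment$ids
  ord <- order(ids)   # scan order independent of input order
  nt <- mat %in% c("A", "C", "G", "T")
  dim(nt) <- dim(mat)
  poly <- vapply(seq_len(ncol(mat)), function(j) {
    v <- mat[nt[, j], j]
    length(unique(v)) > 1L
  }, logical(1))
  polycols <- which(poly)
  events <- list()
  stop_at <- floor(alpha * (n_permutations + 1))
  if (length(polycols) >= 4L) {
    for (ii in seq_len(length(ids) - 1L)) {
      for (jj in (ii + 1L):length(ids)) {
        i <- ord[ii]; j <- ord[jj]
        ok <- nt[i, polycols] & nt[j, polycols]
        cols <- polycols[ok]
        if (length(cols) < 4L) next
        x <- as.integer(mat[i, cols] != mat[j, cols])
        if (sum(x) == 0L || sum(x) == length(x)) next
        obs <- .maxchi_stat(x, window)
        if (obs$chi2 <= 0) next
        cnt <- 0L; done <- 0L
        for (b in seq_len(n_permutations)) {
          perm <- .maxchi_stat(sample(x), window)
          if (perm$chi2 >= obs$chi2) cnt <- cnt + 1L
          done <- b
          if (cnt >= stop_at) break
        }
        p <- (1 + cnt) / (1 + done)
        if (p < alpha) {
          events[[length(events) + 1L]] <- data.frame(
            seq1 = ids[i], seq2 = ids[j],
            breakpoint = cols[obs$index + 1L],
            chi2 = obs$chi2, p_value = p, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(events) == 0L)
    return(data.frame(seq1 = character(), seq2 = character(),
                      breakpoint = integer(), chi2 = numeric(),
                      p_value = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, events)
}

#' Consolidate recombination signals into independent events
#'
#' Greedy transitive merge: two signals belong to the same event when
#' their breakpoints differ by at most `breakpoint_tolerance` nucleotides
#' and their sequence sets overlap. Reports the number of merged groups
#' (independent events) and the union of sequences involved.
#'
#' @param events Event data frame as returned by [maxchi_scan()] (or an
#'   externally supplied table with columns `seq1`, `seq2`, `breakpoint`).
#' @param breakpoint_tolerance Maximum breakpoint separation in nt for
#'   merging (default 30).
#' @return List with `n_independent_events`, `recombinant_ids` and
#'   `groups` (event-group index per input row).
#' @export
consolidate_events <- function(events, breakpoint_tolerance = 30) {
  n <- nrow(events)
  if (n == 0L)
    return(list(n_independent_events = 0L, recombinant_ids = character(),
                groups = integer()))
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (abs(events$breakpoint[i] - events$breakpoint[j]) >
          breakpoint_tolerance) next
      si <- c(events$seq1[i], events$seq2[i])
      sj <- c(events$seq1[j], events$seq2[j])
      if (length(intersect(si, sj)) == 0L) next
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  groups <- match(roots, unique(roots))
  list(n_independent_events = length(unique(groups)),
       recombinant_ids = sort(unique(c(events$seq1, events$seq2))),
       groups = groups)
}

#' Total synonymous mutations implied by an alignment on a tree
#'
#' Parsimony stand-in for model-based counting: ancestral nucleotides are
#' reconstructed by Fitch parsimony, every inferred change is classified
#' in its reconstructed codon context (minimal-pathway averaging for
#' multi-hit codons), and the synonymous changes are summed over all
#' branches and codons. Codons with alignment gaps are excluded.
#'
#' @param alignment A [codon_alignment()].
#' @param tree [ape::phylo] with tip labels equal to the alignment ids.
#' @return Total synonymous mutation count (possibly fractional because of
#'   pathway averaging).
#' @export
count_syn_mutations <- function(alignment, tree) {
  counts <- .parsimony_codon_counts(alignment, tree)
  sum(counts$syn)
}

#' Recombination events per synonymous mutation
#'
#' @param n_events Number of independent recombination events.
#' @param n_syn Number of synonymous mutations implied by the data
#'   (must be positive).
#' @return The ratio, rounded to 3 decimals.
#' @examples
#' recomb_per_synmut(17, 571.1)  # 0.030
#' recomb_per_synmut(6, 484.9)   # 0.012
#' @export
recomb_per_synmut <- function(n_events, n_syn) {
  if (n_syn <= 0) stop("n_syn must be positive (undefined ratio)")
  round(n_events / n_syn, 3)
}

#' Full recombination report for an alignment
#'
#' Runs [maxchi_scan()], [consolidate_events()] and
#' [count_syn_mutations()] and assembles the events-per-synonymous-
#' mutation ratio and the percentage of sequences showing evidence of a
#' recombination event (a lower bound on the recombinant fraction).
#'
#' @inheritParams maxchi_scan
#' @param tree Optional tree; defaults to [linearized_tree()] on the
#'   amino-acid distance matrix.
#' @param breakpoint_tolerance Merge tolerance for
#'   [consolidate_events()].
#' @return List of class `recombination_report` with `events`,
#'   `n_independent_events`, `n_syn_mutations`, `ratio`,
#'   `recombinant_ids`, `percent_recombinant_sequences`.
#' @export
recombination_report <- function(alignment, tree = NULL,
                                 n_permutations = 1000, seed = 1,
                                 alpha = 0.05, window = 20,
                                 breakpoint_tolerance = 30) {
  if (is.null(tree))
    tree <- linearized_tree(aa_distance_matrix(alignment))
  events <- maxchi_scan(alignment, n_permutations, seed, alpha, window)
  cons <- consolidate_events(events, breakpoint_tolerance)
  nsyn <- count_syn_mutations(alignment, tree)
  ratio <- if (nsyn > 0 && cons$n_independent_events > 0)
    recomb_per_synmut(cons$n_independent_events, nsyn)
  else if (nsyn > 0) 0 else NA_real_
  structure(list(
    events = events,
    n_independent_events = cons$n_independent_events,
    n_syn_mutations = nsyn,
    ratio = ratio,
    recombinant_ids = cons$recombinant_ids,
    percent_recombinant_sequences =
      100 * length(cons$recombinant_ids) / length(alignment$ids)),
    class = "recombination_report")
}

#' @export
print.recombination_report <- function(x, ...) {
  cat("recombination report\n")
  cat("  independent events:     ", x$n_independent_events, "\n")
  cat("  synonymous mutations:   ", format(x$n_syn_mutations, digits = 5),
      "\n")
  cat("  events per syn mutation:", format(x$ratio, nsmall = 3), "\n")
  cat(sprintf("  recombinant sequences:   %d (>= %.1f%% of sequences)\n",
              length(x$recombinant_ids), x$percent_recombinant_sequences))
  invisible(x)
}
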