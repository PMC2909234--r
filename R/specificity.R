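# Allelic specificities: single-linkage clustering at an amino-acid
# divergence threshold, per-genus counting, trans-generic (ancestral)
# lineage sharing, lineage ages under a divergence clock, the
# new-specificity rate, and its Poisson divergence threshold.

#' Cluster sequences into specificities
#'
#' Single-linkage connected components over pairs with amino-acid
#' p-distance at or below `threshold`: sequences differing by more than
#' the threshold belong to different specificities unless connected
#' through intermediates. Boundary pairs (distance exactly equal to the
#' threshold) are the same specificity. Clusters are ordered by their
#' lexicographically smallest member.
#'
#' @param matrix Symmetric amino-acid distance matrix with dimnames.
#' @param threshold Divergence threshold (default 0.05, i.e. 5%).
#' @param genus Optional named character vector of genus labels per id;
#'   parsed from the ids with [parse_genus()] when omitted.
#' @return An object of class `specificity_partition`: list with
#'   `clusters` (list of id vectors), `genus`, `threshold`.
#' @export
cluster_specificities <- function(matrix, threshold = 0.05, genus = NULL) {
  ids <- rownames(matrix)
  if (is.null(genus)) {
    genus <- parse_genus(ids)
    names(genus) <- ids
  }
  n <- length(ids)
  adj <- matrix <= threshold
  adj[is.na(adj)] <- FALSE
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cur <- cur + 1L
    queue <- i
    comp[i] <- cur
    while (length(queue) > 0L) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      nb <- which(adj[v, ] & is.na(comp))
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  clusters <- split(ids, comp)
  clusters <- lapply(clusters, sort)
  clusters <- clusters[order(vapply(clusters, `[`, character(1), 1L))]
  names(clusters) <- NULL
  structure(list(clusters = clusters, genus = genus, threshold = threshold),
            class = "specificity_partition")
}

#' @export
print.specificity_partition <- function(x, ...) {
  cat("specificity partition: ", length(x$clusters),
      " specificities among ", length(unlist(x$clusters)),
      " sequences (threshold ", x$threshold, ")\n", sep = "")
  invisible(x)
}

#' Specificity counts per genus
#'
#' Per genus, the number of specificity clusters containing at least one
#' sequence of that genus; the total is the number of clusters (a cluster
#' spanning several genera counts once in the total but once per genus).
#'
#' @param partition A `specificity_partition`.
#' @return List with `per_genus` (named integer vector) and `total`.
#' @export
genus_counts <- function(partition) {
  genus <- partition$genus
  if (any(!nzchar(genus) | is.na(genus))) {
    warning("empty genus labels counted under 'unknown'")
    genus[!nzchar(genus) | is.na(genus)] <- "unknown"
  }
  genera <- sort(unique(genus))
  per <- vapply(genera, function(g) {
    sum(vapply(partition$clusters,
               function(cl) any(genus[cl] == g), logical(1)))
  }, integer(1))
  list(per_genus = per, total = length(partition$clusters))
}

#' Ancestral lineages shared between genera
#'
#' Entry `(A, B)` is the number of clusters containing both genus A and
#' genus B divided by the number of clusters containing genus A (row
#' convention: the denominator is the row genus, so the matrix is
#' asymmetric while the numerator is symmetric). The diagonal is `NA`.
#'
#' @param partition A `specificity_partition` with at least 2 genera.
#' @return List with `fraction` (numeric matrix), `shared` (numerator
#'   matrix), `n_lineages` (per-genus denominators) and `formatted`
#'   (character matrix of `"n/d (pct)"` cells).
#' @export
shared_lineages <- function(partition) {
  genus <- partition$genus
  genera <- sort(unique(genus))
  if (length(genera) < 2L) stop("need at least 2 genera")
  has <- vapply(genera, function(g) {
    vapply(partition$clusters, function(cl) any(genus[cl] == g), logical(1))
  }, logical(length(partition$clusters)))
  if (is.null(dim(has))) has <- matrix(has, nrow = 1L,
                                       dimnames = list(NULL, genera))
  den <- colSums(has)
  keep <- genera[den > 0L]
  has <- has[, keep, drop = FALSE]
  den <- den[keep]
  k <- length(keep)
  shared <- matrix(0L, k, k, dimnames = list(keep, keep))
  for (a in seq_len(k)) for (b in seq_len(k))
    shared[a, b] <- sum(has[, a] & has[, b])
  fraction <- shared / den
  diag(fraction) <- NA_real_
  formatted <- matrix("-", k, k, dimnames = list(keep, keep))
  for (a in seq_len(k)) for (b in seq_len(k)) {
    if (a == b) next
    formatted[a, b] <- sprintf("%d/%d (%.0f%%)", shared[a, b], den[a],
                               100 * fraction[a, b])
  }
  list(fraction = fraction, shared = shared, n_lineages = den,
       formatted = formatted)
}

#' Lineage ages from amino-acid divergence
#'
#' Linear divergence clock: `age (My) = p_aa * calibration`, with the
#' default calibration of 100 My per unit divergence (1% amino-acid
#' divergence per million years).
#'
#' @param matrix Amino-acid distance matrix.
#' @param calibration Million years per unit divergence (default 100).
#' @return List with `ages` (matrix, My) and `oldest` (maximum age, My).
#' @export
lineage_ages <- function(matrix, calibration = 100) {
  ages <- matrix * calibration
  list(ages = ages, oldest = max(ages, na.rm = TRUE))
}

#' Close sequence pairs with their divergence and PSS differences
#'
#' All pairs with amino-acid p-distance strictly below `threshold`, with
#' Ka, Ks, the number of amino-acid differences and the number of
#' differences at positively selected sites. This is the input of
#' [new_specificity_rate()].
#'
#' @param alignment A [codon_alignment()].
#' @param pss Either a `site_selection_profile` or an integer vector of
#'   positively selected codon indices.
#' @param matrix Optional precomputed [aa_distance_matrix()].
#' @param threshold Amino-acid divergence bound (default 0.05).
#' @return Data frame: `id1`, `id2`, `ka`, `ks`, `n_aa_diffs`,
#'   `n_pss_diffs`.
#' @export
close_pairs <- function(alignment, pss, matrix = NULL, threshold = 0.05) {
  if (inherits(pss, "site_selection_profile")) pss <- attr(pss, "pss_set")
  if (is.null(matrix)) matrix <- aa_distance_matrix(alignment)
  aa <- translate_alignment(alignment)
  aa[aa %in% c("-", "X", "*")] <- NA_character_
  cm <- .codon_matrix(alignment)
  ids <- alignment$ids
  idx <- which(upper.tri(matrix) & matrix < threshold, arr.ind = TRUE)
  rows <- lapply(seq_len(nrow(idx)), function(k) {
    i <- idx[k, 1L]; j <- idx[k, 2L]
    d <- kaks_pair(cm[i, ], cm[j, ])
    ok <- !is.na(aa[i, ]) & !is.na(aa[j, ])
    diffs <- which(ok & aa[i, ] != aa[j, ])
    data.frame(id1 = ids[i], id2 = ids[j], ka = d$ka, ks = d$ks,
               n_aa_diffs = length(diffs),
               n_pss_diffs = sum(diffs %in% pss),
               stringsAsFactors = FALSE)
  })
  if (length(rows) == 0L)
    return(data.frame(id1 = character(), id2 = character(), ka = numeric(),
                      ks = numeric(), n_aa_diffs = integer(),
                      n_pss_diffs = integer(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Rate of appearance of new specificities
#'
#' Under the assumption that a single amino-acid change at a positively
#' selected site creates a new specificity, the rate is expressed as
#' percent synonymous (and non-synonymous) divergence per PSS change.
#' The default estimator is the ratio of sums over close pairs,
#' `100 * sum(Ks) / sum(n_pss_diffs)`; a mean-of-ratios alternative
#' (mean over pairs with at least one PSS difference) is available.
#'
#' @param pairs Data frame as from [close_pairs()] (columns `ks`, `ka`,
#'   `n_pss_diffs`).
#' @param estimator `"ratio_of_sums"` (default) or `"mean_of_ratios"`.
#' @return List with `ks_per_new_specificity` and
#'   `ka_per_new_specificity`, both in percent divergence per new
#'   specificity.
#' @export
new_specificity_rate <- function(pairs,
                                 estimator = c("ratio_of_sums",
                                               "mean_of_ratios")) {
  estimator <- match.arg(estimator)
  if (sum(pairs$n_pss_diffs) == 0)
    stop("no differences at positively selected sites; rate undefined")
  if (estimator == "ratio_of_sums") {
    ks <- 100 * sum(pairs$ks) / sum(pairs$n_pss_diffs)
    ka <- 100 * sum(pairs$ka) / sum(pairs$n_pss_diffs)
  } else {
    sel <- pairs$n_pss_diffs > 0
    ks <- 100 * mean(pairs$ks[sel] / pairs$n_pss_diffs[sel])
    ka <- 100 * mean(pairs$ka[sel] / pairs$n_pss_diffs[sel])
  }
  list(ks_per_new_specificity = ks, ka_per_new_specificity = ka)
}

#' Poisson probability of no hit at a positively selected site
#'
#' Probability that a pair with non-synonymous divergence `ka` shows zero
#' changes at positively selected sites, when one PSS change is expected
#' per `rate` units of non-synonymous divergence: `exp(-ka / rate)`.
#'
#' @param ka Non-synonymous divergence of the pair.
#' @param rate Non-synonymous divergence per PSS change (default 0.0192).
#' @return Probability in `[0, 1]`.
#' @examples
#' poisson_no_hit(0.058, 0.0192)  # < 0.05
#' @export
poisson_no_hit <- function(ka, rate = 0.0192) {
  if (any(ka < 0)) stop("ka must be non-negative")
  if (rate <= 0) stop("rate must be positive")
  exp(-ka / rate)
}

#' Divergence threshold for a given no-hit probability
#'
#' Inverse of [poisson_no_hit()]: the non-synonymous divergence above
#' which the probability of zero PSS changes falls below `p`.
#'
#' @param p Target probability.
#' @param rate Non-synonymous divergence per PSS change (default 0.0192).
#' @return The divergence threshold `-rate * log(p)`.
#' @export
threshold_ka <- function(p, rate = 0.0192) {
  if (any(p <= 0 | p > 1)) stop("p must lie in (0, 1]")
  -rate * log(p)
}
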