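# Codon-level utilities shared by the divergence, selection, recombination
# and simulation code: the standard genetic code, synonymous site fractions
# (Nei-Gojobori 1986), and minimal-pathway decomposition of codon
# differences with stop-avoiding paths.

.NT <- c("A", "C", "G", "T")

# standard genetic code, codon -> one-letter amino acid ("*" = stop)
.codon_env <- new.env(parent = emptyenv())

.genetic_code <- function() {
  if (is.null(.codon_env$code)) {
    gc <- Biostrings::GENETIC_CODE
    .codon_env$code <- setNames(as.character(gc), names(gc))
  }
  .codon_env$code
}

.all_codons <- function() {
  if (is.null(.codon_env$codons)) {
    .codon_env$codons <- names(Biostrings::GENETIC_CODE)
  }
  .codon_env$codons
}

#' Translate a single codon
#'
#' Codons made entirely of gaps translate to `"-"`; codons containing `N`
#' (or a partial gap) translate to `"X"`; stop codons translate to `"*"`.
#'
#' @param codon Character scalar of length-3 nucleotides over `A,C,G,T,-,N`.
#' @return Single amino-acid character.
#' @export
translate_codon <- function(codon) {
  if (nchar(codon) != 3L) stop("codon must have exactly 3 nucleotides")
  if (codon == "---") return("-")
  code <- .genetic_code()
  aa <- code[[codon]]
  if (is.null(aa)) return("X")
  aa
}

.is_stop <- function(codon) {
  code <- .genetic_code()
  aa <- code[[codon]]
  !is.null(aa) && aa == "*"
}

# Synonymous site count of a codon (0..3): per position, the fraction of the
# non-stop single-nucleotide changes that are synonymous.  Changes to stop
# codons are excluded from the denominator (DNasp/MEGA convention).
.syn_sites_one <- function(codon) {
  code <- .genetic_code()
  aa0 <- code[[codon]]
  nts <- strsplit(codon, "", fixed = TRUE)[[1L]]
  s <- 0
  for (pos in 1:3) {
    nsyn <- 0L
    nvalid <- 0L
    for (b in .NT) {
      if (b == nts[pos]) next
      alt <- nts
      alt[pos] <- b
      altc <- paste(alt, collapse = "")
      if (code[[altc]] == "*") next
      nvalid <- nvalid + 1L
      if (code[[altc]] == aa0) nsyn <- nsyn + 1L
    }
    if (nvalid > 0L) s <- s + nsyn / nvalid
  }
  s
}

#' Synonymous site fraction of a codon (Nei-Gojobori counting)
#'
#' Number of synonymous sites (0 to 3) of an unambiguous non-stop codon:
#' for each codon position, the fraction of possible single-nucleotide
#' changes (excluding changes to stop codons) that leave the amino acid
#' unchanged. The non-synonymous site count is `3 - syn_sites(codon)`.
#'
#' @param codon Character vector of codons over `A,C,G,T`.
#' @return Numeric vector of synonymous site counts; `NA` for codons that
#'   are stops or contain characters other than `A,C,G,T`.
#' @export
syn_sites <- function(codon) {
  if (is.null(.codon_env$syn_sites)) {
    codons <- .all_codons()
    v <- vapply(codons, function(cd) {
      if (.is_stop(cd)) NA_real_ else .syn_sites_one(cd)
    }, numeric(1))
    .codon_env$syn_sites <- v
  }
  out <- .codon_env$syn_sites[codon]
  names(out) <- NULL
  unname(out)
}

# All minimal mutational pathways between two codons: permutations of the
# differing positions. Paths passing through (or ending in) a stop codon are
# discarded; if every path hits a stop, all paths are used as a fallback.
# Returns list of pathways; each pathway is a data.frame of steps with
# columns pos, from_codon, to_codon, from_aa, to_aa, syn.
.codon_pathways <- function(c1, c2) {
  code <- .genetic_code()
  n1 <- strsplit(c1, "", fixed = TRUE)[[1L]]
  n2 <- strsplit(c2, "", fixed = TRUE)[[1L]]
  dpos <- which(n1 != n2)
  if (length(dpos) == 0L) return(list())
  perms <- .permutations(dpos)
  paths <- list()
  valid <- logical(length(perms))
  for (i in seq_along(perms)) {
    ord <- perms[[i]]
    cur <- n1
    steps <- vector("list", length(ord))
    ok <- TRUE
    for (k in seq_along(ord)) {
      pos <- ord[k]
      nxt <- cur
      nxt[pos] <- n2[pos]
      fromc <- paste(cur, collapse = "")
      toc <- paste(nxt, collapse = "")
      from_aa <- code[[fromc]]
      to_aa <- code[[toc]]
      if (to_aa == "*" && k < length(ord)) ok <- FALSE
      if (to_aa == "*" || from_aa == "*") ok <- FALSE
      steps[[k]] <- data.frame(pos = pos, from_codon = fromc, to_codon = toc,
                               from_aa = from_aa, to_aa = to_aa,
                               syn = identical(from_aa, to_aa),
                               stringsAsFactors = FALSE)
      cur <- nxt
    }
    paths[[i]] <- do.call(rbind, steps)
    valid[i] <- ok
  }
  if (any(valid)) paths[valid] else paths
}

.permutations <- function(x) {
  n <- length(x)
  if (n == 1L) return(list(x))
  out <- list()
  for (i in seq_len(n)) {
    rest <- .permutations(x[-i])
    for (r in rest) out[[length(out) + 1L]] <- c(x[i], r)
  }
  out
}

#' Synonymous/non-synonymous difference counts between two codons
#'
#' Differences are resolved over all minimal mutational pathways between the
#' two codons, weighted equally; pathways passing through stop codons are
#' excluded. Returns the average number of synonymous and non-synonymous
#' steps (their sum equals the number of differing positions).
#'
#' @param c1,c2 Codons over `A,C,G,T`.
#' @return Named numeric vector `c(syn = , nonsyn = )`.
#' @export
codon_diff_counts <- function(c1, c2) {
  key <- paste(c1, c2, sep = "|")
  cache <- .codon_env
  if (is.null(cache$diffs)) cache$diffs <- new.env(parent = emptyenv())
  hit <- cache$diffs[[key]]
  if (!is.null(hit)) return(hit)
  paths <- .codon_pathways(c1, c2)
  if (length(paths) == 0L) {
    res <- c(syn = 0, nonsyn = 0)
  } else {
    syn <- mean(vapply(paths, function(p) sum(p$syn), numeric(1)))
    tot <- nrow(paths[[1L]])
    res <- c(syn = syn, nonsyn = tot - syn)
  }
  cache$diffs[[key]] <- res
  cache$diffs[[paste(c2, c1, sep = "|")]] <- res
  res
}

# Deterministic single minimal pathway between two codons: the first
# stop-free pathway when differing positions are permuted in lexicographic
# order (fallback: first pathway). Used to decompose multi-step codon
# changes into individual replacement steps.
.codon_path_steps <- function(c1, c2) {
  paths <- .codon_pathways(c1, c2)
  if (length(paths) == 0L) return(NULL)
  paths[[1L]]
}

# TRUE for codons usable in counting: unambiguous, non-stop
.codon_ok <- function(codon) {
  !is.na(syn_sites(codon))
}
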