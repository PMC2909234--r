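# In-frame codon alignments: construction, validation, FASTA IO, genus
# parsing from sequence identifiers, region masks and per-codon
# probability tracks.

.VALID_CHARS <- c("A", "C", "G", "T", "-", "N")

#' Construct a codon alignment
#'
#' An in-frame, gap-aware alignment of coding sequences with a genus label
#' per sequence. All sequences must have equal length, divisible by 3, over
#' the alphabet `A,C,G,T,-,N` (other ambiguity codes are rejected).
#'
#' @param sequences Named character vector of aligned nucleotide sequences
#'   (names are the sequence identifiers), or a character matrix with one
#'   row per sequence and one column per alignment position.
#' @param genus Optional character vector of genus labels, one per
#'   sequence. When `NULL`, labels are parsed from the identifiers with
#'   `label_rule`.
#' @param label_rule Delimiter used to split identifiers when parsing genus
#'   labels; the first token is the genus. Default `"_"`.
#' @return An object of class `codon_alignment`: a list with elements
#'   `seqs` (character matrix, rows = sequences), `ids`, `genus`,
#'   `length` (nucleotide columns) and `n_codons`.
#' @examples
#' aln <- codon_alignment(c(Malus_a = "ATGAAATTT", Pyrus_b = "ATGAAGTTC"))
#' aln$genus
#' @export
codon_alignment <- function(sequences, genus = NULL, label_rule = "_") {
  if (is.matrix(sequences)) {
    mat <- sequences
    ids <- rownames(mat)
  } else {
    ids <- names(sequences)
    if (is.null(ids)) stop("sequences must be named")
    sequences <- toupper(sequences)
    lens <- nchar(sequences)
    if (length(unique(lens)) != 1L)
      stop("ragged alignment: sequences have unequal lengths (",
           paste(unique(lens), collapse = ", "), ")")
    mat <- do.call(rbind, strsplit(sequences, "", fixed = TRUE))
    rownames(mat) <- ids
  }
  if (is.null(ids) || any(!nzchar(ids)))
    stop("all sequences must have nonempty identifiers")
  if (anyDuplicated(ids)) stop("duplicated sequence identifiers")
  if (nrow(mat) < 2L) stop("an alignment needs at least 2 sequences")
  len <- ncol(mat)
  if (len %% 3L != 0L)
    stop("alignment length ", len, " is not divisible by 3 (frame error)")
  bad <- setdiff(unique(as.vector(mat)), .VALID_CHARS)
  if (length(bad) > 0L)
    stop("illegal characters in alignment: ", paste(bad, collapse = ", "),
         " (only A,C,G,T,-,N are allowed)")
  if (is.null(genus)) genus <- parse_genus(ids, label_rule)
  structure(list(seqs = mat, ids = ids, genus = genus,
                 length = len, n_codons = len %/% 3L),
            class = "codon_alignment")
}

#' Parse genus labels from sequence identifiers
#'
#' @param ids Character vector of identifiers.
#' @param label_rule Delimiter; the first delimited token is the genus.
#' @return Character vector of genus labels.
#' @export
parse_genus <- function(ids, label_rule = "_") {
  vapply(strsplit(ids, label_rule, fixed = TRUE),
         function(x) x[[1L]], character(1))
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("codon alignment: ", length(x$ids), " sequences, ", x$length,
      " nt columns (", x$n_codons, " codons)\n", sep = "")
  cat("genera:", paste(sort(unique(x$genus)), collapse = ", "), "\n")
  invisible(x)
}

#' Read a codon alignment from a FASTA file
#'
#' @param path Path to an aligned FASTA file (gaps allowed).
#' @param label_rule Delimiter for genus parsing (see [parse_genus()]).
#' @return A [codon_alignment()].
#' @export
read_fasta <- function(path, label_rule = "_") {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  codon_alignment(seqs, label_rule = label_rule)
}

#' Write a codon alignment to a FASTA file
#'
#' @param alignment A [codon_alignment()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(alignment, path) {
  seqs <- apply(alignment$seqs, 1L, paste, collapse = "")
  set <- Biostrings::BStringSet(seqs)
  names(set) <- alignment$ids
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Extract a sub-alignment of selected codons
#'
#' Restricts the alignment to the codons in `mask` (1-based codon indices,
#' closed-set semantics), preserving codon order and sequence identifiers.
#' Applying the same mask twice is idempotent.
#'
#' @param alignment A [codon_alignment()].
#' @param mask Integer vector of 1-based codon indices to keep.
#' @return A [codon_alignment()] with `3 * length(unique(mask))` columns.
#' @export
apply_mask <- function(alignment, mask) {
  mask <- sort(unique(as.integer(mask)))
  if (length(mask) == 0L) stop("empty region mask")
  if (any(mask < 1L | mask > alignment$n_codons))
    stop("mask indices out of range [1, ", alignment$n_codons, "]")
  cols <- as.vector(rbind(3L * mask - 2L, 3L * mask - 1L, 3L * mask))
  codon_alignment(alignment$seqs[, cols, drop = FALSE],
                  genus = alignment$genus)
}

#' Read a per-codon selection-probability track
#'
#' Reads a TSV with columns `codon_index`, `prob_a`, `prob_b`, `gapped`
#' (the plug-in format for per-site posterior probabilities from external
#' site-selection tools). Codons absent from the file are filled with
#' probability 0 and a warning.
#'
#' @param path Path to the TSV file.
#' @param alignment The [codon_alignment()] the track belongs to.
#' @return A `probability_track`: a data frame with one row per codon and
#'   columns `codon`, `prob_a`, `prob_b`, `gapped`.
#' @export
read_probability_track <- function(path, alignment) {
  if (!file.exists(path)) stop("file not found: ", path)
  n <- alignment$n_codons
  empty <- file.size(path) == 0L ||
    length(readLines(path, n = 1L, warn = FALSE)) == 0L
  if (empty) {
    warning("empty probability track; filling all ", n, " codons with 0")
    return(probability_track(rep(0, n), rep(0, n), rep(FALSE, n)))
  }
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("codon_index", "prob_a", "prob_b", "gapped")
  if (!all(need %in% names(tab)))
    stop("probability track must have columns: ", paste(need, collapse = ", "))
  if (any(tab$codon_index < 1L | tab$codon_index > n))
    stop("codon_index out of range [1, ", n, "]")
  if (anyDuplicated(tab$codon_index)) stop("duplicated codon_index rows")
  if (any(tab$prob_a < 0 | tab$prob_a > 1 | tab$prob_b < 0 | tab$prob_b > 1))
    stop("probabilities must lie in [0, 1]")
  prob_a <- rep(0, n); prob_b <- rep(0, n); gapped <- rep(FALSE, n)
  idx <- as.integer(tab$codon_index)
  prob_a[idx] <- tab$prob_a
  prob_b[idx] <- tab$prob_b
  gapped[idx] <- as.logical(tab$gapped)
  if (length(idx) < n)
    warning(n - length(idx), " codons missing from track; filled with 0")
  probability_track(prob_a, prob_b, gapped)
}

#' Construct a per-codon probability track
#'
#' @param prob_a,prob_b Per-codon probabilities in `[0, 1]` from the
#'   phylogenetic and population-genetics detectors respectively.
#' @param gapped Logical vector flagging codons with alignment gaps.
#' @return A `probability_track` data frame.
#' @export
probability_track <- function(prob_a, prob_b, gapped) {
  stopifnot(length(prob_a) == length(prob_b),
            length(prob_a) == length(gapped))
  if (any(prob_a < 0 | prob_a > 1 | prob_b < 0 | prob_b > 1))
    stop("probabilities must lie in [0, 1]")
  structure(data.frame(codon = seq_along(prob_a), prob_a = prob_a,
                       prob_b = prob_b, gapped = as.logical(gapped)),
            class = c("probability_track", "data.frame"))
}

#' Write a probability track or other report table to TSV
#'
#' @param x A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# amino-acid matrix of an alignment: one column per codon; "-" fully
# gapped, "X" partial gap/ambiguous, "*" stop
translate_alignment <- function(alignment) {
  n <- alignment$n_codons
  out <- matrix("", nrow = length(alignment$ids), ncol = n,
                dimnames = list(alignment$ids, NULL))
  for (j in seq_len(n)) {
    cols <- (3L * j - 2L):(3L * j)
    cods <- apply(alignment$seqs[, cols, drop = FALSE], 1L, paste,
                  collapse = "")
    out[, j] <- vapply(cods, function(cd) {
      if (grepl("-", cd, fixed = TRUE)) {
        if (cd == "---") "-" else "X"
      } else translate_codon(cd)
    }, character(1))
  }
  out
}

# codon string matrix: rows sequences, cols codons
.codon_matrix <- function(alignment) {
  n <- alignment$n_codons
  m <- matrix("", nrow = length(alignment$ids), ncol = n,
              dimnames = list(alignment$ids, NULL))
  for (j in seq_len(n)) {
    cols <- (3L * j - 2L):(3L * j)
    m[, j] <- apply(alignment$seqs[, cols, drop = FALSE], 1L, paste,
                    collapse = "")
  }
  m
}

# codons (columns of .codon_matrix) with an alignment gap in any sequence
.gapped_codons <- function(alignment) {
  n <- alignment$n_codons
  vapply(seq_len(n), function(j) {
    any(alignment$seqs[, (3L * j - 2L):(3L * j)] == "-")
  }, logical(1))
}
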