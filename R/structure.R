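# Protein-structure analyses: PDB parsing, Shrake-Rupley accessible
# surface area with a deterministic sphere point set, mapping of
# alignment positions onto structure residues, exposure statistics for
# positively selected vs other sites, and lysine conservation profiles.

# Chothia-style van der Waals radii (Angstrom) for heavy atoms
.VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)

#' Parse a protein structure from a PDB file
#'
#' Reads ATOM records with \pkg{bio3d}, keeping heavy atoms of the first
#' model only; waters and heteroatoms are excluded. Atoms are assigned
#' van der Waals radii C 1.70, N 1.55, O 1.52, S 1.80 Angstrom; atoms of
#' other elements (e.g. hydrogens) are dropped.
#'
#' @param path Path to a PDB file.
#' @return An object of class `structure_model`: list with `atoms` (data
#'   frame: `element`, `resno`, `chain`, `resid`, `x`, `y`, `z`,
#'   `radius`), `residues` (data frame: `resno`, `chain`, `aa`) and
#'   `sequence` (one-letter string).
#' @export
parse_structure <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop("no ATOM records in ", path)
  at <- at[at$resid != "HOH", , drop = FALSE]
  elem <- toupper(at$elesy)
  miss <- is.na(elem) | !nzchar(elem)
  if (any(miss)) elem[miss] <- substr(gsub("[0-9 ]", "", at$elety[miss]), 1, 1)
  keep <- elem %in% names(.VDW_RADII)
  at <- at[keep, , drop = FALSE]
  elem <- elem[keep]
  if (nrow(at) == 0L) stop("no heavy atoms with known radii in ", path)
  atoms <- data.frame(element = elem, resno = at$resno, chain = at$chain,
                      resid = at$resid, x = at$x, y = at$y, z = at$z,
                      radius = unname(.VDW_RADII[elem]),
                      stringsAsFactors = FALSE)
  res <- unique(atoms[, c("resno", "chain", "resid")])
  res <- res[order(res$chain, res$resno), , drop = FALSE]
  aa <- suppressWarnings(bio3d::aa321(res$resid))
  residues <- data.frame(resno = res$resno, chain = res$chain, aa = aa,
                         stringsAsFactors = FALSE)
  structure(list(atoms = atoms, residues = residues,
                 sequence = paste(aa, collapse = "")),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat("structure model: ", nrow(x$atoms), " heavy atoms, ",
      nrow(x$residues), " residues\n", sep = "")
  invisible(x)
}

# deterministic golden-spiral point set on the unit sphere
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- (seq_len(n) - 1) * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

#' Accessible surface area by the Shrake-Rupley method
#'
#' Per-atom solvent-accessible surface area by uniform sphere sampling
#' with a deterministic golden-spiral point set: each atom's sphere of
#' radius `r + probe` is sampled at `n_points` points, and the accessible
#' fraction (points outside every neighbouring sphere) is multiplied by
#' the sphere area. Residue ASA is the sum over the residue's atoms.
#'
#' @param model A `structure_model` from [parse_structure()].
#' @param probe Probe radius in Angstrom (default 1.4, water).
#' @param n_points Sphere sample points per atom (default 960).
#' @return List with `atom_asa` (numeric, per atom) and `residue_asa`
#'   (named numeric, names `"chain:resno"`, in residue order).
#' @export
shrake_rupley_asa <- function(model, probe = 1.4, n_points = 960) {
  atoms <- model$atoms
  n <- nrow(atoms)
  xyz <- cbind(atoms$x, atoms$y, atoms$z)
  rad <- atoms$radius + probe
  pts <- .sphere_points(n_points)
  atom_asa <- numeric(n)
  maxr <- max(rad)
  for (i in seq_len(n)) {
    d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
      (xyz[, 3] - xyz[i, 3])^2
    nb <- which(d2 < (rad[i] + maxr)^2 & seq_len(n) != i)
    nb <- nb[sqrt(d2[nb]) < rad[i] + rad[nb]]
    sp <- pts * rad[i]
    sp[, 1] <- sp[, 1] + xyz[i, 1]
    sp[, 2] <- sp[, 2] + xyz[i, 2]
    sp[, 3] <- sp[, 3] + xyz[i, 3]
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(acc)) break
      dj2 <- (sp[, 1] - xyz[j, 1])^2 + (sp[, 2] - xyz[j, 2])^2 +
        (sp[, 3] - xyz[j, 3])^2
      acc <- acc & dj2 > rad[j]^2
    }
    atom_asa[i] <- 4 * pi * rad[i]^2 * sum(acc) / n_points
  }
  key <- paste(atoms$chain, atoms$resno, sep = ":")
  reskey <- paste(model$residues$chain, model$residues$resno, sep = ":")
  residue_asa <- vapply(reskey, function(k) sum(atom_asa[key == k]),
                        numeric(1))
  list(atom_asa = atom_asa, residue_asa = residue_asa)
}

#' Map a reference protein sequence onto structure residues
#'
#' Global pairwise alignment (BLOSUM62, affine gaps) of the reference
#' sequence against the structure's residue sequence; each reference
#' position is mapped to a structure residue index or `NA` where
#' unaligned. A warning is emitted when alignment identity falls below
#' 30%.
#'
#' @param reference Amino-acid sequence of the reference (character
#'   scalar; gaps are removed).
#' @param model A `structure_model`.
#' @return Data frame: `ref_pos` (1-based position in the ungapped
#'   reference) and `struct_res` (row index into `model$residues`, `NA`
#'   if unmapped).
#' @export
map_alignment_to_structure <- function(reference, model) {
  ref <- gsub("[-*]", "", toupper(reference))
  if (!nzchar(ref)) stop("empty reference sequence")
  data(list = "BLOSUM62", package = "Biostrings",
       envir = environment())
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(ref), Biostrings::AAString(model$sequence),
    substitutionMatrix = get("BLOSUM62", envir = environment()),
    gapOpening = 10, gapExtension = 0.5, type = "global")
  if (Biostrings::pid(al) < 30)
    warning("alignment identity below 30%; mapping may be unreliable")
  p <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1L]]
  s <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1L]]
  map <- rep(NA_integer_, nchar(ref))
  ip <- 0L; is <- 0L
  for (k in seq_along(p)) {
    if (p[k] != "-") ip <- ip + 1L
    if (s[k] != "-") is <- is + 1L
    if (p[k] != "-" && s[k] != "-") map[ip] <- is
  }
  data.frame(ref_pos = seq_len(nchar(ref)), struct_res = map)
}

# Mann-Whitney two-sided test: exact for small samples without ties,
# normal approximation with tie correction otherwise
.mann_whitney <- function(x, y) {
  exact <- min(length(x), length(y)) <= 8 &&
    !any(duplicated(c(x, y)))
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = FALSE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       exact = exact)
}

#' Surface exposure of positively selected vs other sites
#'
#' Mean accessible surface area per category, the fraction of the total
#' exposed surface contributed by each category, and a two-sided
#' Mann-Whitney test of the per-residue ASA distributions (exact when the
#' smaller category has at most 8 residues and there are no ties; normal
#' approximation with tie correction otherwise).
#'
#' @param asa Named numeric vector of per-residue ASA (as
#'   `residue_asa` from [shrake_rupley_asa()]), or unnamed with positions
#'   implied by order.
#' @param pss_residues Indices (or names) of the residues at positively
#'   selected sites; all other residues form the non-PSS category.
#' @return An object of class `surface_report`: list with `n_pss`,
#'   `n_npss`, `mean_pss`, `mean_npss`, `exposed_fraction_pss`,
#'   `exposed_fraction_npss`, `statistic`, `p_value`, `exact`.
#' @export
category_surface_stats <- function(asa, pss_residues) {
  if (is.character(pss_residues)) {
    sel <- names(asa) %in% pss_residues
  } else {
    sel <- seq_along(asa) %in% pss_residues
  }
  x <- unname(asa[sel])   # PSS
  y <- unname(asa[!sel])  # non-PSS
  if (length(x) == 0L || length(y) == 0L)
    stop("both categories need at least one residue")
  tot <- sum(asa)
  mw <- .mann_whitney(x, y)
  structure(list(n_pss = length(x), n_npss = length(y),
                 mean_pss = mean(x), mean_npss = mean(y),
                 exposed_fraction_pss = sum(x) / tot,
                 exposed_fraction_npss = sum(y) / tot,
                 statistic = mw$statistic, p_value = mw$p_value,
                 exact = mw$exact),
            class = "surface_report")
}

#' @export
print.surface_report <- function(x, ...) {
  cat("surface report (accessible surface area)\n")
  cat(sprintf("  PSS:     n = %3d  mean ASA = %7.2f  exposed fraction = %.1f%%\n",
              x$n_pss, x$mean_pss, 100 * x$exposed_fraction_pss))
  cat(sprintf("  non-PSS: n = %3d  mean ASA = %7.2f  exposed fraction = %.1f%%\n",
              x$n_npss, x$mean_npss, 100 * x$exposed_fraction_npss))
  cat(sprintf("  Mann-Whitney U = %.1f, two-sided p = %.4g (%s)\n",
              x$statistic, x$p_value,
              if (x$exact) "exact" else "normal approximation"))
  invisible(x)
}

#' Lysine conservation profile of a reference sequence
#'
#' For each lysine of the reference sequence, the frequency of lysine in
#' the corresponding alignment column over all sequences (gaps and
#' ambiguous codons excluded from the denominator), binned into
#' `<50%`, `50-75%` and `>75%` conservation classes.
#'
#' @param alignment A [codon_alignment()].
#' @param reference_id Identifier of the reference sequence (must contain
#'   at least one lysine).
#' @return Data frame: `ref_pos` (position in the ungapped reference
#'   protein), `codon` (alignment codon column), `freq`, `bin`.
#' @export
lysine_profile <- function(alignment, reference_id) {
  if (!reference_id %in% alignment$ids)
    stop("reference_id not in alignment")
  aa <- translate_alignment(alignment)
  ref <- aa[reference_id, ]
  refpos <- cumsum(ref != "-")
  kcols <- which(ref == "K")
  if (length(kcols) == 0L) stop("reference sequence has no lysine")
  rows <- lapply(kcols, function(j) {
    col <- aa[, j]
    ok <- !(col %in% c("-", "X", "*"))
    freq <- if (any(ok)) sum(col[ok] == "K") / sum(ok) else 0
    bin <- if (freq < 0.50) "<50%" else if (freq <= 0.75) "50-75%" else ">75%"
    data.frame(ref_pos = refpos[j], codon = j, freq = freq, bin = bin,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
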