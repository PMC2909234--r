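# Fixture builders shared across test files. Everything is generated in
# code; no binary fixtures.

# small 4-codon alignment over two genera
toy_alignment <- function() {
  codon_alignment(c(Malus_a = "TTTGGGCCCAAA",
                    Malus_b = "TTCGGGCCCAAA",
                    Pyrus_c = "TTTGGACCCAAA",
                    Pyrus_d = "TTTGGGCCGAAA"))
}

# alignment where sequences fall into well-separated clades
clade_alignment <- function() {
  base1 <- "ATGAAATTTGGGCCCAAAGAG"
  base2 <- "ATGCGGTACGTTAGATCTTGG"
  codon_alignment(c(Malus_a = base1, Pyrus_b = base1,
                    Sorbus_c = base2, Crataegus_d = base2))
}

# brute-force two-sided Mann-Whitney p-value by full enumeration of the
# choose(n1+n2, n1) group assignments (independent oracle)
mw_enum_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  ustat <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  u_obs <- ustat(x, y)
  mu <- n1 * n2 / 2
  combs <- utils::combn(n1 + n2, n1)
  us <- apply(combs, 2L, function(idx) ustat(pooled[idx], pooled[-idx]))
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

# minimal PDB text: `atoms` is a data.frame with name, resn, chain,
# resno, x, y, z, elem
write_toy_pdb <- function(atoms, path = tempfile(fileext = ".pdb")) {
  lines <- vapply(seq_len(nrow(atoms)), function(i) {
    sprintf("ATOM  %5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            i, atoms$name[i], atoms$resn[i], atoms$chain[i], atoms$resno[i],
            atoms$x[i], atoms$y[i], atoms$z[i], 1, 0, atoms$elem[i])
  }, character(1))
  writeLines(c(lines, "END"), path)
  path
}

# a single isolated carbon atom
single_carbon_pdb <- function() {
  write_toy_pdb(data.frame(name = " CA ", resn = "ALA", chain = "A",
                           resno = 1L, x = 0, y = 0, z = 0, elem = "C",
                           stringsAsFactors = FALSE))
}
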