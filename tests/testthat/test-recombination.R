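# MaxChi scan, event consolidation, synonymous-mutation counting and the
# events-per-synonymous-mutation ratio

test_that("max chi-square matches the 2x2 formula on a clean recombinant", {
  # 20 informative sites, all mismatch left of the midpoint, all match
  # right: table (10,0;0,10) -> chi2 = n(ad-bc)^2/prod(margins) = 20
  x <- c(rep(1L, 10), rep(0L, 10))
  st <- SRNaseEvol:::.maxchi_stat(x, 20)
  expect_equal(st$chi2, 20)
  expect_equal(st$index, 10L)
})

test_that("alignments without polymorphism yield no events", {
  aln <- codon_alignment(c(a_1 = "ATGAAATTT", a_2 = "ATGAAATTT",
                           a_3 = "ATGAAATTT"))
  ev <- maxchi_scan(aln, n_permutations = 100, seed = 1)
  expect_equal(nrow(ev), 0L)
})

test_that("a constructed mosaic pair is detected at its breakpoint", {
  # two haplotypes with 13 diagnostic sites per flank; the recombinant
  # copies h2 left of codon 28 and h1 from codon 28 on
  n_cod <- 40
  h1 <- rep("GCT", n_cod)
  h2 <- h1
  h2[seq(2, 26, by = 2)] <- "ACT"   # left-flank diagnostics (pos 1)
  h2[28:40] <- "GTT"                # right-flank diagnostics (pos 2)
  rec <- h2
  rec[28:40] <- h1[28:40]
  aln <- codon_alignment(c(s_h1 = paste(h1, collapse = ""),
                           s_h2 = paste(h2, collapse = ""),
                           s_rec = paste(rec, collapse = "")))
  ev <- maxchi_scan(aln, n_permutations = 500, seed = 2)
  hit <- ev[(ev$seq1 == "s_h2" & ev$seq2 == "s_rec") |
              (ev$seq1 == "s_rec" & ev$seq2 == "s_h2"), , drop = FALSE]
  expect_gte(nrow(hit), 1L)
  # true transition is at nt 82 (codon 28)
  expect_lte(min(abs(hit$breakpoint - 82)), 30)
})

test_that("seeded scans are reproducible and order-invariant", {
  sim <- simulate_dataset(sim_config(n_sequences = 10, n_codons = 60,
                                     n_clades = 2, conversion_rate = 0,
                                     seed = 4))
  aln <- sim$alignment
  ev1 <- maxchi_scan(aln, n_permutations = 200, seed = 9)
  ev2 <- maxchi_scan(aln, n_permutations = 200, seed = 9)
  expect_identical(ev1, ev2)
  # reorder rows: same events
  perm <- rev(seq_along(aln$ids))
  aln_r <- codon_alignment(aln$seqs[perm, , drop = FALSE],
                           genus = aln$genus[perm])
  ev3 <- maxchi_scan(aln_r, n_permutations = 200, seed = 9)
  expect_identical(ev1, ev3)
})

test_that("clonally structured data stays quiet across permutation seeds", {
  # neutral, conversion-free data: spatially homogeneous mismatches
  sim <- simulate_dataset(sim_config(n_sequences = 6, n_codons = 60,
                                     n_clades = 2, omega_pss = 1,
                                     omega_background = 1,
                                     conversion_rate = 0, seed = 8))
  hits <- vapply(1:6, function(s)
    nrow(maxchi_scan(sim$alignment, n_permutations = 200, seed = s)),
    integer(1))
  # no recombination was simulated; at most an occasional false positive
  expect_gte(sum(hits == 0L), 5L)
})

test_that("consolidation merges overlapping signals and counts groups", {
  empty <- data.frame(seq1 = character(), seq2 = character(),
                      breakpoint = integer())
  expect_equal(consolidate_events(empty)$n_independent_events, 0L)
  ev <- data.frame(seq1 = c("a", "a"), seq2 = c("b", "c"),
                   breakpoint = c(430L, 440L), stringsAsFactors = FALSE)
  cons <- consolidate_events(ev, breakpoint_tolerance = 30)
  expect_equal(cons$n_independent_events, 1L)
  expect_equal(cons$recombinant_ids, c("a", "b", "c"))
  far <- data.frame(seq1 = c("a", "a"), seq2 = c("b", "c"),
                    breakpoint = c(100L, 500L), stringsAsFactors = FALSE)
  expect_equal(consolidate_events(far)$n_independent_events, 2L)
  # overlapping breakpoints but disjoint sequences stay separate
  disj <- data.frame(seq1 = c("a", "c"), seq2 = c("b", "d"),
                     breakpoint = c(430L, 440L), stringsAsFactors = FALSE)
  expect_equal(consolidate_events(disj)$n_independent_events, 2L)
})

test_that("parsimony synonymous counting handles two-sequence cases", {
  # two pairs of identical sequences so UPGMA has 4 leaves; one
  # synonymous difference between the pairs
  aln <- codon_alignment(c(a_1 = "TTTGGG", a_2 = "TTTGGG",
                           b_1 = "TTCGGG", b_2 = "TTCGGG"))
  tree <- linearized_tree(aa_distance_matrix(aln))
  expect_equal(count_syn_mutations(aln, tree), 1)
  # one non-synonymous difference: zero synonymous mutations
  aln2 <- codon_alignment(c(a_1 = "TTTGGG", a_2 = "TTTGGG",
                            b_1 = "TATGGG", b_2 = "TATGGG"))
  tree2 <- linearized_tree(aa_distance_matrix(aln2))
  expect_equal(count_syn_mutations(aln2, tree2), 0)
})

test_that("synonymous counts recover simulated truth at low divergence", {
  sim <- simulate_dataset(sim_config(n_sequences = 20, n_codons = 300,
                                     crown_depth = 0.05,
                                     clade_depth = 0.005,
                                     conversion_rate = 0, seed = 9))
  tree <- linearized_tree(aa_distance_matrix(sim$alignment))
  sc <- count_syn_mutations(sim$alignment, tree)
  expect_lt(abs(sc - sim$truth$n_syn_substitutions) /
              sim$truth$n_syn_substitutions, 0.15)
})

test_that("the ratio is exact division reported to 3 decimals", {
  expect_equal(recomb_per_synmut(17, 571.1), 0.030)
  expect_equal(recomb_per_synmut(6, 484.9), 0.012)
  expect_equal(recomb_per_synmut(0, 100), 0)
  expect_error(recomb_per_synmut(3, 0), "positive")
})
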