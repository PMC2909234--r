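# Simulator: determinism, biological invariants, neutral calibration and
# truth-channel recovery

test_that("the same seed and config reproduce the run byte-identically", {
  a <- simulate_dataset(sim_config(n_sequences = 12, n_codons = 60,
                                   n_clades = 3, seed = 42))
  b <- simulate_dataset(sim_config(n_sequences = 12, n_codons = 60,
                                   n_clades = 3, seed = 42))
  expect_identical(a$alignment$seqs, b$alignment$seqs)
  expect_identical(a$truth$events, b$truth$events)
  expect_identical(a$truth$pss, b$truth$pss)
  c <- simulate_dataset(sim_config(n_sequences = 12, n_codons = 60,
                                   n_clades = 3, seed = 43))
  expect_false(identical(a$alignment$seqs, c$alignment$seqs))
})

test_that("simulated sequences never contain internal stop codons", {
  for (s in c(1, 2)) {
    sim <- simulate_dataset(sim_config(n_sequences = 16, n_codons = 80,
                                       n_clades = 4,
                                       conversion_rate = 0.1, seed = s))
    aa <- SRNaseEvol:::translate_alignment(sim$alignment)
    expect_equal(sum(aa == "*"), 0L)
  }
})

test_that("zero conversion rate plants zero events", {
  sim <- simulate_dataset(sim_config(n_sequences = 10, n_codons = 40,
                                     n_clades = 2, conversion_rate = 0,
                                     seed = 2))
  expect_equal(nrow(sim$truth$events), 0L)
})

test_that("config validation rejects infeasible settings", {
  expect_error(sim_config(omega_background = 0), "positive")
  expect_error(sim_config(clade_depth = 0.3, crown_depth = 0.2),
               "crown_depth")
  expect_error(sim_config(n_sequences = 3, n_clades = 6), "n_clades")
  expect_error(sim_config(n_codons = 10, n_pss = 20), "n_pss")
})

test_that("neutral simulation yields mean Ka/Ks near one", {
  sim <- simulate_dataset(sim_config(n_sequences = 20, n_codons = 300,
                                     omega_pss = 1, omega_background = 1,
                                     conversion_rate = 0, seed = 5))
  kk <- kaks_table(sim$alignment)
  ok <- !kk$saturated & kk$ks > 0
  expect_gte(sum(ok), 50)
  ratio <- mean(kk$ka[ok] / kk$ks[ok])
  expect_gt(ratio, 0.9)
  expect_lt(ratio, 1.1)
})

test_that("realized substitution counts track branch lengths", {
  # under neutrality one unit of branch length is one expected
  # substitution per nucleotide site (less a small stop-exclusion loss)
  sim <- simulate_dataset(sim_config(n_sequences = 12, n_codons = 400,
                                     n_clades = 2, omega_pss = 1,
                                     omega_background = 1,
                                     conversion_rate = 0, seed = 10))
  bc <- sim$truth$branch_counts
  big <- bc[bc$length > 0.05, ]
  rate <- (big$syn + big$nonsyn) / (big$length * 3 * 400)
  expect_gt(mean(rate), 0.85)
  expect_lt(mean(rate), 1.05)
})

test_that("clade structure separates at the 5% specificity threshold", {
  sim <- simulate_dataset(sim_config(n_sequences = 30, n_codons = 200,
                                     n_clades = 5, seed = 12))
  D <- aa_distance_matrix(sim$alignment)
  part <- cluster_specificities(D)
  expect_length(part$clusters, 5L)
  # recovered clusters coincide with the planted clades
  truth_clades <- split(sim$truth$clades$id, sim$truth$clades$clade)
  expect_setequal(lapply(part$clusters, sort),
                  lapply(truth_clades, sort))
})

test_that("genera are shared across clades (trans-generic structure)", {
  sim <- simulate_dataset(sim_config(seed = 1))
  tab <- table(sim$truth$clades$genus, sim$truth$clades$clade)
  # every clade contains several genera
  expect_true(all(colSums(tab > 0) >= 3))
})

test_that("recovery metrics are exact on perfect inputs", {
  sim <- simulate_dataset(sim_config(n_sequences = 10, n_codons = 40,
                                     n_clades = 2, conversion_rate = 0,
                                     seed = 2))
  m <- recovery_metrics(sim$truth, pss = sim$truth$pss,
                        syn_count = sim$truth$n_syn_substitutions)
  expect_equal(m$pss_recall, 1)
  expect_equal(m$pss_precision, 1)
  expect_equal(m$pss_fpr, 0)
  expect_equal(m$syn_count_relative_error, 0)
  # empty inferred set: recall 0, precision undefined
  m0 <- recovery_metrics(sim$truth, pss = integer())
  expect_equal(m0$pss_recall, 0)
  expect_true(is.na(m0$pss_precision))
})
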