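# Specificity clustering, genus counting, lineage sharing, ages, the
# new-specificity rate and the Poisson threshold

.dmat <- function(ids, ...) {
  vals <- c(...)
  n <- length(ids)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  D[upper.tri(D)] <- vals
  D[lower.tri(D)] <- t(D)[lower.tri(D)]
  D
}

test_that("single-linkage clustering follows the 5% rule with boundary ties", {
  D <- .dmat(c("A", "B", "C"), 0.02, 0.10, 0.10)  # AB, AC, BC
  part <- cluster_specificities(D, genus = c(A = "g", B = "g", C = "g"))
  expect_equal(part$clusters, list(c("A", "B"), "C"))
  # boundary pair at exactly the threshold joins
  Db <- .dmat(c("A", "B"), 0.05)
  expect_length(cluster_specificities(Db, genus = c(A = "g", B = "g"))$clusters, 1L)
  # identical sequences: one cluster
  D0 <- .dmat(c("A", "B", "C"), 0, 0, 0)
  expect_length(cluster_specificities(D0, genus = c(A = "g", B = "g", C = "g"))$clusters, 1L)
})

test_that("cluster count is non-increasing in the threshold", {
  set.seed(1)
  n <- 12
  ids <- sprintf("s%02d", 1:n)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  D[upper.tri(D)] <- runif(n * (n - 1) / 2, 0, 0.2)
  D[lower.tri(D)] <- t(D)[lower.tri(D)]
  genus <- setNames(rep("g", n), ids)
  counts <- vapply(c(0.01, 0.03, 0.05, 0.1, 0.2), function(th)
    length(cluster_specificities(D, th, genus)$clusters), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("genus counts include shared clusters once per genus", {
  D <- .dmat(c("A", "B", "C"), 0.10, 0.10, 0.02)  # B,C together
  part <- cluster_specificities(
    D, genus = c(A = "Malus", B = "Malus", C = "Pyrus"))
  gc <- genus_counts(part)
  expect_equal(unname(gc$per_genus["Malus"]), 2L)
  expect_equal(unname(gc$per_genus["Pyrus"]), 1L)
  expect_equal(gc$total, 2L)
  # single-genus data: genus count equals total
  part1 <- cluster_specificities(D, genus = c(A = "g", B = "g", C = "g"))
  gc1 <- genus_counts(part1)
  expect_equal(unname(gc1$per_genus["g"]), gc1$total)
  # empty labels go to "unknown" with a warning
  part2 <- cluster_specificities(D, genus = c(A = "", B = "g", C = "g"))
  expect_warning(gc2 <- genus_counts(part2), "unknown")
  expect_true("unknown" %in% names(gc2$per_genus))
})

test_that("shared lineages use the asymmetric row-denominator convention", {
  # clusters: {Malus+Pyrus}, {Malus}
  D <- .dmat(c("M1", "M2", "P1"), 0.2, 0.2, 0.02)  # M2-P1 together
  part <- cluster_specificities(
    D, genus = c(M1 = "Malus", M2 = "Malus", P1 = "Pyrus"))
  sl <- shared_lineages(part)
  expect_equal(sl$fraction["Malus", "Pyrus"], 1 / 2)
  expect_equal(sl$fraction["Pyrus", "Malus"], 1 / 1)
  expect_identical(sl$shared, t(sl$shared))  # numerator symmetric
  expect_true(all(sl$fraction >= 0 & sl$fraction <= 1, na.rm = TRUE))
  expect_match(sl$formatted["Malus", "Pyrus"], "^1/2 \\(50%\\)$")
  # no mixed clusters: zero off-diagonal
  D2 <- .dmat(c("M1", "P1"), 0.5)
  part2 <- cluster_specificities(D2, genus = c(M1 = "Malus", P1 = "Pyrus"))
  expect_equal(shared_lineages(part2)$fraction["Malus", "Pyrus"], 0)
  expect_error(shared_lineages(cluster_specificities(
    D2, genus = c(M1 = "g", P1 = "g"))), "2 genera")
})

test_that("lineage ages scale divergence by the clock calibration", {
  D <- .dmat(c("A", "B"), 0.23)
  la <- lineage_ages(D)
  expect_equal(la$oldest, 23)
  expect_equal(lineage_ages(.dmat(c("A", "B"), 0))$oldest, 0)
  expect_equal(lineage_ages(.dmat(c("A", "B"), 0.1), calibration = 50)$oldest, 5)
})

test_that("the new-specificity rate reproduces the ratio-of-sums identities", {
  one <- data.frame(ks = 0.077, ka = 0.0192, n_pss_diffs = 1L)
  r1 <- new_specificity_rate(one)
  expect_equal(r1$ks_per_new_specificity, 7.7)
  expect_equal(r1$ka_per_new_specificity, 1.92)
  two <- data.frame(ks = c(0.05, 0.10), ka = c(0.01, 0.02),
                    n_pss_diffs = c(1L, 1L))
  expect_equal(new_specificity_rate(two)$ks_per_new_specificity, 7.5)
  expect_equal(new_specificity_rate(two, "mean_of_ratios")$ks_per_new_specificity,
               7.5)
  none <- data.frame(ks = 0.05, ka = 0.01, n_pss_diffs = 0L)
  expect_error(new_specificity_rate(none), "undefined")
})

test_that("close_pairs reports PSS differences for nearby sequences", {
  # a_1/a_2 differ at codon 2 (non-synonymous, a PSS) and codon 3
  # (synonymous); 1 aa difference over 21 codons keeps them below 5%
  base <- rep("GCT", 21)
  v <- base; v[2] <- "CGT"; v[3] <- "GCC"
  far <- rep("TAC", 21)
  aln <- codon_alignment(c(a_1 = paste(base, collapse = ""),
                           a_2 = paste(v, collapse = ""),
                           b_1 = paste(far, collapse = ""),
                           b_2 = paste(far, collapse = "")))
  cp <- close_pairs(aln, pss = c(2L))
  hit <- cp[cp$id1 == "a_1" & cp$id2 == "a_2", ]
  expect_equal(hit$n_aa_diffs, 1L)
  expect_equal(hit$n_pss_diffs, 1L)
  # distant pairs are absent
  expect_false(any(cp$id1 == "a_1" & cp$id2 == "b_1"))
})

test_that("Poisson no-hit and its threshold are exact inverses", {
  expect_equal(poisson_no_hit(0.058, 0.0192), exp(-0.058 / 0.0192))
  expect_lt(poisson_no_hit(0.058, 0.0192), 0.05)
  expect_equal(poisson_no_hit(0, 123), 1)
  expect_equal(threshold_ka(0.05, 0.0192), 0.0575, tolerance = 1e-3)
  p <- c(0.001, 0.01, 0.05, 0.5, 0.99)
  expect_equal(poisson_no_hit(threshold_ka(p)), p, tolerance = 1e-12)
})
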