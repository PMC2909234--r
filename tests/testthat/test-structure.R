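# PDB parsing, Shrake-Rupley ASA, structure mapping, surface statistics
# and lysine profiles

test_that("parse_structure keeps heavy atoms and drops waters", {
  atoms <- data.frame(
    name = c(" N  ", " CA ", " C  ", " O  ", " SG ", " O  "),
    resn = c("CYS", "CYS", "CYS", "CYS", "CYS", "HOH"),
    chain = "A", resno = c(1L, 1L, 1L, 1L, 1L, 2L),
    x = c(0, 1.5, 3, 4, 1.8, 20), y = 0, z = 0,
    elem = c("N", "C", "C", "O", "S", "O"), stringsAsFactors = FALSE)
  model <- parse_structure(write_toy_pdb(atoms))
  expect_equal(nrow(model$atoms), 5L)          # water excluded
  expect_equal(model$sequence, "C")
  expect_equal(model$atoms$radius[model$atoms$element == "S"], 1.80)
  expect_equal(model$atoms$radius[model$atoms$element == "N"], 1.55)
})

test_that("an isolated atom recovers the closed-form sphere area", {
  model <- parse_structure(single_carbon_pdb())
  asa <- shrake_rupley_asa(model, probe = 1.4, n_points = 960)
  exact <- 4 * pi * (1.7 + 1.4)^2
  expect_equal(asa$atom_asa, exact, tolerance = 0.01)
  expect_equal(unname(asa$residue_asa), exact, tolerance = 0.01)
})

test_that("a caged atom is buried and rotation leaves ASA unchanged", {
  # carbon at the origin surrounded by an octahedral cage of six carbons
  d <- 2.0
  cage <- data.frame(
    name = " CA ", resn = "ALA", chain = "A", resno = 1:7,
    x = c(0, d, -d, 0, 0, 0, 0), y = c(0, 0, 0, d, -d, 0, 0),
    z = c(0, 0, 0, 0, 0, d, -d), elem = "C", stringsAsFactors = FALSE)
  model <- parse_structure(write_toy_pdb(cage))
  asa <- shrake_rupley_asa(model)
  expect_lt(asa$atom_asa[1], 1)  # central atom essentially buried
  # rigid rotation: rotate all coordinates 40 degrees about z
  th <- 40 * pi / 180
  rot <- cage
  rot$x <- cage$x * cos(th) - cage$y * sin(th)
  rot$y <- cage$x * sin(th) + cage$y * cos(th)
  asar <- shrake_rupley_asa(parse_structure(write_toy_pdb(rot)))
  expect_equal(asar$atom_asa, asa$atom_asa, tolerance = 0.02)
})

test_that("ASA is additive over well-separated atoms", {
  two <- data.frame(name = " CA ", resn = "ALA", chain = "A",
                    resno = 1:2, x = c(0, 50), y = 0, z = 0, elem = "C",
                    stringsAsFactors = FALSE)
  asa <- shrake_rupley_asa(parse_structure(write_toy_pdb(two)))
  expect_equal(asa$atom_asa[1], asa$atom_asa[2])
  expect_equal(sum(asa$atom_asa), 2 * 4 * pi * 3.1^2, tolerance = 0.02)
})

test_that("alignment-to-structure mapping handles offsets and insertions", {
  atoms <- do.call(rbind, lapply(1:6, function(i)
    data.frame(name = " CA ", resn = c("MET", "LYS", "PHE", "GLY", "TRP",
                                       "HIS")[i],
               chain = "A", resno = i, x = 4 * i, y = 0, z = 0,
               elem = "C", stringsAsFactors = FALSE)))
  model <- parse_structure(write_toy_pdb(atoms))
  expect_equal(model$sequence, "MKFGWH")
  # identical sequences map one to one
  m1 <- map_alignment_to_structure("MKFGWH", model)
  expect_equal(m1$struct_res, 1:6)
  # leading truncation: offset map
  m2 <- map_alignment_to_structure("FGWH", model)
  expect_equal(m2$struct_res, 3:6)
})

test_that("Mann-Whitney p-values match brute-force enumeration", {
  # {1,2,3} vs {4,5,6}: U = 0, one-sided 1/20, two-sided 0.1
  r <- category_surface_stats(
    setNames(c(4, 5, 6, 1, 2, 3), paste0("r", 1:6)), pss_residues = 4:6)
  expect_true(r$exact)
  expect_equal(r$p_value, 0.1)
  expect_equal(r$p_value, mw_enum_p(c(1, 2, 3), c(4, 5, 6)))
  # random configurations, n1 + n2 <= 10, against the enumeration oracle
  set.seed(11)
  for (k in 1:5) {
    n1 <- sample(2:4, 1); n2 <- sample(2:6, 1)
    vals <- sample(1:50, n1 + n2)  # distinct -> exact path
    r2 <- category_surface_stats(setNames(vals, seq_along(vals)),
                                 pss_residues = seq_len(n1))
    expect_equal(r2$p_value, mw_enum_p(vals[seq_len(n1)],
                                       vals[-seq_len(n1)]),
                 tolerance = 1e-12)
  }
})

test_that("surface report fractions sum to one and categories validate", {
  asa <- setNames(c(10, 20, 30, 40), paste0("r", 1:4))
  r <- category_surface_stats(asa, pss_residues = c(3, 4))
  expect_equal(r$exposed_fraction_pss + r$exposed_fraction_npss, 1)
  expect_equal(r$mean_pss, 35)
  expect_equal(r$mean_npss, 15)
  expect_error(category_surface_stats(asa, pss_residues = 1:4),
               "both categories")
})

test_that("lysine profiles follow the gap-excluded denominator", {
  # column 2: K in all sequences; column 3: K in 6 of 10; column 4: half
  # gapped, all non-gap K
  mk <- function(c2, c3, c4) paste0("ATG", c2, c3, c4)
  seqs <- vapply(1:10, function(i) {
    mk("AAA", if (i <= 6) "AAA" else "CGT",
       if (i <= 5) "---" else "AAG")
  }, character(1))
  names(seqs) <- sprintf("s_%02d", 1:10)
  aln <- codon_alignment(seqs)
  prof <- lysine_profile(aln, "s_06")
  expect_equal(prof$freq[prof$codon == 2], 1.0)
  expect_equal(prof$bin[prof$codon == 2], ">75%")
  expect_equal(prof$freq[prof$codon == 3], 0.6)
  expect_equal(prof$bin[prof$codon == 3], "50-75%")
  expect_equal(prof$freq[prof$codon == 4], 1.0)
  # reference without lysine errors
  noK <- codon_alignment(c(a_1 = "ATGGGG", a_2 = "ATGGGG"))
  expect_error(lysine_profile(noK, "a_1"), "no lysine")
})
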