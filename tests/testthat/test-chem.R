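test_that("printed reference masses reproduce from sequence + mods", {
  # unmodified tryptic products
  expect_equal(mono_mass("AGGEESQFEMDI"), 1312.536, tolerance = 1e-3)
  expect_equal(mono_mass("RAGGEESQFEMDI"), 1468.637, tolerance = 1e-3)
  # phosphopeptides
  expect_equal(
    mono_mass(modified_peptide("VADPDHDHTGFLTEYVATR",
                               c(phospho = 13, phospho = 15))),
    2303.937, tolerance = 1e-3)
  expect_equal(
    mono_mass(modified_peptide("RLSSLRASTSKSESSQK",
                               c(phospho = 3, phospho = 4))),
    2011.921, tolerance = 1e-3)
  # carbamidomethyl + phospho
  expect_equal(
    mono_mass(modified_peptide("YCRPESQEHPEADPGSAAPYLK",
                               c(carbamidomethyl = 2, phospho = 20))),
    2582.102, tolerance = 1e-3)
})

test_that("single-residue masses are forced by the constant table", {
  k <- mass_constants()
  expect_equal(mono_mass("G"), 57.021464 + k[["water_mono"]] + k[["proton"]])
  expect_equal(avg_mass("G"), 57.0519 + k[["water_avg"]] + k[["proton"]])
})

test_that("mono mass agrees with an elemental-composition oracle", {
  set.seed(11)
  for (i in 1:25) {
    s <- random_sequence(sample(5:30, 1))
    np <- sample(0:2, 1)
    sty <- which(strsplit(s, "")[[1]] %in% c("S", "T", "Y"))
    np <- min(np, length(sty))
    pep <- if (np > 0) {
      modified_peptide(s, data.frame(position = sty[seq_len(np)],
                                     name = "phospho"))
    } else s
    expect_equal(mono_mass(pep), oracle_mh(s, np, "mono"), tolerance = 1e-4)
  }
})

test_that("average mass tracks the elemental oracle and exceeds mono", {
  # avg constants across sources differ in the 3rd decimal per residue
  expect_equal(avg_mass("G"), oracle_mh("G", 0, "avg"), tolerance = 2e-3)
  expect_equal(avg_mass(modified_peptide("DMYDKEYYSVHNK",
                                         c(phospho = 7, phospho = 8))),
               oracle_mh("DMYDKEYYSVHNK", 2, "avg"), tolerance = 0.05)
  set.seed(21)
  for (i in 1:10) {
    s <- random_sequence(sample(3:25, 1))
    expect_gt(avg_mass(s), mono_mass(s))
    expect_equal(avg_mass(s), oracle_mh(s, 0, "avg"), tolerance = 0.05)
  }
})

test_that("concatenation identity holds for random peptide pairs", {
  k <- mass_constants()
  set.seed(31)
  for (i in 1:10) {
    a <- random_sequence(sample(2:20, 1))
    b <- random_sequence(sample(2:20, 1))
    expect_equal(mono_mass(paste0(a, b)),
                 mono_mass(a) + mono_mass(b) - k[["water_mono"]] - k[["proton"]])
  }
})

test_that("phospho adds exactly its delta and ladders are arithmetic", {
  base <- "RLSSLRASTSKSESSQK"
  m0 <- mono_mass(base)
  sty <- which(strsplit(base, "")[[1]] %in% c("S", "T"))
  masses <- vapply(0:4, function(k) {
    if (k == 0) return(m0)
    mono_mass(modified_peptide(base, data.frame(position = sty[seq_len(k)],
                                                name = "phospho")))
  }, numeric(1))
  expect_equal(diff(masses), rep(79.96633, 4), tolerance = 1e-5)
})

test_that("label deltas are additive, integer in nominal mode, exact otherwise", {
  pep2k <- modified_peptide("DMYDKEYYSVHNK", labeled = c(5, 13))
  expect_identical(label_delta(pep2k, label_scheme()), 16)
  expect_equal(1867.669 - 1851.669, label_delta(pep2k, label_scheme()))
  pep1k <- modified_peptide("DMYDKEYYSVHNK", labeled = 13)
  expect_equal(label_delta(pep1k, label_scheme(mode = "exact")), 8.014199)
  # nominal and exact differ by < 0.05 Da per residue
  sc_n <- label_scheme()
  sc_e <- label_scheme(mode = "exact")
  expect_true(all(abs(sc_n$deltas - sc_e$deltas) < 0.05))
  # two R+10 labels explain a 20 Da pair spacing
  pep2r <- modified_peptide("RVVLGDGVQLPPGDYSTTPGGTLFSTTPGGTR",
                            labeled = c(1, 32))
  expect_identical(label_delta(pep2r, label_scheme()), 20)
  # labeled residue absent from the scheme is an error
  expect_error(label_delta(modified_peptide("AGA", labeled = 2),
                           label_scheme()), "does not define")
})

test_that("SIS and SILAC heavy masses reproduce the printed values", {
  sis <- modified_peptide("DMYDKEYYSVHNK", c(phospho = 7, phospho = 8),
                          labeled = c(10, 13))
  expect_equal(mono_mass(sis, label_scheme()), 1865.670, tolerance = 1e-3)
  heavy <- modified_peptide("DMYDKEYYSVHNK", c(phospho = 7, phospho = 8),
                            labeled = c(5, 13))
  expect_equal(mono_mass(heavy, label_scheme()), 1867.669, tolerance = 1e-3)
  light <- modified_peptide("DMYDKEYYSVHNK", c(phospho = 7, phospho = 8))
  expect_equal(mono_mass(light), 1851.670, tolerance = 1e-3)
})

test_that("fragment ions satisfy length and complementarity contracts", {
  pep <- "RAGGEESQFEMDI"
  ions <- fragment_ions(pep)
  n <- nchar(pep)
  expect_equal(sum(ions$series == "b"), n - 1)
  expect_equal(sum(ions$series == "y"), n - 1)
  b2 <- ions$mz[ions$ion == "b2"]
  expect_equal(b2, 228.146, tolerance = 1e-3)
  # b_i + y_(n-i) = MH+ + proton for every split point
  k <- mass_constants()
  b <- ions$mz[ions$series == "b"]
  y <- rev(ions$mz[ions$series == "y"])
  expect_equal(b + y, rep(mono_mass(pep) + k[["proton"]], n - 1))
  # shortest possible series
  gg <- fragment_ions("GG", series = "b")
  expect_equal(nrow(gg), 1)
  expect_equal(gg$mz, 58.029, tolerance = 1e-3)
  # modifications shift the ions that contain them
  mod <- fragment_ions(modified_peptide(pep, c(phospho = 7)), series = "b")
  plain <- fragment_ions(pep, series = "b")
  expect_equal(mod$mz[7:(n - 1)] - plain$mz[7:(n - 1)],
               rep(79.96633, n - 7), tolerance = 1e-5)
  expect_equal(mod$mz[1:6], plain$mz[1:6])
})

test_that("point mutations shift mass by the residue difference", {
  wt <- "RAGGEESQFEMDI"
  mut <- apply_mutation(wt, 2, "V")
  expect_identical(mut$sequence, "RVGGEESQFEMDI")
  expect_identical(mut$mutation, "A2V")
  expect_equal(mono_mass(mut) - mono_mass(wt), 28.0313, tolerance = 1e-4)
  expect_equal(mono_mass(mut), 1496.669, tolerance = 1e-3)
})

test_that("invalid inputs are rejected with informative errors", {
  expect_error(mono_mass("AGXDE"), "position 3")
  expect_error(modified_peptide("AGA", c(phospho = 1)), "not allowed")
  expect_error(modified_peptide("ASA", c(phospho = 9)), "outside")
  expect_error(modified_peptide("ASA", c(phospho = 2, acetyl = 2)),
               "position 2")
})
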