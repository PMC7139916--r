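test_that("variant counts follow the combinatorics of variable placements", {
  set.seed(51)
  for (i in 1:8) {
    s <- random_sequence(20)
    m <- sum(strsplit(s, "")[[1]] %in% c("S", "T"))
    e <- sample(0:3, 1)
    v <- enumerate_variants(s, variable_mod = "phospho",
                            variable_residues = "ST", max_extra = e)
    expected <- sum(choose(m, 0:min(e, m)))
    # rows collapse by mass; total multiplicity preserves the count
    expect_equal(sum(v$multiplicity), expected)
  }
  # no variable mods: exactly the base + required mods
  v1 <- enumerate_variants("ASATK", required = c(phospho = 2))
  expect_equal(nrow(v1), 1L)
  expect_equal(v1$mods, "phospho@2")
})

test_that("variable-phospho ladders are arithmetic with the phospho delta", {
  v <- enumerate_variants("RLSSLRASTSKSESSQK",
                          required = c(phospho = 3, phospho = 4),
                          variable_mod = "phospho", variable_residues = "ST",
                          max_extra = 3)
  m <- sort(v$mono_mass)
  expect_equal(m[1], 2011.921, tolerance = 1e-3)
  expect_equal(diff(m), rep(79.96633, 3), tolerance = 1e-5)
  expect_equal(v$multiplicity[order(v$mono_mass)], c(1L, 6L, 15L, 20L))
})

test_that("any-of semantics enumerates each non-empty required subset", {
  v <- enumerate_variants("VVLGDGVQLPPGDYSTTPGGTLFSTTPGGTR",
                          required = c(phospho = 17, phospho = 26),
                          required_semantics = "any")
  expect_equal(sort(v$mono_mass), c(3127.498, 3207.465), tolerance = 1e-3)
  # the two singly phosphorylated placements share a mass
  expect_equal(v$multiplicity[which.min(v$mono_mass)], 2L)
})

test_that("label schemes add the heavy channel; unlabelable variants collapse", {
  sc <- label_scheme(c(K = 8, R = 10))
  v <- enumerate_variants("RAGGEESQFEMDI", scheme = sc)
  expect_setequal(v$channel, c("light", "heavy"))
  expect_equal(diff(sort(v$mono_mass)), 10)
  # no K/R at all: heavy is indistinguishable and collapses onto light
  v2 <- enumerate_variants("AGGEESQFEMDI", scheme = sc)
  expect_equal(nrow(v2), 1L)
  expect_equal(v2$channel, "both")
})

test_that("mutation alleles keep the wild type alongside the variant", {
  v <- enumerate_variants("RAGGEESQFEMDI",
                          mutations = list(list(position = 2, to = "V")))
  expect_equal(nrow(v), 2L)
  expect_equal(sort(v$mono_mass), c(1468.637, 1496.669), tolerance = 1e-3)
  expect_setequal(v$mutation[!is.na(v$mutation)], "A2V")
})

test_that("the variant cap rejects explosive configurations", {
  s <- strrep("SA", 40)
  expect_error(enumerate_variants(s, variable_mod = "phospho",
                                  variable_residues = "S", max_extra = 6,
                                  max_variants = 1000),
               "too large")
})

test_that("stored masses recompute bit-for-bit from their peptides", {
  panel <- demo_panel()
  idx <- panel$index
  sc <- label_scheme(c(K = 8, R = 10))
  for (i in seq_len(nrow(idx))) {
    mods <- idx$mods[i]
    md <- if (nzchar(mods)) {
      parts <- strsplit(strsplit(mods, "+", fixed = TRUE)[[1]], "@")
      data.frame(position = as.integer(vapply(parts, `[`, "", 2)),
                 name = vapply(parts, `[`, "", 1))
    } else NULL
    labeled <- if (idx$channel[i] == "heavy") {
      which(strsplit(idx$sequence[i], "")[[1]] %in% c("K", "R"))
    } else integer()
    pep <- modified_peptide(idx$sequence[i], md, labeled = labeled)
    expect_identical(mono_mass(pep, sc), idx$mono_mass[i])
    expect_identical(avg_mass(pep, sc), idx$avg_mass[i])
  }
})

test_that("4EBP1 total assay stores the three validated reference masses", {
  reg <- demo_proteins()[["FourEBP1_region"]]
  a <- build_assay("ebp1", reg, epitope_spec(96, 105), "trypsin",
                   max_missed = 2)
  expect_equal(sort(a$variants$mono_mass),
               c(1312.536, 1468.637, 2138.929), tolerance = 1e-3)
})

test_that("cross-reactive phospho assay produces the four printed masses", {
  reg <- demo_proteins()[["FourEBP1_region"]]
  ep <- epitope_spec(22, 33, required_mods = c(phospho = 24, phospho = 33),
                     semantics = "any")
  a <- build_assay("ebp1p", reg, ep, "trypsin", max_missed = 1)
  expect_true(all(c(3127.498, 3207.465, 3283.599, 3363.566) %in%
                    round(a$variants$mono_mass, 3)))
})

test_that("C-MET assay covers all printed missed-cleavage products", {
  reg <- demo_proteins()[["CMET_region"]]
  ep <- epitope_spec(12, 13, required_mods = c(phospho = 12, phospho = 13))
  a <- build_assay("cmet", reg, ep, "trypsin", max_missed = 2)
  expect_true(all(c("EYYSVHNK", "EYYSVHNKTGAK", "DMYDKEYYSVHNK") %in%
                    a$variants$sequence))
  # the printed average mass of the dually phosphorylated long product is
  # 0.02 Da off the standard average table; monoisotopic pins the variant
  long2p <- a$variants[a$variants$sequence == "DMYDKEYYSVHNK", ]
  expect_equal(long2p$mono_mass, 1851.670, tolerance = 1e-3)
  expect_equal(long2p$avg_mass, oracle_mh("DMYDKEYYSVHNK", 2, "avg"),
               tolerance = 0.05)
})

test_that("a protease that destroys the epitope yields a structured failure", {
  reg <- demo_proteins()[["FourEBP1_region"]]
  err <- tryCatch(
    build_assay("bad", reg, epitope_spec(92, 96), "trypsin", max_missed = 0),
    condition = identity)
  expect_s3_class(err, "maldipanel_no_assay")
  expect_match(conditionMessage(err), "9[23]")
})

test_that("panel compilation is deterministic and reports collisions", {
  cfg <- system.file("extdata", "demo_panel.yaml", package = "maldipanel")
  p1 <- read_panel_config(cfg)
  p2 <- read_panel_config(cfg)
  expect_identical(p1$index, p2$index)
  expect_equal(nrow(p1$collisions), 0L)
  # independent pairwise check: reference masses of different assays are
  # separated by more than the strict linear tolerance
  m <- p1$index$mono_mass
  a <- p1$index$assay_id
  dd <- abs(outer(m, m, "-"))
  cross <- outer(a, a, "!=")
  expect_true(all(dd[cross] > p1$tolerances$linear_da))
  # constructed degenerate panel: shared mass is flagged, compile succeeds
  reg <- demo_proteins()[["FourEBP1_region"]]
  a1 <- build_assay("a1", reg, epitope_spec(96, 105), "trypsin", 1)
  a2 <- build_assay("a2", reg, epitope_spec(96, 105), "trypsin", 1)
  expect_warning(pan <- compile_panel(list(a1, a2)), "collision")
  expect_s3_class(pan, "assay_panel")
  expect_gt(nrow(pan$collisions), 0L)
  expect_error(compile_panel(list(a1, a1)), "duplicate")
})
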