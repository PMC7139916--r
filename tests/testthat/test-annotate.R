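test_that("tolerance tiers gate matching the way the validation data behave", {
  panel <- demo_panel()
  # observed linear-mode masses can sit ~0.3 Da off calculation: outside the
  # strict tier, inside the fallback tier
  pk <- data.frame(mz = c(1312.25, 1468.80), intensity = c(80, 100),
                   snr = c(50, 60))
  ann <- match_spot(pk, panel, mode = "linear")
  expect_equal(ann$assay, "EBP1_TOT")
  m <- ann$matches[order(ann$matches$observed_mz), ]
  # 1312.25 sits ~0.29 Da off calculation (fallback tier only);
  # 1468.80 is within the strict 0.25 Da window
  expect_equal(m$tier, c("fallback", "strict"))
  expect_equal(m$error_da, c(1312.25 - 1312.536, 1468.80 - 1468.637),
               tolerance = 0.01)
  # a strict-only tolerance drops the 0.29 Da peak but keeps the other
  strict <- tolerance_settings(linear_da = 0.25, linear_fallback_da = 0.25)
  ann2 <- match_spot(pk, panel, tol = strict)
  expect_equal(ann2$assay, "EBP1_TOT")
  expect_equal(nrow(ann2$matches), 1L)
  expect_equal(ann2$matches$observed_mz, 1468.80)
  expect_equal(nrow(ann2$unmatched), 1L)
  # no peaks: unassigned with zero explained intensity
  empty <- match_spot(data.frame(mz = numeric(), intensity = numeric()),
                      panel)
  expect_true(is.na(empty$assay))
  expect_equal(empty$explained_fraction, 0)
})

test_that("no match ever exceeds the active tolerance", {
  panel <- demo_panel()
  set.seed(61)
  for (i in 1:5) {
    pk <- data.frame(mz = runif(120, 750, 4200), intensity = runif(120),
                     snr = 5)
    ann <- match_spot(pk, panel, mode = "linear")
    if (nrow(ann$matches)) {
      expect_true(all(abs(ann$matches$error_da) <=
                        panel$tolerances$linear_fallback_da))
    }
    annr <- match_spot(pk, panel, mode = "reflector")
    if (nrow(annr$matches)) {
      expect_true(all(abs(annr$matches$error_ppm) <=
                        panel$tolerances$reflector_ppm + 1e-9))
    }
    # reflector-valid matches are linear-valid below m/z 10,000
    if (nrow(annr$matches)) {
      expect_true(all(abs(annr$matches$error_da) <= 0.25))
    }
  }
})

test_that("simulated spots from every assay decode to the right identity", {
  panel <- demo_panel()
  for (id in names(panel$assays)) {
    sp <- simulate_spot(panel, id, hl_ratio = 1.5, snr = 25,
                        seed = 100 + match(id, names(panel$assays)))
    ann <- match_spot(pick_peaks(subtract_baseline(sp)), panel)
    expect_equal(ann$assay, id)
    expect_gt(ann$explained_fraction, 0.5)
  }
})

test_that("phospho-ladder annotation reports composition and missed level", {
  panel <- demo_panel()
  sp <- simulate_spot(panel, "RPS6_S235_236", hl_ratio = 0, snr = 25,
                      seed = 62)
  ann <- match_spot(pick_peaks(subtract_baseline(sp)), panel)
  lad <- annotate_ladder(ann, panel)
  lad <- lad[lad$channel %in% c("light", "both"), ]
  # phospho count increments along each missed-cleavage series
  for (mc in unique(lad$missed)) {
    ser <- lad[lad$missed == mc, ]
    ser <- ser[order(ser$expected_mz), ]
    expect_equal(ser$n_phospho, seq(2, 1 + nrow(ser)))
    expect_equal(diff(ser$expected_mz), rep(79.96633, nrow(ser) - 1),
                 tolerance = 1e-5)
  }
  expect_error(annotate_ladder(match_spot(data.frame(), panel), panel),
               "unassigned")
})

test_that("acetyl ladders annotate acetyl counts from 42 Da spacing", {
  base <- "KSTGGKAPR"
  v <- enumerate_variants(base, variable_mod = "acetyl",
                          variable_residues = "K", max_extra = 2)
  a <- structure(list(id = "h3", accession = NA, protein_name = NA,
                      site = NA, epitope = epitope_spec(1, 9),
                      protease = "argc", max_missed = 0, scheme = NULL,
                      peptides = NULL, variants = v),
                 class = "assay_definition")
  pan <- compile_panel(list(a))
  pk <- data.frame(mz = sort(v$mono_mass), intensity = c(50, 80, 30),
                   snr = 20)
  ann <- match_spot(pk, pan)
  lad <- annotate_ladder(ann, pan)
  lad <- lad[order(lad$expected_mz), ]
  expect_equal(lad$n_acetyl, 0:2)
  expect_equal(diff(lad$expected_mz), rep(42.010565, 2), tolerance = 1e-5)
})

test_that("SILAC pair finding matches a brute-force search", {
  panel <- demo_panel()
  assay <- panel$assays$RPS6_S235_236
  set.seed(63)
  v <- assay$variants
  light <- v[v$channel == "light", ]
  heavy <- v[v$channel == "heavy", ]
  # random subset of true peaks plus decoys
  present <- sample(c(TRUE, FALSE), nrow(light), replace = TRUE)
  h_present <- sample(c(TRUE, FALSE), nrow(light), replace = TRUE)
  key_l <- sub("\\.light", "", light$variant_id)
  key_h <- sub("\\.heavy", "", heavy$variant_id)
  hmass <- heavy$mono_mass[match(key_l, key_h)]
  pk <- data.frame(
    mz = c(light$mono_mass[present], hmass[h_present], c(900, 1000)),
    intensity = runif(sum(present) + sum(h_present) + 2, 10, 100))
  got <- find_silac_pairs(pk, assay)
  # brute force over every (variant, peak, peak) combination
  tol <- 0.25
  for (i in seq_along(key_l)) {
    li <- which(abs(pk$mz - light$mono_mass[i]) <= tol)
    hi <- which(abs(pk$mz - hmass[i]) <= tol)
    want <- if (length(li) && length(hi)) "pair"
      else if (length(li)) "light_only"
      else if (length(hi)) "heavy_only" else "absent"
    expect_equal(got$status[got$variant_id == key_l[i]], want)
  }
  # printed C-MET SILAC pair spacing: 2 lysines, nominal K+8
  reg <- demo_proteins()[["CMET_region"]]
  cmet <- build_assay("cmet", reg,
                      epitope_spec(12, 13,
                                   required_mods = c(phospho = 12,
                                                     phospho = 13)),
                      "trypsin", max_missed = 1,
                      scheme = label_scheme(c(K = 8, R = 10)))
  pk2 <- data.frame(mz = c(1851.669, 1867.669), intensity = c(40, 80))
  pairs <- find_silac_pairs(pk2, cmet)
  hit <- pairs[pairs$status == "pair", ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$delta, 16)
  # heavy absent: light-only singleton
  single <- find_silac_pairs(data.frame(mz = 1851.669, intensity = 40), cmet)
  expect_true("light_only" %in% single$status)
  expect_false("pair" %in% single$status)
})
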