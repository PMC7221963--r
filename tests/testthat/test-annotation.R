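lib <- tea_compound_library()
cfg0 <- sim_config(seed = 1, precursor_ppm_sd = 0, fragment_mda_sd = 0,
                   n_decoy_peaks = 0)

test_that("library transcription is internally consistent", {
  expect_equal(nrow(lib), 42L)
  # recomputed calc m/z agrees with the printed column on self-consistent
  # rows; the known transcription errata are exactly these peaks
  errata <- c(12, 13, 22, 23, 28, 32, 34, 35)
  expect_equal(lib$peak_no[!lib$calc_consistent], errata)
  expect_equal(lib$calc_mz[lib$calc_consistent],
               lib$printed_calc_mz[lib$calc_consistent])
  expect_equal(lib$rdb, lib$printed_rdb)
  # found ions always within 10 ppm of the recomputed calc
  expect_true(all(abs(ppm_error(lib$printed_found_mz, lib$calc_mz_exact,
                                digits = NA)) < 10))
})

test_that("neutral-loss detection finds the galloyl loss of a galloylhexoside", {
  s <- msms_spectrum(631.0950, c(479.0853, 316.0225), c(30, 100))
  nl <- detect_neutral_losses(s)
  gall <- nl[nl$rule == "galloyl", ]
  expect_equal(nrow(gall), 1L)
  expect_equal(gall$from_mz, 631.0950)
  expect_equal(gall$to_mz, 479.0853)
  expect_equal(gall$delta, 152.0097)
  # sorted by descending origin
  expect_true(!is.unsorted(rev(nl$from_mz)))
})

test_that("neutral-loss chains walk glycosyl residues down to the aglycone", {
  # deoxyhexosyl hexoside: residue masses planted exactly
  hex <- monoisotopic_mass("C6H10O5")
  dhx <- monoisotopic_mass("C6H10O4")
  agly <- deprotonated_mz("C15H10O8", digits = NA)
  s <- msms_spectrum(agly + hex + dhx, c(agly + hex, agly), c(50, 100))
  nl <- detect_neutral_losses(s)
  expect_true(any(nl$rule == "deoxyhexose" & abs(nl$from_mz - s$precursor_mz) < 1e-9))
  expect_true(any(nl$rule == "hexose" & abs(nl$to_mz - agly) < 1e-9))
  # a single peak equal to the precursor yields no assignments
  s1 <- msms_spectrum(289.0718, 289.0718, 100)
  expect_equal(nrow(detect_neutral_losses(s1)), 0L)
  expect_error(detect_neutral_losses(s1, rules = neutral_loss_rules()[0, ]),
               "empty rule set")
})

test_that("radical-aglycone dominance localizes the sugar at 3-O", {
  s <- msms_spectrum(463.0887, c(300.0290, 301.0367), c(100, 40))
  ag <- identify_aglycone(s)
  expect_equal(ag$aglycone, "quercetin")
  expect_equal(ag$evidence, "3-O")
  # even-electron ion only: aglycone known, position indeterminate
  s2 <- msms_spectrum(479.0831, 317.0303, 100)
  ag2 <- identify_aglycone(s2)
  expect_equal(ag2$aglycone, "myricetin")
  expect_equal(ag2$evidence, "indeterminate")
  # intensity tie is not dominance
  s3 <- msms_spectrum(463.0887, c(300.0290, 301.0367), c(70, 70))
  expect_equal(identify_aglycone(s3)$evidence, "indeterminate")
  expect_null(identify_aglycone(msms_spectrum(300, c(100.1, 120.2), 1)))
})

test_that("cross-ring losses diagnose C-glycosides, whole residues do not", {
  s19 <- msms_spectrum(563.1418,
                       c(503.1225, 473.1113, 443.1004, 383.0782),
                       c(40, 60, 100, 20))
  expect_true(detect_c_glycoside(s19)$is_c_glycoside)
  expect_equal(nrow(detect_c_glycoside(s19)$evidence), 3L)
  s28 <- msms_spectrum(463.0887, c(301.0367, 300.0290), c(40, 100))
  expect_false(detect_c_glycoside(s28)$is_c_glycoside)
  expect_false(detect_c_glycoside(
    msms_spectrum(563.1418, numeric(0), numeric(0)))$is_c_glycoside)
})

test_that("the class cascade reproduces reference calls", {
  # catechin-type fragmentation: HRF/RDA/BFF ions, no galloylation
  s_cat <- msms_spectrum(289.0722,
                         c(245.0825, 203.0719, 151.0407, 137.0251, 125.0248,
                           109.0300),
                         c(30, 23, 5, 10, 7, 100))
  a <- classify_compound(s_cat)
  expect_equal(a$compound_class, "flavan-3-ol")
  # coumaroylated quercetin triglycoside: acyl loss pair + radical aglycone
  s36 <- msms_spectrum(917.2361,
                       c(771.2075, 753.1915, 301.0355, 300.0277),
                       c(35, 20, 30, 100))
  a36 <- classify_compound(s36)
  expect_equal(a36$compound_class, "acylated flavonol glycoside")
  expect_equal(a36$aglycone, "quercetin")
  expect_equal(a36$position_evidence, "3-O")
  # unmatched noise peaks give no class and explain nothing
  s_noise <- msms_spectrum(400.1, c(111.1111, 222.2222, 333.3333), 1)
  a_noise <- classify_compound(s_noise)
  expect_equal(a_noise$compound_class, "unclassified")
  expect_equal(a_noise$score, 0)
  expect_error(classify_compound(msms_spectrum(400, numeric(0), numeric(0))),
               "empty")
})

test_that("zero-noise simulations of the whole library recover every class", {
  res <- simulate_and_classify(lib, cfg0)
  expect_equal(unname(res["class", ]), lib$compound_class)
  fg <- lib$compound_class %in%
    c("flavonol O-glycoside", "acylated flavonol glycoside")
  expect_equal(unname(res["aglycone", fg]), lib$aglycone[fg])
})

test_that("C-glycoside and O-glycoside calls are mutually exclusive", {
  for (i in seq_len(nrow(lib))) {
    s <- simulate_spectrum(lib[i, ], cfg0)
    a <- classify_compound(s, precursor_formula = lib$formula[i])
    if (a$compound_class == "flavonol O-glycoside") {
      expect_false(detect_c_glycoside(s)$is_c_glycoside)
    }
    if (a$compound_class == "flavone C-glycoside") {
      expect_true(detect_c_glycoside(s)$is_c_glycoside)
    }
  }
})

test_that("class calls are invariant under intensity rescaling", {
  for (i in c(9, 11, 19, 21, 36)) {
    s <- simulate_spectrum(lib[i, ], cfg0)
    s_big <- msms_spectrum(s$precursor_mz, s$peaks$mz,
                           s$peaks$intensity * 1e4, rt = s$rt)
    expect_equal(classify_compound(s_big)$compound_class,
                 classify_compound(s)$compound_class)
  }
})

test_that("loss chains respect tolerance and never reuse a peak", {
  for (i in c(4, 20, 24, 36, 39)) {
    s <- simulate_spectrum(lib[i, ], cfg0)
    a <- classify_compound(s)
    ch <- a$loss_chain
    if (is.null(ch)) next
    expect_true(all(abs(ch$delta - ch$exact_mass) <= 0.02))
    expect_equal(anyDuplicated(ch$to_mz), 0L)
    expect_gte(a$score, 0)
    expect_lte(a$score, 1)
  }
})

test_that("library annotation matches simulated spectra and keeps strays", {
  spectra <- lapply(seq_len(nrow(lib)), function(i)
    simulate_spectrum(lib[i, ], cfg0))
  ann <- annotate_library(spectra, lib)
  expect_equal(ann$matched_peak_no, lib$peak_no)
  expect_true(all(ann$ppm == 0))
  expect_equal(ann$class, lib$compound_class)
  # a precursor far outside the library stays unmatched but classified
  stray <- msms_spectrum(5000, c(301.0354, 300.0276), c(40, 100))
  ann2 <- annotate_library(list(stray), lib)
  expect_true(is.na(ann2$matched_name))
  expect_false(is.na(ann2$class))
})

test_that("class relative abundances are percentages summing to 100", {
  one <- class_relative_abundance("catechins", 5)
  expect_equal(one$percent, 100)
  two <- class_relative_abundance(c("a", "b"), c(3, 1))
  expect_equal(two$percent[two$class == "a"], 75)
  expect_equal(two$percent[two$class == "b"], 25)
  expect_error(class_relative_abundance(c("a", "b"), c(0, 0)), "zero total")
  # planted composition: catechins at 89.9% of summed abundance
  classes <- c(rep("catechins", 5), "saccharide", "flavonol glycoside")
  ab <- c(rep(89.9 / 5, 5), 6, 4.1)
  cra <- class_relative_abundance(classes, ab)
  expect_equal(cra$percent[cra$class == "catechins"], 89.9, tolerance = 1e-9)
  expect_equal(sum(cra$percent), 100, tolerance = 1e-9)
})
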