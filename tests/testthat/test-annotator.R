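lib <- enumerate_candidates("C10H16", default_rules())
fixture <- load_fixture("limonene_metabolites")
fix_features <- data.frame(feature_id = fixture$id, mz = fixture$mz,
                           rt = fixture$rt, stringsAsFactors = FALSE)

test_that("MS1 matching finds the documented candidates and rejects decoys", {
  hits <- match_features(data.frame(feature_id = "f1", mz = 375.1304,
                                    rt = 1.89),
                         lib, tol_ppm = 10)
  expect_true("limonene+COOH+OH+OH glucuronide" %in% hits$label)
  expect_equal(best_hits(hits)$label, "limonene+COOH+OH+OH glucuronide")

  # zero tolerance only matches exact masses
  exact <- match_features(data.frame(feature_id = "f2", mz = lib$mz_mh[1],
                                     rt = 1), lib, tol_ppm = 0)
  expect_true(nrow(exact) >= 1L)
  off <- match_features(data.frame(feature_id = "f3", mz = lib$mz_mh[1] + 1e-4,
                                   rt = 1), lib, tol_ppm = 0)
  expect_equal(nrow(off), 0L)
  expect_equal(attr(off, "unmatched"), "f3")

  # a decoy far from every library mass finds no candidate
  expect_gt(min(abs(ppm_error(lib$mz_mh, 500.0000))), 10)
  decoy <- match_features(data.frame(feature_id = "d", mz = 500.0000, rt = 1),
                          lib, tol_ppm = 10)
  expect_equal(nrow(decoy), 0L)
})

test_that("annotation is monotone in the mass tolerance", {
  h2 <- match_features(fix_features, lib, tol_ppm = 2)
  h10 <- match_features(fix_features, lib, tol_ppm = 10)
  key <- function(h) paste(h$feature_id, h$label)
  expect_true(all(key(h2) %in% key(h10)))
  expect_true(all(abs(h2$ppm_error) <= 2))
  expect_true(all(abs(h10$ppm_error) <= 10))
})

test_that("diagnostic fragments corroborate conjugate classes", {
  spectra <- fixture_spectra(fixture)
  top <- best_hits(match_features(fix_features, lib, tol_ppm = 10))
  top <- assign_fragments(top, spectra, tol_mz = 0.005)

  m10 <- top[top$feature_id == "M10", ]
  expect_gte(m10$n_diagnostics, 5L)
  expect_true(m10$complement_matched)   # 341.1242 - 176.0321 ~ 165.0923

  m6 <- top[top$feature_id == "M6", ]
  expect_true(grepl("SO3", m6$diagnostics_matched))
  expect_true(m6$complement_matched)    # 245.0489 - 79.9568 ~ 165.0919

  # no conjugate, or no spectrum -> no fragment evidence
  plain <- assign_fragments(
    best_hits(match_features(
      data.frame(feature_id = "p", mz = ion_mz("C10H14O2"), rt = 1), lib)),
    spectra)
  expect_equal(plain$n_diagnostics, 0L)
  expect_false(plain$complement_matched)

  # a diagnostic heavier than the precursor is never matched
  heavy <- data.frame(mz = 175.0248, intensity_rel = 100)
  small_hit <- top[top$feature_id == "M6", ]
  small_hit$theo_mz <- 120  # pretend a light precursor
  res <- assign_fragments(small_hit, list(M6 = heavy))
  expect_equal(res$n_diagnostics, 0L)
  expect_true(all(top$n_diagnostics == 0 |
                    vapply(seq_len(nrow(top)), function(i) {
                      d <- strsplit(top$diagnostics_matched[i], ";")[[1]]
                      all(vapply(d, anion_mz, numeric(1)) <=
                            top$theo_mz[i] + 0.005)
                    }, logical(1))))
})

test_that("control-group presence excludes endogenous features", {
  meta <- data.frame(
    sample_id = paste0("s", 1:8),
    group = rep(c("NL", "HL", "HL0.1", "HL0.8"), each = 2),
    tissue = "urine", creatinine = 1, stringsAsFactors = FALSE)
  feats <- data.frame(feature_id = c("endog", "metab"),
                      mz = c(300, 301), rt = c(2, 3))
  feats[paste0("s", 1:8)] <- 0
  feats[feats$feature_id == "endog", paste0("s", 3:8)] <- 1000 # HL + dosed
  feats[feats$feature_id == "metab", paste0("s", 5:8)] <- 1000 # dosed only
  hits <- data.frame(feature_id = c("endog", "metab"),
                     stringsAsFactors = FALSE)
  out <- control_exclusion(hits, feats, meta, control_groups = c("NL", "HL"),
                           threshold = 0.05)
  expect_true(out$control_present[out$feature_id == "endog"])
  expect_false(out$control_present[out$feature_id == "metab"])
  expect_error(control_exclusion(hits, feats, meta,
                                 control_groups = "missing"), "control")
})

test_that("annotation confidence levels follow the evidence", {
  spectra <- fixture_spectra(fixture)
  top <- best_hits(match_features(fix_features, lib, tol_ppm = 10))
  top <- msi_level(assign_fragments(top, spectra))
  expect_equal(top$msi_level[top$feature_id == "M10"], "2")
  expect_equal(top$msi_level[top$feature_id == "M7-III"], "3") # MS/MS n.d.
  low_iso <- top[1, ]; low_iso$isotope_score <- 0
  expect_equal(msi_level(low_iso)$msi_level, "rejected")
})

test_that("isotope scoring is advisory and fills in where patterns exist", {
  top <- best_hits(match_features(fix_features[1, , drop = FALSE], lib))
  pat <- isotope_pattern(top$formula[1])
  scored <- score_isotopes(top, setNames(list(pat), top$feature_id[1]))
  expect_equal(scored$isotope_score, 1)
  unscored <- score_isotopes(top, list())
  expect_true(is.na(unscored$isotope_score))
})

test_that("isomer suffixes follow retention-time order", {
  top <- best_hits(match_features(fix_features, lib, tol_ppm = 10))
  top <- assign_isomer_suffixes(top)
  m4 <- top[top$feature_id %in% c("M4-I", "M4-II", "M4-III"), ]
  m4 <- m4[order(m4$rt), ]
  expect_equal(m4$display_label,
               paste("limonene+COOH+OH+H2 glucuronide", c("I", "II", "III")))
  # singleton labels stay unsuffixed
  expect_equal(top$display_label[top$feature_id == "M6"],
               "limonene+COOH sulfate")
})
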