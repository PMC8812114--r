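ev <- function(ppm = 3, rt = NA_real_, msig = NA_real_, score = NA_real_,
               recorded = FALSE, blank = NA, cv = NA) {
  list(ppm_error = ppm, rt_dev_min = rt, msigma = msig, msms_score = score,
       msms_recorded = recorded, blank_pass = blank, cv_pass = cv)
}

feature_for <- function(entry, adduct = "[M+H]+", ppm_off = 3, rt = 120,
                        id = "F001", mode = "+", intensity = c(9e4, 1e5, 1.1e5),
                        with_iso = TRUE, msms_recorded = FALSE) {
  mz <- adduct_mz(entry$formula, adduct) * (1 + ppm_off * 1e-6)
  df <- data.frame(feature_id = id, ion_mode = mode, mz = mz, rt = rt,
                   blank_intensity = 0, msms_recorded = msms_recorded,
                   stringsAsFactors = FALSE)
  for (j in seq_along(intensity)) df[[paste0("intensity_", j)]] <- intensity[j]
  tab <- feature_table(df)
  if (with_iso) {
    pat <- isotope_pattern(entry$formula)
    delta <- adduct_table()$delta_mass[match(adduct, adduct_table()$adduct)]
    tab$isotope_peaks <- list(as_isotope_pattern(pat$mz + delta, pat$rel_intensity))
  }
  tab
}

test_that("match_feature picks the best adduct and respects the ppm gate", {
  susp <- suspect_entry("atenolol", parse_formula("C14H22N2O3"), "AL+",
                        expected_rt = 117, adducts = "[M+H]+")
  tab <- feature_for(susp, ppm_off = 3, rt = 120)
  m <- match_feature(tab$mz[1], tab$rt[1], "+", susp,
                     isotope_peaks = tab$isotope_peaks[[1]],
                     intensities = c(9e4, 1e5, 1.1e5), blank_intensity = 0)
  expect_equal(m$ppm_error, 3, tolerance = 1e-6)
  expect_equal(m$rt_dev_min, 0.05, tolerance = 1e-9)
  expect_lt(m$msigma, 1)
  expect_true(m$blank_pass)

  far <- match_feature(adduct_mz(susp$formula) * (1 + 15e-6), 120, "+", susp)
  expect_null(far)

  # suspect without expected RT: rt_dev absent
  al <- suspect_entry("cand", parse_formula("C14H22N2O3"), "AL")
  m2 <- match_feature(adduct_mz(al$formula), 120, "+", al)
  expect_true(is.na(m2$rt_dev_min))

  # wrong ion mode: no compatible adduct
  expect_null(match_feature(adduct_mz(susp$formula), 120, "-", susp))
})

test_that("TAQ code tiers every criterion in fixed order", {
  # strict mass/RT/isotope, MS/MS recorded without a library match, filters pass
  expect_identical(taq_code(ev(3, 0.05, 20, recorded = TRUE,
                               blank = TRUE, cv = TRUE)), "222122")
  expect_identical(taq_code(ev(3, 0.05, 20, score = 850, recorded = TRUE,
                               blank = TRUE, cv = TRUE)), "222222")
  expect_identical(taq_code(ev(8, NA, 80, recorded = FALSE)), "1-10--")
  # loose tiers and fails
  expect_identical(taq_code(ev(-7, 0.15, 150, score = 400, recorded = TRUE,
                               blank = FALSE, cv = TRUE)), "110102")
  expect_identical(taq_code(ev(12, 0.25, NA, recorded = FALSE)), "00-0--")
})

test_that("confidence levels follow the TAQ/list-class rules", {
  # spiked standard: strict mass+RT+isotope, no library MS/MS -> 2b
  expect_identical(assign_level("222122", "AL+"), "2b")
  expect_identical(assign_level("221122", "AL+"), "2b")
  # with a qualifying library match -> 1
  expect_identical(assign_level("222222", "AL+"), "1")
  # spectral library + MS/MS score >= 600 -> 2a
  expect_identical(assign_level("2-0222", "SL"), "2a")
  # analyte list, formula-level evidence, MS/MS recorded -> 4*
  expect_identical(assign_level("2-1122", "AL"), "4*")
  expect_identical(assign_level("2-1022", "AL"), "4")
  # mass-only evidence -> 5
  expect_identical(assign_level("2-0022", "AL"), "5")
  # SL without a qualifying match falls through to the formula rules
  expect_identical(assign_level("221122", "SL"), "4*")
  # AL+ failing RT falls through too
  expect_identical(assign_level("202122", "AL+"), "4*")
})

test_that("upgrading any single TAQ symbol never lowers the level", {
  upgrade <- list("0" = c("1", "2"), "1" = "2", "-" = "2")
  set.seed(5)
  syms <- c("0", "1", "2", "-")
  for (cls in c("SL", "AL", "AL+")) {
    for (i in 1:60) {
      taq <- paste0(sample(syms, 6, replace = TRUE), collapse = "")
      base_rank <- level_rank(assign_level(taq, cls))
      for (pos in 1:6) {
        cur <- substr(taq, pos, pos)
        for (up in upgrade[[cur]]) {
          taq2 <- taq
          substr(taq2, pos, pos) <- up
          expect_lte(level_rank(assign_level(taq2, cls)), base_rank,
                     label = sprintf("%s[%s] pos %d %s->%s", taq, cls, pos, cur, up))
        }
      }
    }
  }
})

test_that("annotate_table selects the highest-level annotation as primary", {
  comp <- parse_formula("C8H10N4O2")
  sl <- suspect_list("library", list(
    suspect_entry("caffeine", comp, "SL", adducts = "[M+H]+",
                  library_spectra = list(msms_spectrum(
                    c(110.0712, 138.0662), c(300, 900),
                    precursor_mz = adduct_mz(comp), ion_mode = "+")))), rank = 1L)
  al <- suspect_list("cecscreen", list(
    suspect_entry("cec_a", comp, "AL", adducts = "[M+H]+"),
    suspect_entry("cec_b", comp, "AL", adducts = "[M+H]+")), rank = 2L)

  tab <- feature_for(sl$entries[[1]], msms_recorded = TRUE)
  tab$msms <- list(msms_spectrum(c(110.0712, 138.0662), c(310, 880),
                                 precursor_mz = adduct_mz(comp), ion_mode = "+"))
  ann <- annotate_table(tab, list(sl, al))
  expect_equal(nrow(ann), 3)  # caffeine + two isomer candidates
  prim <- ann[ann$primary_flag, ]
  expect_equal(nrow(prim), 1)
  expect_identical(prim$suspect, "caffeine")
  expect_identical(prim$level, "2a")
  expect_true(all(ann$level[ann$suspect != "caffeine"] == "4*"))
  expect_equal(ann$isomer_count[ann$suspect == "cec_a"], 2)

  # unannotated feature -> level-5 record
  lone <- feature_table(data.frame(feature_id = "F999", ion_mode = "+",
                                   mz = 777.777, rt = 10, intensity_1 = 50))
  ann5 <- annotate_table(lone, list(sl, al))
  expect_equal(nrow(ann5), 1)
  expect_identical(ann5$level, "5")
  expect_true(ann5$primary_flag)
})

test_that("primary selection is deterministic under entry permutation", {
  comp <- parse_formula("C9H13NO3")
  mk <- function(names_) suspect_list("cec", lapply(names_, function(nm)
    suspect_entry(nm, comp, "AL", adducts = "[M+H]+")), rank = 1L)
  tab <- feature_for(suspect_entry("x", comp, "AL"), msms_recorded = TRUE)
  a1 <- annotate_table(tab, list(mk(c("beta", "alpha", "gamma"))))
  a2 <- annotate_table(tab, list(mk(c("gamma", "beta", "alpha"))))
  expect_identical(a1$suspect[a1$primary_flag], a2$suspect[a2$primary_flag])
  expect_identical(a1$suspect[a1$primary_flag], "alpha")  # name tie-break
})

test_that("tightening thresholds never increases the annotation count", {
  set.seed(77)
  comp <- parse_formula("C16H25NO2")
  entries <- list(suspect_entry("target", comp, "AL+", expected_rt = 300,
                                adducts = "[M+H]+"))
  hier <- list(suspect_list("std", entries, rank = 1L))
  count_ann <- function(tab, th) {
    a <- annotate_table(tab, hier, thresholds = th)
    sum(!is.na(a$suspect))
  }
  for (i in 1:10) {
    n <- 15
    mz0 <- adduct_mz(comp)
    df <- data.frame(feature_id = sprintf("F%02d", 1:n), ion_mode = "+",
                     mz = mz0 * (1 + rnorm(n, 0, 8e-6)),
                     rt = 300 + rnorm(n, 0, 10),
                     intensity_1 = runif(n, 1e3, 1e5))
    tab <- feature_table(df)
    loose <- annotation_thresholds()
    tight <- loose; tight$ppm <- 5
    expect_lte(count_ann(tab, tight), count_ann(tab, loose))
  }
})

test_that("isomer counting matches formula multiplicity", {
  comp <- parse_formula("C9H13NO3")
  lst <- suspect_list("cec", list(
    suspect_entry("a", comp, "AL"),
    suspect_entry("b", comp, "AL"),
    suspect_entry("c", comp, "AL"),
    suspect_entry("unique", parse_formula("C10H14N2"), "AL")), rank = 1L)
  expect_equal(count_isomers(lst$entries[[1]], lst), 3)
  expect_equal(count_isomers(lst$entries[[4]], lst), 1)
  expect_error(count_isomers(lst$entries[[1]], suspect_list("empty", list())),
               "empty")
})

test_that("box-1 candidate reduction reproduces the published six-feature replay", {
  rows <- list(  # feature: isomers, box1..box4, unpredicted
    f1522 = c(15, 3, 4, 1, 7, 0),
    f2701 = c(10, 0, 5, 4, 1, 0),
    f3837 = c(8, 6, 2, 0, 0, 0),
    f6602 = c(10, 4, 3, 0, 1, 2),
    f3367 = c(22, 9, 12, 0, 1, 0),
    f4255 = c(18, 4, 14, 0, 0, 0)
  )
  reductions <- vapply(rows, function(r) {
    set <- make_isomer_set("CxHy", r[1], r[2], r[3], r[4], r[5], r[6])
    reduce_candidates(set)$reduction_fraction
  }, numeric(1))
  expect_equal(unname(reductions["f3837"]), 0.25, tolerance = 1e-12)
  expect_equal(unname(reductions["f2701"]), 1.0, tolerance = 1e-12)
  expect_equal(mean(reductions), 0.63, tolerance = 0.005 / 0.63)
  expect_equal(sd(reductions), 0.25, tolerance = 0.005 / 0.25)

  # all box 1: nothing removed
  allb1 <- make_isomer_set("CxHy", 4, n_box1 = 4)
  expect_equal(reduce_candidates(allb1)$reduction_fraction, 0)
  # all box 4: undefined, flagged for reconsideration
  allb4 <- make_isomer_set("CxHy", 3, n_box4 = 3)
  r4 <- reduce_candidates(allb4)
  expect_true(r4$undefined)
  expect_true(is.na(r4$reduction_fraction))
  expect_equal(nrow(r4$reconsider), 3)
})

test_that("level boosting needs box 1 and at least two matched fragments", {
  spec <- msms_spectrum(c(120.0808, 160.5, 250.9), c(1000, 800, 50), ion_mode = "+")
  good <- fragment_match(spec, c(120.0809, 160.5003))
  expect_equal(good$n_matched_peaks, 2)
  none <- fragment_match(spec, 119.9)
  expect_identical(boost_level("4*", 1, good), "3")
  expect_identical(boost_level("4*", 3, good), "4*")
  expect_identical(boost_level("4*", 1, none), "4*")
  expect_identical(boost_level("4*", NA, good), "4*")
  expect_error(boost_level("4", 1, good), "level 4\\*")
})
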