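test_that("formula parsing handles plain, halogenated and labelled formulas", {
  w <- parse_formula("H2O")
  expect_equal(unclass(w)[c("H", "O")], c(H = 2L, O = 1L))

  pfoa <- parse_formula("C8HF15O2")
  expect_equal(unclass(pfoa)[c("C", "H", "F", "O")],
               c(C = 8L, H = 1L, F = 15L, O = 2L))

  dbb <- parse_formula("C6H4Br2")
  expect_equal(unclass(dbb)[["Br"]], 2L)

  cipro_d8 <- parse_formula("C17H10D8FN3O3")
  expect_equal(unclass(cipro_d8)[["D"]], 8L)
  labelled <- parse_formula("C37H69D3N2O12[13C]")
  expect_equal(unclass(labelled)[["[13C]"]], 1L)

  expect_error(parse_formula("C2Xx4"), "unknown element")
  expect_error(parse_formula(""), "empty")
})

test_that("formula serialization round-trips in canonical Hill order", {
  for (f in c("H2O", "C8HF15O2", "C6H4Br2", "C17H10D8FN3O3",
              "C37H69D3N2O12[13C]", "C12H22O11", "ClH")) {
    canon <- formula_string(parse_formula(f))
    expect_identical(formula_string(parse_formula(canon)), canon)
  }
  # Hill order: C (and 13C label), H (and D), then alphabetical
  expect_identical(formula_string(parse_formula("O2F15HC8")), "C8HF15O2")
})

test_that("monoisotopic and average masses match reference values", {
  w <- parse_formula("H2O")
  expect_equal(formula_mass(w, "monoisotopic"), 18.01056, tolerance = 1e-4 / 18)
  pfoa <- parse_formula("C8HF15O2")
  expect_equal(formula_mass(pfoa, "average"), 414.07, tolerance = 0.01 / 414)
  expect_error(formula_mass(element_composition(integer(0))), "empty")
})

test_that("adduct m/z uses the proton mass for singly charged adducts", {
  w <- parse_formula("H2O")
  expect_equal(adduct_mz(w, "[M+H]+"), 18.010565 + 1.007276, tolerance = 1e-4 / 19)
  expect_equal(adduct_mz(w, "[M-H]-"), 18.010565 - 1.007276, tolerance = 1e-4 / 17)
  expect_error(adduct_mz(w, "[M+Zz]"), "unknown adduct")
})

test_that("ppm_error is signed, exact and antisymmetric around theoretical mass", {
  expect_equal(ppm_error(500.0025, 500.0000), 5.0, tolerance = 1e-6)
  expect_equal(ppm_error(500.0000, 500.0000), 0.0)
  expect_equal(ppm_error(413.97369 * (1 - 2e-6), 413.97369), -2.0, tolerance = 1e-6)
  # antisymmetry: equal residuals on either side give opposite signs
  th <- 250.1234
  expect_equal(ppm_error(th + 1e-3, th), -ppm_error(th - 1e-3, th))
  expect_error(ppm_error(100, 0), "must be > 0")
})

test_that("isotope pattern of carbon and of dibromobenzene match hand values", {
  pc <- isotope_pattern(parse_formula("C1"))
  expect_equal(nrow(pc), 2)
  expect_equal(pc$mz[1], 12.0, tolerance = 1e-6)
  expect_equal(pc$rel_intensity, c(1, 0.0107 / 0.9893), tolerance = 1e-4)

  pb <- isotope_pattern(parse_formula("C6H4Br2"))
  dom <- pb[order(-pb$rel_intensity), ][1:3, ]
  dom <- dom[order(dom$mz), ]
  expect_equal(dom$rel_intensity, c(0.514, 1.000, 0.486), tolerance = 5e-3)
  # base peak is M+2, not the monoisotopic peak
  expect_false(monoisotopic_is_base(pb))
  expect_true(monoisotopic_is_base(pc))
})

test_that("isotope pattern equals brute-force isotopologue enumeration", {
  fixed <- list(list(C = 3, H = 6, O = 3), list(C = 2, Cl = 2, H = 2),
                list(Br = 2, C = 4), list(S = 2, O = 4), list(N = 4, H = 8))
  set.seed(42)
  cases <- c(fixed, replicate(12, random_small_formula(), simplify = FALSE))
  for (counts in cases) {
    got <- isotope_pattern(element_composition(unlist(counts)))
    want <- oracle_isotope_pattern(counts)
    expect_equal(nrow(got), nrow(want),
                 info = paste(names(counts), unlist(counts), collapse = " "))
    expect_lt(max(abs(got$rel_intensity - want$rel_intensity)), 1e-9)
    expect_lt(max(abs(got$mz - want$mz)), 1e-9)
  }
})

test_that("every isotope pattern has one base peak and positive intensities", {
  set.seed(7)
  for (i in 1:10) {
    counts <- random_small_formula()
    p <- isotope_pattern(element_composition(unlist(counts)))
    expect_equal(sum(p$rel_intensity == 1), 1)
    expect_true(all(p$rel_intensity > 0 & p$rel_intensity <= 1))
    expect_true(!is.unsorted(p$mz))
    # monoisotopic mass bounds every isotopologue mass
    expect_true(all(p$mz >= formula_mass(element_composition(unlist(counts)),
                                         "monoisotopic") - 1e-6))
  }
})

test_that("msigma is zero for identity, matches hand computations, grows with residual", {
  p <- isotope_pattern(parse_formula("C10H14N2"))
  expect_equal(msigma(p, p), 0)

  theo <- as_isotope_pattern(c(100, 101), c(1, 0.5))
  meas <- as_isotope_pattern(c(100, 101), c(1, 0.55))
  expect_equal(msigma(meas, theo), 1000 * sqrt((0^2 + 0.05^2) / 2), tolerance = 1e-4)
  expect_equal(msigma(meas, theo), 35.36, tolerance = 0.01 / 35)

  missing2nd <- as_isotope_pattern(100, 1)
  expect_equal(msigma(missing2nd, theo), 1000 * sqrt((0^2 + 0.5^2) / 2), tolerance = 1e-4)
  expect_equal(msigma(missing2nd, theo), 353.6, tolerance = 0.1 / 353)

  # strictly increasing in a single matched residual
  scores <- vapply(c(0.5, 0.55, 0.6, 0.7, 0.9), function(x)
    msigma(as_isotope_pattern(c(100, 101), c(1, x)), theo), numeric(1))
  expect_true(all(diff(scores) > 0))
  expect_error(msigma(meas, theo[0, ]), "no theoretical peaks")
})

test_that("multihalogenated formulas never have the monoisotopic base peak", {
  set.seed(11)
  for (i in 1:12) {
    nbr <- sample(2:4, 1)
    counts <- c(C = sample(1:10, 1), H = sample(0:8, 1), Br = nbr)
    counts <- counts[counts > 0]
    p <- isotope_pattern(element_composition(counts))
    expect_false(monoisotopic_is_base(p),
                 label = sprintf("monoisotopic_is_base(%s)",
                                 formula_string(element_composition(counts))))
  }
  # single-peak pattern is trivially monoisotopic-based
  expect_true(monoisotopic_is_base(as_isotope_pattern(100, 1)))
})

test_that("micromolar/mass-concentration conversion reproduces the PFOA case", {
  pfoa <- parse_formula("C8HF15O2")
  expect_equal(micromolar_to_mass_conc(1.1, pfoa), 455, tolerance = 1 / 455)
  expect_equal(micromolar_to_mass_conc(0, pfoa), 0)
  expect_equal(mass_conc_to_micromolar(micromolar_to_mass_conc(1.1, pfoa), pfoa),
               1.1, tolerance = 1e-9)
  expect_error(micromolar_to_mass_conc(1, element_composition(integer(0))), "empty")
})
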