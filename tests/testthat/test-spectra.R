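make_spec <- function(mz, int, mode = "+") msms_spectrum(mz, int, ion_mode = mode)

test_that("relative-intensity filter keeps peaks strictly above the threshold", {
  s <- make_spec(c(100, 110, 120), c(1000, 9, 11))
  f <- relative_intensity_filter(s, 0.01)
  expect_equal(f$peaks$mz, c(100, 120))  # 9 counts = 0.9% of base: dropped
  expect_equal(relative_intensity_filter(s, 0)$peaks, s$peaks)
  allsame <- make_spec(c(1, 2, 3), c(5, 5, 5))
  expect_equal(nrow(relative_intensity_filter(allsame, 0.01)$peaks), 3)
  # idempotence
  expect_equal(relative_intensity_filter(f, 0.01)$peaks, f$peaks)
  expect_error(relative_intensity_filter(s, 1), "rel_threshold")
})

test_that("spectral match score: identity 1000, disjoint 0, hand-computed cosine", {
  s <- make_spec(c(100, 150.5, 200), c(10, 40, 5))
  expect_equal(spectral_match_score(s, s), 1000)

  a <- make_spec(c(100, 200), c(5, 5))
  b <- make_spec(c(300, 400), c(5, 5))
  expect_equal(spectral_match_score(a, b), 0)

  # sqrt intensities: (2,1) vs (1,2) -> cos = 4/5
  q <- make_spec(c(100, 200), c(4, 1))
  l <- make_spec(c(100, 200), c(1, 4))
  expect_equal(spectral_match_score(q, l), 800, tolerance = 0.5 / 800)

  expect_error(spectral_match_score(q, make_spec(c(100), 1, mode = "-")),
               "ion-mode mismatch")
})

test_that("spectral match score is symmetric, scale-invariant and order-invariant", {
  set.seed(3)
  for (i in 1:8) {
    n1 <- sample(3:10, 1); n2 <- sample(3:10, 1)
    q <- make_spec(runif(n1, 50, 500), runif(n1, 1, 1000))
    l <- make_spec(runif(n2, 50, 500), runif(n2, 1, 1000))
    s <- spectral_match_score(q, l)
    expect_gte(s, 0); expect_lte(s, 1000)
    expect_equal(spectral_match_score(l, q), s, tolerance = 1e-12)
    scaled <- msms_spectrum(l$peaks$mz, l$peaks$intensity * 37.5, ion_mode = "+")
    expect_equal(spectral_match_score(q, scaled), s, tolerance = 1e-12)
    perm <- sample(n2)
    shuffled <- msms_spectrum(l$peaks$mz[perm], l$peaks$intensity[perm], ion_mode = "+")
    expect_equal(spectral_match_score(q, shuffled), s, tolerance = 1e-12)
  }
})

test_that("fragment matching respects the 5 ppm tolerance and injectivity", {
  s <- make_spec(150.0000, 100)
  hit <- fragment_match(s, 150.0005)           # 3.3 ppm
  expect_equal(hit$n_matched_peaks, 1)
  expect_equal(hit$matched_pairs$ppm, ppm_error(150.0000, 150.0005), tolerance = 1e-9)
  miss <- fragment_match(s, 150.0010)          # 6.7 ppm
  expect_equal(miss$n_matched_peaks, 0)

  two <- make_spec(c(150.0000, 250.0000), c(100, 50))
  r <- fragment_match(two, c(150.0003, 250.0004))
  expect_equal(r$n_matched_peaks, 2)
  expect_equal(anyDuplicated(r$matched_pairs$fragment_mz), 0)
  expect_equal(r$matched_intensity_fraction, 1)

  # two fragments near one peak: injective, only one match
  r1 <- fragment_match(s, c(150.0003, 150.0004))
  expect_equal(r1$n_matched_peaks, 1)
  expect_error(fragment_match(s, numeric(0)), "empty")
})

test_that("adding candidate fragments never decreases the match count", {
  set.seed(9)
  for (i in 1:6) {
    n <- sample(4:12, 1)
    s <- make_spec(sort(runif(n, 100, 600)), runif(n, 10, 1000))
    frags <- runif(8, 100, 600)
    prev <- -1L
    for (k in 1:8) {
      r <- fragment_match(s, frags[1:k])
      expect_gte(r$n_matched_peaks, prev)
      prev <- r$n_matched_peaks
    }
  }
})

test_that("MGF files round-trip spectra, precursor, mode and extra headers", {
  path <- withr::local_tempfile(fileext = ".mgf")
  spectra <- list(
    feat_1 = msms_spectrum(c(100.1234, 200.5), c(50, 1000), precursor_mz = 300.15,
                           ion_mode = "+", meta = list(RTINSECONDS = "120.5")),
    feat_2 = msms_spectrum(c(90.05, 130.1), c(10, 20), precursor_mz = 180.08,
                           ion_mode = "-"))
  write_mgf(spectra, path)
  got <- read_mgf(path)
  expect_named(got, c("feat_1", "feat_2"))
  expect_equal(got$feat_1$peaks$mz, spectra$feat_1$peaks$mz, tolerance = 1e-6)
  expect_equal(got$feat_1$precursor_mz, 300.15, tolerance = 1e-6)
  expect_equal(got$feat_1$ion_mode, "+")
  expect_equal(got$feat_2$ion_mode, "-")
  expect_equal(got$feat_1$meta$RTINSECONDS, "120.5")
})

test_that("MSP files round-trip spectra and preserve unknown headers", {
  path <- withr::local_tempfile(fileext = ".msp")
  spectra <- list(
    caffeine = msms_spectrum(c(110.0712, 138.0662, 195.0877), c(300, 900, 120),
                             precursor_mz = 195.0877, ion_mode = "+",
                             meta = list(FORMULA = "C8H10N4O2")),
    anion = msms_spectrum(c(78.9585, 96.9601), c(500, 100),
                          precursor_mz = 212.002, ion_mode = "-"))
  write_msp(spectra, path)
  got <- read_msp(path)
  expect_named(got, c("caffeine", "anion"))
  expect_equal(got$caffeine$peaks$intensity, c(300, 900, 120))
  expect_equal(got$anion$ion_mode, "-")
  expect_equal(got$caffeine$meta$FORMULA, "C8H10N4O2")
})
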