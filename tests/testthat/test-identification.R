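test_that("monoisotopic masses sum most-abundant-isotope masses", {
  expect_equal(monoisotopic_mass("H2O"), 18.010565, tolerance = 1e-6)
  expect_equal(monoisotopic_mass("C4H7N3O"), 113.058912, tolerance = 1e-6)
  expect_equal(monoisotopic_mass(""), 0)
  expect_error(monoisotopic_mass("C2Xx4"), "unknown element")
})

test_that("adduct m/z adds or subtracts one proton", {
  expect_equal(adduct_mz(monoisotopic_mass("C4H7N3O"), "[M+H]+"),
               114.066188, tolerance = 1e-6)
  expect_equal(adduct_mz(monoisotopic_mass("C2H7NO3S"), "[M-H]-"),
               124.007388, tolerance = 1e-6)
  expect_equal(adduct_mz(0, "[M+H]+"), 1.00727646)
  expect_equal(adduct_mz(0, "[M-H]-"), -1.00727646)
  expect_error(adduct_mz(100, "[M+Na]+"), "unsupported")
  # typographic variants accepted
  expect_equal(adduct_mz(100, "[M + H]+"), adduct_mz(100, "[M+H]+"))
})

test_that("ppm error is the scaled absolute deviation and scale-free", {
  expect_equal(ppm_error(100, 100), 0)
  expect_equal(ppm_error(100.0001, 100), 1, tolerance = 1e-6)
  expect_error(ppm_error(100, 0), "> 0")
  set.seed(1)
  a <- runif(10, 50, 1000)
  b <- a * (1 + runif(10, -5e-6, 5e-6))
  expect_equal(ppm_error(3 * a, 3 * b), ppm_error(a, b))
})

test_that("printed taurine m/z agrees with theory within negative-mode tolerance", {
  theo <- adduct_mz(monoisotopic_mass("C2H7NO3S"), "[M-H]-")
  expect_lte(ppm_error(124.00748, theo), 2)
})

test_that("spectral similarity: identity, disjointness and closed-form dilution", {
  a <- ms2_spectrum(200, "positive", mz = c(50, 70, 90, 110),
                    intensity = c(10, 20, 30, 40))
  expect_equal(spectral_similarity(a, a), 1)
  b <- ms2_spectrum(200, "positive", mz = c(55.5, 75.5, 95.5),
                    intensity = c(5, 5, 5))
  expect_equal(spectral_similarity(a, b), 0)
  # k of 2k unit peaks retained -> cosine 1/sqrt(2)
  full <- ms2_spectrum(300, "positive", mz = seq(50, 240, by = 10),
                       intensity = rep(7, 20))
  half <- ms2_spectrum(300, "positive", mz = seq(50, 240, by = 20),
                       intensity = rep(7, 10))
  expect_equal(spectral_similarity(full, half), 1 / sqrt(2),
               tolerance = 1e-12)
})

test_that("spectral similarity is symmetric and intensity-scale invariant", {
  set.seed(7)
  for (i in 1:5) {
    a <- ms2_spectrum(300, "positive", mz = sort(runif(8, 50, 290)),
                      intensity = runif(8, 1, 100))
    b <- ms2_spectrum(300, "positive", mz = sort(runif(6, 50, 290)),
                      intensity = runif(6, 1, 100))
    s <- spectral_similarity(a, b)
    expect_equal(spectral_similarity(b, a), s)
    a_scaled <- ms2_spectrum(300, "positive", a$peaks$mz,
                             a$peaks$intensity * 37)
    expect_equal(spectral_similarity(a_scaled, b), s, tolerance = 1e-12)
    expect_gte(s, 0)
    expect_lte(s, 1)
  }
})

test_that("feature-standard matching gates on mass, RT and MS2 jointly", {
  lib <- generate_reference_library(c("Creatinine", "Taurine"))
  cre <- lib[[1]]
  self <- match_feature_to_standard(cre$theoretical_mz, cre$rt,
                                    "positive", cre$spectrum, cre)
  expect_true(self$confirmed)
  expect_equal(self$ppm_error, 0)
  expect_equal(self$ms2_score, 1)
  shifted <- match_feature_to_standard(cre$theoretical_mz, cre$rt + 5,
                                       "positive", cre$spectrum, cre,
                                       rt_window = 2)
  expect_false(shifted$rt_ok)
  expect_false(shifted$confirmed)
  expect_error(
    match_feature_to_standard(cre$theoretical_mz, cre$rt, "negative",
                              cre$spectrum, cre),
    "polarity")
  # no MS2: unconfirmed unless explicitly allowed
  no_ms2 <- match_feature_to_standard(cre$theoretical_mz, cre$rt,
                                      "positive", NULL, cre)
  expect_false(no_ms2$confirmed)
  allow <- match_feature_to_standard(cre$theoretical_mz, cre$rt,
                                     "positive", NULL, cre,
                                     allow_no_ms2 = TRUE)
  expect_true(allow$confirmed)
})

test_that("loosening any tolerance never unconfirms a match", {
  lib <- generate_reference_library()
  set.seed(11)
  for (std in lib[c(1, 6, 19)]) {
    sp <- perturb_spectrum(std$spectrum, jitter_da = 0.02, drop_frac = 0.3,
                           seed = 5)
    strict <- match_feature_to_standard(
      std$theoretical_mz * (1 + 0.8e-6), std$rt + 1.5, std$mode, sp, std,
      rt_window = 2, tol_pos = 1, tol_neg = 2, score_min = 0.7)
    loose <- match_feature_to_standard(
      std$theoretical_mz * (1 + 0.8e-6), std$rt + 1.5, std$mode, sp, std,
      rt_window = 4, tol_pos = 5, tol_neg = 5, score_min = 0.3)
    if (strict$confirmed) expect_true(loose$confirmed)
    expect_gte(as.integer(loose$mass_ok), as.integer(strict$mass_ok))
    expect_gte(as.integer(loose$rt_ok), as.integer(strict$rt_ok))
    expect_gte(as.integer(loose$ms2_ok), as.integer(strict$ms2_ok))
  }
})

test_that("MSP and MGF files round-trip the library and spectra", {
  lib <- generate_reference_library(c("Creatinine", "Taurine", "Caffeine"))
  msp <- tempfile(fileext = ".msp")
  write_msp(lib, msp)
  back <- read_msp(msp)
  expect_length(back, 3)
  expect_equal(back[[1]]$name, lib[[1]]$name)
  expect_equal(back[[1]]$theoretical_mz, lib[[1]]$theoretical_mz,
               tolerance = 1e-8)
  expect_equal(back[[1]]$spectrum$peaks$mz, lib[[1]]$spectrum$peaks$mz,
               tolerance = 1e-7)
  expect_equal(back[[2]]$mode, "negative")

  spectra <- stats::setNames(lapply(lib, `[[`, "spectrum"),
                             c("F0001", "F0002", "F0003"))
  mgf <- tempfile(fileext = ".mgf")
  write_mgf(spectra, mgf)
  back2 <- read_mgf(mgf)
  expect_setequal(names(back2), names(spectra))
  expect_equal(back2$F0002$mode, "negative")
  expect_equal(back2$F0001$peaks$mz, spectra$F0001$peaks$mz,
               tolerance = 1e-7)
})
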