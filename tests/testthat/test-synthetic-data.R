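test_that("cohort generation is byte-identical under a fixed seed", {
  cfg <- synth_config(n_features = 100, seed = 11)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$table$intensity, b$table$intensity)
  expect_identical(a$table$features, b$table$features)
  expect_identical(a$truth, b$truth)
})

test_that("invalid configs are rejected", {
  expect_error(synth_config(frac_catI = 0.6, frac_catII = 0.5),
               "invalid config")
  expect_error(synth_config(n_per_group = -1), "counts")
  expect_error(synth_config(noise_sigma = -0.1), "noise_sigma")
})

test_that("ground-truth category counts follow the planted fractions", {
  cfg <- synth_config(n_features = 1000, frac_catI = 0.3,
                      frac_catII = 0.2, frac_catIII = 0.1, seed = 2)
  truth <- generate_cohort(cfg)$truth
  counts <- table(truth$planted_category)
  expect_equal(unname(counts[c("I", "II", "III", "unchanged")]),
               as.table(c(300, 200, 100, 400)), ignore_attr = TRUE)
  expect_equal(anyDuplicated(truth$feature_id), 0L)
})

test_that("planted fold changes are consistent with category definitions", {
  truth <- generate_cohort(synth_config(n_features = 500, seed = 3))$truth
  i <- truth$planted_category == "I"
  ii <- truth$planted_category == "II"
  iii <- truth$planted_category == "III"
  un <- truth$planted_category == "unchanged"
  expect_true(all(truth$planted_log2fc_pre_ctrl[i | ii] > 0))
  expect_true(all(truth$planted_log2fc_post_pre[i] < 0))
  expect_true(all(truth$planted_log2fc_post_pre[ii] == 0))
  expect_true(all(truth$planted_log2fc_pre_ctrl[iii] < 0))
  expect_true(all(truth$planted_log2fc_pre_ctrl[un] == 0 &
                    truth$planted_log2fc_post_pre[un] == 0))
})

test_that("noiseless all-category-I plant drops every POST mean below PRE", {
  cfg <- synth_config(n_features = 50, frac_catI = 1, frac_catII = 0,
                      frac_catIII = 0, noise_sigma = 0, seed = 4)
  tab <- generate_cohort(cfg)$table
  pre <- rowMeans(tab$intensity[, role_columns(tab, "PRE"), drop = FALSE])
  post <- rowMeans(tab$intensity[, role_columns(tab, "POST"), drop = FALSE])
  expect_true(all(post < pre))
})

test_that("QC columns resample the pooled mean and blanks sit near 1/50", {
  cfg <- synth_config(n_features = 80, noise_sigma = 0, seed = 5)
  tab <- generate_cohort(cfg)$table
  bio <- tab$intensity[, role_columns(tab, c("CTRL", "PRE", "POST"))]
  pooled <- rowMeans(bio)
  qc <- tab$intensity[, role_columns(tab, "QC"), drop = FALSE]
  blank <- tab$intensity[, role_columns(tab, "BLANK"), drop = FALSE]
  expect_equal(qc[, 1], pooled, ignore_attr = TRUE)
  expect_equal(blank[, 1], pooled / 50, ignore_attr = TRUE)
})

test_that("TMT proteome has 15 channels and planted geometric ratios near fc", {
  sim <- generate_tmt_proteome(n_proteins = 300, n_diff = 40, fc = 2,
                               noise_sigma = 0.2, seed = 6)
  expect_equal(ncol(sim$table$intensity), 15)
  expect_equal(unname(table(sim$table$channels$group)),
               c(5L, 5L, 5L), ignore_attr = TRUE)
  lg <- log2(sim$table$intensity)
  pre <- rowMeans(lg[, sim$table$channels$group == "PRE"])
  ctrl <- rowMeans(lg[, sim$table$channels$group == "CTRL"])
  ratio <- 2^(pre - ctrl)
  expect_equal(mean(ratio[sim$truth$planted_diff]), 2, tolerance = 0.1)
  expect_equal(mean(ratio[!sim$truth$planted_diff]), 1, tolerance = 0.05)
  expect_identical(sim$table$intensity,
                   generate_tmt_proteome(n_proteins = 300, n_diff = 40,
                                         fc = 2, noise_sigma = 0.2,
                                         seed = 6)$table$intensity)
})

test_that("association edges keep planted pairs and match density", {
  mets <- sprintf("m%02d", 1:40)
  prots <- sprintf("p%02d", 1:50)
  planted <- data.frame(chemical = c("m01", "m01"),
                        protein = c("p01", "p02"))
  e0 <- generate_association_edges(mets, prots, density = 0,
                                   planted_pairs = planted, seed = 7)
  expect_equal(nrow(e0), 2)
  expect_true(all(e0$combined_score > 0 & e0$combined_score <= 1))
  e <- generate_association_edges(mets, prots, density = 0.1, seed = 7)
  # binomial expectation 200, sd ~ 13.4
  expect_true(abs(nrow(e) - 0.1 * 40 * 50) < 4 * sqrt(200 * 0.9))
  expect_true(all(paste(planted$chemical, planted$protein) %in%
                    paste(e0$chemical, e0$protein)))
})

test_that("dose-response generator follows the 4PL and is seeded", {
  dr <- generate_dose_response(ic50 = 10, hill = 1, top = 1, bottom = 0,
                               doses = c(100, 10, 1, 0.1, 0.01),
                               noise_sd = 0, seed = 8)
  at_ic50 <- dr$response[dr$dose_uM == 10]
  expect_equal(unique(at_ic50), 0.5)
  means <- tapply(dr$response, dr$dose_uM, mean)
  expect_true(all(diff(means[order(as.numeric(names(means)))]) < 0))
  noisy1 <- generate_dose_response(10, noise_sd = 0.05, seed = 9)
  noisy2 <- generate_dose_response(10, noise_sd = 0.05, seed = 9)
  expect_identical(noisy1, noisy2)
})

test_that("perturb_spectrum drops floor(drop_frac * n) fragments within jitter", {
  sp <- ms2_spectrum(200, "positive", mz = seq(50, 140, by = 10),
                     intensity = rep(1, 10))
  same <- perturb_spectrum(sp, jitter_da = 0, drop_frac = 0, seed = 1)
  expect_equal(same$peaks, sp$peaks)
  half <- perturb_spectrum(sp, jitter_da = 0, drop_frac = 0.5, seed = 1)
  expect_equal(nrow(half$peaks), 5)
  jit1 <- perturb_spectrum(sp, jitter_da = 0.01, drop_frac = 0, seed = 3)
  jit2 <- perturb_spectrum(sp, jitter_da = 0.01, drop_frac = 0, seed = 3)
  expect_identical(jit1, jit2)
  expect_true(all(abs(jit1$peaks$mz - sp$peaks$mz) <= 0.01))
})

test_that("reference library lookups use the built-in confirmed table", {
  lib <- generate_reference_library(c("Creatinine", "Taurine"))
  expect_equal(lib[[1]]$formula, "C4H7N3O")
  expect_equal(lib[[1]]$adduct, "[M+H]+")
  expect_equal(lib[[1]]$observed_mz, 114.06605)
  expect_equal(lib[[2]]$adduct, "[M-H]-")
  expect_equal(lib[[2]]$observed_mz, 124.00748)
  expect_equal(generate_reference_library(character(0)), list())
  expect_error(generate_reference_library("NotACompound"), "unknown")
})
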