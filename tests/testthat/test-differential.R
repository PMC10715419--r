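test_that("median normalization restores a rescaled column and is idempotent", {
  cohort <- generate_cohort(synth_config(n_features = 80, seed = 31))
  tab <- cohort$table
  norm1 <- normalize_intensities(tab)
  norm2 <- normalize_intensities(norm1)
  expect_equal(norm1$intensity, norm2$intensity, tolerance = 1e-12)
  # doubling one biological column then normalizing undoes the doubling:
  # the output equals the original normalization up to the single global
  # target factor re-estimated from the perturbed medians
  doubled <- tab
  doubled$intensity[, 3] <- doubled$intensity[, 3] * 2
  renorm <- normalize_intensities(feature_table(
    doubled$features, doubled$intensity, doubled$samples))
  ratio <- renorm$intensity / norm1$intensity
  expect_lt(max(ratio) - min(ratio), 1e-9 * max(ratio))
  expect_equal(renorm$intensity[, 3], norm1$intensity[, 3],
               tolerance = 0.05)
  expect_identical(normalize_intensities(tab, method = "none"), tab)
})

test_that("test_contrast handles null, exact-doubling and degenerate cases", {
  feats <- toy_features(2)
  samples <- data.frame(
    sample_id = c(paste0("C", 1:4), paste0("P", 1:4)),
    role = rep(c("CTRL", "PRE"), each = 4),
    subject = c(rep(NA, 4), paste0("S", 1:4)),
    stringsAsFactors = FALSE
  )
  base <- matrix(c(10, 12, 14, 16), 2, 4, byrow = TRUE)
  # identical groups -> lfc 0, p 1
  tab <- feature_table(feats, cbind(base, base), samples)
  res <- test_contrast(tab, "PRE", "CTRL")
  expect_equal(res$log2fc, c(0, 0))
  expect_true(all(res$p > 0.999))
  # A = 2B exactly -> lfc 1
  tab2 <- feature_table(feats, cbind(base, 2 * base), samples)
  res2 <- test_contrast(tab2, "PRE", "CTRL")
  expect_equal(res2$log2fc, c(1, 1))
  # constant different groups (noiseless): degenerate p = 0
  tab3 <- feature_table(feats, cbind(matrix(8, 2, 4), matrix(64, 2, 4)),
                        samples)
  res3 <- test_contrast(tab3, "PRE", "CTRL")
  expect_equal(res3$p, c(0, 0))
  expect_equal(res3$log2fc, c(3, 3))
})

test_that("paired POST/PRE testing uses subject matching and beats Welch on matched data", {
  samples <- data.frame(
    sample_id = c(paste0("PRE", 1:4), paste0("POST", 1:4)),
    role = rep(c("PRE", "POST"), each = 4),
    subject = rep(paste0("S", 1:4), 2),
    stringsAsFactors = FALSE
  )
  feats <- toy_features(1)
  # strong subject effects, constant within-pair halving
  pre <- c(100, 1000, 10000, 1e5)
  intensity <- matrix(c(pre, pre / 2), 1, 8)
  tab <- feature_table(feats, intensity, samples)
  res <- test_contrast(tab, "POST", "PRE", paired = TRUE, min_n = 3)
  expect_equal(res$log2fc, -1)
  expect_lt(res$p, 1e-6)
  # shuffling POST columns consistently with subjects changes nothing
  perm <- c(1:4, 8:5)
  res_perm <- test_contrast(tab[, perm], "POST", "PRE", paired = TRUE,
                            min_n = 3)
  expect_equal(res_perm$p, res$p)
  # missing subject metadata errors
  samples_bad <- samples
  samples_bad$subject <- NA
  tab_bad <- feature_table(feats, intensity, samples_bad)
  expect_error(test_contrast(tab_bad, "POST", "PRE", paired = TRUE),
               "subject")
})

test_that("estimated log2fc tracks planted 8-fold effects across seeds", {
  est <- vapply(c(101, 102, 103), function(s) {
    cohort <- generate_cohort(synth_config(n_features = 200, seed = s))
    rec <- run_differential(cohort$table)
    truth <- cohort$truth
    mean(rec$log2fc_pre_ctrl[truth$planted_category %in% c("I", "II")])
  }, numeric(1))
  expect_true(all(abs(est - 3) < 0.25))
})

test_that("BH adjustment matches hand-computed and brute-force values", {
  expect_equal(adjust_fdr_bh(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_fdr_bh(0.2), 0.2)
  expect_equal(adjust_fdr_bh(rep(1, 5)), rep(1, 5))
  expect_error(adjust_fdr_bh(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_equal(adjust_fdr_bh(c(0.4, NA, 0.01)),
               c(0.4, NA, 0.02))
  set.seed(42)
  for (i in 1:20) {
    p <- runif(sample(2:30, 1))
    expect_equal(adjust_fdr_bh(p), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("significance flags apply p, q and fold-change gates jointly", {
  expect_equal(flag_significance(1, 0.01, 0.01, fc_min = 2), "up")
  expect_equal(flag_significance(1, 0.01, 0.2, fc_min = 2), "ns")
  expect_equal(flag_significance(log2(1.9), 0.001, 0.001, fc_min = 2), "ns")
  expect_equal(flag_significance(-1.2, 0.01, 0.01, fc_min = 2), "down")
  expect_equal(flag_significance(NA, NA, NA), "ns")
  # relaxing the FDR gate
  expect_equal(flag_significance(1, 0.01, 0.2, fc_min = 2, q_alpha = Inf),
               "up")
})

test_that("contrast results are invariant to sample-column order", {
  cohort <- generate_cohort(synth_config(n_features = 50, seed = 33))
  tab <- cohort$table
  res <- test_contrast(tab, "PRE", "CTRL")
  perm <- sample(nrow(tab$samples))
  res_perm <- test_contrast(tab[, perm], "PRE", "CTRL")
  expect_equal(res_perm$log2fc, res$log2fc)
  expect_equal(res_perm$p, res$p)
})
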