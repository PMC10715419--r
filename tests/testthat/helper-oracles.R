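# Independent oracles and small fixture builders shared across tests.

# Brute-force BH: q_(i) = min_{j >= i} p_(j) * m / j on the sorted vector,
# mapped back to the original order. Written from the step-up definition,
# independent of the implementation under test.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(ps[i:m] * m / (i:m), 1)
  }
  out <- numeric(m)
  out[ord] <- q
  out
}

# Brute-force hypergeometric upper tail by enumerating every size-n draw
# from a universe of N elements of which K are marked.
hyper_oracle <- function(N, K, n, k) {
  marked <- seq_len(K)
  draws <- utils::combn(N, n)
  hits <- apply(draws, 2, function(d) sum(d %in% marked) >= k)
  mean(hits)
}

# Planted-category recovery: synthetic truth labels unchanged features
# "unchanged"; the classifier calls them "none".
recovery_accuracy <- function(calls, truth) {
  truth <- truth[match(calls$feature_id, truth$feature_id), ]
  planted <- ifelse(truth$planted_category == "unchanged", "none",
                    truth$planted_category)
  mean(calls$category == planted)
}

# Minimal five-role feature table for filter tests: intensities constant
# at `level` for biological samples, `blank_level` for blanks, and
# per-feature QC vectors supplied by the caller.
make_toy_table <- function(features, qc_values, level = 1000,
                           blank_level = 10) {
  nf <- nrow(features)
  samples <- data.frame(
    sample_id = c("C1", "C2", "C3", "P1", "P2", "P3", "Q1", "Q2", "B1"),
    role = c("CTRL", "CTRL", "CTRL", "PRE", "PRE", "PRE", "QC", "QC",
             "BLANK"),
    subject = NA_character_,
    stringsAsFactors = FALSE
  )
  intensity <- matrix(level, nf, nrow(samples))
  intensity[, 7] <- vapply(qc_values, `[`, numeric(1), 1)
  intensity[, 8] <- vapply(qc_values, `[`, numeric(1), 2)
  intensity[, 9] <- blank_level
  feature_table(features, intensity, samples)
}

toy_features <- function(n, mz = 100, rt = 1, mode = "positive",
                         peak_width = 10, snr = 50) {
  data.frame(
    feature_id = sprintf("T%03d", seq_len(n)),
    mz = mz, rt = rt, mode = mode,
    peak_width = peak_width, snr = snr,
    stringsAsFactors = FALSE
  )
}
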