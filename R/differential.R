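#' Median-normalize a feature table
#'
#' Rescales every sample column so its median nonzero intensity equals the
#' target: the median of the per-column nonzero medians of the biological
#' columns (CTRL/PRE/POST). QC and BLANK columns are excluded from the
#' target estimate but rescaled with their own factors. The median-of-
#' medians target is robust: rescaling any single column leaves it (and
#' hence every other column's output) unchanged. Run this after the
#' blank-ratio filter: rescaling blanks to the sample median would defeat
#' that filter.
#'
#' @param table a [feature_table()].
#' @param method `"median"` or `"none"` (identity).
#' @return A normalized `feature_table`.
#' @export
normalize_intensities <- function(table, method = c("median", "none")) {
  method <- match.arg(method)
  if (method == "none") return(table)
  intensity <- table$intensity
  col_med <- apply(intensity, 2, function(v) {
    v <- v[v > 0]
    if (length(v) == 0) stop("all-zero sample column; cannot normalize")
    stats::median(v)
  })
  bio_cols <- role_columns(table, c("CTRL", "PRE", "POST"))
  target <- stats::median(col_med[bio_cols])
  scaled <- sweep(intensity, 2, target / col_med, "*")
  out <- feature_table(table$features, scaled, table$samples)
  attr(out, "spectra") <- attr(table, "spectra")
  out
}

# log2 with the documented pseudo-count: zeros replaced by half the
# smallest nonzero value of the matrix before taking logs.
log2_with_pseudocount <- function(x) {
  pos <- x[x > 0]
  if (length(pos) == 0) stop("matrix has no positive intensities")
  x[x == 0] <- min(pos) / 2
  log2(x)
}

#' Differential test of one contrast
#'
#' Per-feature log2 fold change (difference of group means of log2
#' intensities, i.e. a geometric-mean ratio) with a two-sided Welch
#' t-test, or a paired t-test for the POST-vs-PRE contrast (columns are
#' paired by their `subject` identifier). Zero intensities are replaced
#' by half the smallest nonzero intensity of the table before logs.
#' Groups with zero variance (noiseless synthetic data) get the
#' degenerate p-value: 1 if the means agree, 0 otherwise. Features with
#' fewer than `min_n` values in either group are flagged untestable
#' (`p = NA`) and are excluded from FDR adjustment downstream.
#'
#' @param table a [feature_table()].
#' @param groupA,groupB sample roles of numerator / denominator group.
#' @param paired paired t-test on subject-matched columns (POST vs PRE).
#' @param min_n minimum per-group sample count (default 3).
#' @return data.frame: `feature_id`, `log2fc` (A minus B), `p`, `n_A`,
#'   `n_B`.
#' @export
test_contrast <- function(table, groupA, groupB, paired = FALSE,
                          min_n = 3) {
  stopifnot(inherits(table, "feature_table"))
  colsA <- role_columns(table, groupA)
  colsB <- role_columns(table, groupB)
  if (paired) {
    subjA <- table$samples$subject[colsA]
    subjB <- table$samples$subject[colsB]
    if (anyNA(subjA) || anyNA(subjB))
      stop("paired contrast requires subject metadata for both groups")
    common <- intersect(subjA, subjB)
    colsA <- colsA[match(common, subjA)]
    colsB <- colsB[match(common, subjB)]
  }
  la <- log2_with_pseudocount(table$intensity)[, colsA, drop = FALSE]
  lb <- log2_with_pseudocount(table$intensity)[, colsB, drop = FALSE]
  nA <- ncol(la)
  nB <- ncol(lb)
  testable <- nA >= min_n && nB >= min_n
  p <- vapply(seq_len(nrow(la)), function(i) {
    if (!testable) return(NA_real_)
    a <- la[i, ]
    b <- lb[i, ]
    tryCatch({
      if (paired) stats::t.test(a, b, paired = TRUE)$p.value
      else stats::t.test(a, b)$p.value
    }, error = function(e) {
      # constant data: exact answer for the degenerate case
      if (abs(mean(a) - mean(b)) < 1e-12) 1 else 0
    })
  }, numeric(1))
  data.frame(
    feature_id = table$features$feature_id,
    log2fc = rowMeans(la) - rowMeans(lb),
    p = p,
    n_A = nA, n_B = nB,
    stringsAsFactors = FALSE
  )
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up FDR adjustment with monotonicity enforcement. `NA` p-values
#' (untestable features) are passed through as `NA` and do not count
#' toward the number of tests.
#'
#' @param pvalues numeric vector in `[0, 1]` (NAs allowed).
#' @return q-values, same length and order.
#' @export
adjust_fdr_bh <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1))
    stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(pvalues))
  out[ok] <- stats::p.adjust(pvalues[ok], method = "BH")
  out
}

#' Flag per-contrast significance
#'
#' `up` requires p < `alpha`, q < `q_alpha` and log2fc >= log2(`fc_min`);
#' `down` is symmetric with log2fc <= -log2(`fc_min`); anything else
#' (including untestable NAs) is `ns`. Both the raw-p and the FDR gates
#' are enforced by default; pass `q_alpha = Inf` (or `alpha = Inf`) to
#' relax one of them.
#'
#' @param log2fc,p,q numeric vectors (recycled per feature).
#' @param fc_min minimum fold change (default 2).
#' @param alpha raw p-value threshold (default 0.05).
#' @param q_alpha FDR threshold (default 0.05).
#' @return character vector: `"up"`, `"down"`, or `"ns"`.
#' @export
flag_significance <- function(log2fc, p, q, fc_min = 2, alpha = 0.05,
                              q_alpha = 0.05) {
  lfc_min <- log2(fc_min)
  sig <- !is.na(p) & !is.na(q) & p < alpha & q < q_alpha
  out <- rep("ns", length(log2fc))
  out[sig & log2fc >= lfc_min] <- "up"
  out[sig & log2fc <= -lfc_min] <- "down"
  out
}

#' Differential records for the three cohort contrasts
#'
#' Runs [test_contrast()] for PRE/CTRL and POST/CTRL (Welch) and POST/PRE
#' (paired), BH-adjusts each contrast's p-values, and returns one wide
#' record per feature.
#'
#' @param table a (typically filtered and normalized) [feature_table()].
#' @param min_n minimum per-group sample count.
#' @return data.frame with, per contrast suffix `pre_ctrl`, `post_pre`,
#'   `post_ctrl`: `log2fc_*`, `p_*`, `q_*`; plus `feature_id` and group
#'   sizes.
#' @export
run_differential <- function(table, min_n = 3) {
  pre_ctrl <- test_contrast(table, "PRE", "CTRL", min_n = min_n)
  post_pre <- test_contrast(table, "POST", "PRE", paired = TRUE,
                            min_n = min_n)
  post_ctrl <- test_contrast(table, "POST", "CTRL", min_n = min_n)
  data.frame(
    feature_id = pre_ctrl$feature_id,
    log2fc_pre_ctrl = pre_ctrl$log2fc,
    p_pre_ctrl = pre_ctrl$p,
    q_pre_ctrl = adjust_fdr_bh(pre_ctrl$p),
    log2fc_post_pre = post_pre$log2fc,
    p_post_pre = post_pre$p,
    q_post_pre = adjust_fdr_bh(post_pre$p),
    log2fc_post_ctrl = post_ctrl$log2fc,
    p_post_ctrl = post_ctrl$p,
    q_post_ctrl = adjust_fdr_bh(post_ctrl$p),
    n_ctrl = pre_ctrl$n_B, n_pre = pre_ctrl$n_A, n_post = post_ctrl$n_A,
    stringsAsFactors = FALSE
  )
}
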