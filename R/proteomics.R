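#' Construct a TMT protein quantification table
#'
#' @param intensity numeric matrix of reporter-ion intensities, proteins
#'   x channels, all >= 0.
#' @param proteins data.frame with `accession` and `gene` columns.
#' @param channels data.frame with `channel_id` and `group` (one of
#'   CTRL/PRE/POST) columns.
#' @return An object of class `protein_quant`.
#' @export
protein_quant <- function(intensity, proteins, channels) {
  intensity <- as.matrix(intensity)
  stopifnot(nrow(intensity) == nrow(proteins),
            ncol(intensity) == nrow(channels))
  if (any(intensity < 0)) stop("reporter intensities must be >= 0")
  if (!all(channels$group %in% c("CTRL", "PRE", "POST")))
    stop("channel groups must be CTRL, PRE or POST")
  rownames(intensity) <- proteins$accession
  colnames(intensity) <- channels$channel_id
  structure(list(intensity = intensity, proteins = proteins,
                 channels = channels),
            class = "protein_quant")
}

#' @export
print.protein_quant <- function(x, ...) {
  tab <- table(x$channels$group)
  cat("protein_quant:", nrow(x$proteins), "proteins x",
      nrow(x$channels), "channels (",
      paste(names(tab), tab, sep = "=", collapse = " "), ")\n")
  invisible(x)
}

#' Quantile-normalize TMT reporter intensities
#'
#' Reporter intensities are log-transformed (base `log_base`, zeros
#' replaced by half the smallest nonzero value) and quantile-normalized
#' jointly across all channels: after normalization every channel's
#' sorted value vector equals the rank-wise mean distribution, with ties
#' receiving the mean of their rank block.
#'
#' @param table a [protein_quant()].
#' @param log_base logarithm base (default 2).
#' @return A `protein_quant` whose intensity matrix holds normalized
#'   log-scale values.
#' @export
quantile_normalize <- function(table, log_base = 2) {
  stopifnot(inherits(table, "protein_quant"))
  if (any(colSums(table$intensity) == 0))
    stop("all-zero channel; cannot quantile-normalize")
  lg <- log2_with_pseudocount(table$intensity) / log2(log_base)
  norm <- limma::normalizeQuantiles(lg, ties = TRUE)
  dimnames(norm) <- dimnames(table$intensity)
  out <- table
  out$intensity <- norm
  out$log_scale <- TRUE
  out
}

#' Call differential serum proteins
#'
#' Quantile-normalizes (unless the table is already on the log scale) and
#' applies the same Welch-test machinery used for metabolite contrasts to
#' the PRE-vs-CTRL channels, flagging proteins at the serum-proteome
#' thresholds: fold change > 1.5, p < 0.05 (and FDR < 0.05 by default;
#' pass `q_alpha = Inf` to use the raw-p-only reading).
#'
#' @param table a [protein_quant()].
#' @param groupA,groupB channel groups to contrast (defaults PRE vs CTRL).
#' @param fc_min minimum fold change (default 1.5).
#' @param alpha raw p threshold (default 0.05).
#' @param q_alpha FDR threshold (default 0.05).
#' @param min_n minimum channels per group (default 3).
#' @return data.frame: `accession`, `gene`, `log2fc`, `p`, `q`, `flag`
#'   (`up`/`down`/`ns`).
#' @export
test_differential_proteins <- function(table, groupA = "PRE",
                                       groupB = "CTRL", fc_min = 1.5,
                                       alpha = 0.05, q_alpha = 0.05,
                                       min_n = 3) {
  stopifnot(inherits(table, "protein_quant"))
  if (!isTRUE(table$log_scale)) table <- quantile_normalize(table)
  colsA <- which(table$channels$group == groupA)
  colsB <- which(table$channels$group == groupB)
  if (length(colsA) < min_n || length(colsB) < min_n)
    stop("need >= ", min_n, " channels per group")
  la <- table$intensity[, colsA, drop = FALSE]
  lb <- table$intensity[, colsB, drop = FALSE]
  p <- vapply(seq_len(nrow(la)), function(i) {
    a <- la[i, ]
    b <- lb[i, ]
    tryCatch(stats::t.test(a, b)$p.value, error = function(e) {
      if (abs(mean(a) - mean(b)) < 1e-12) 1 else 0
    })
  }, numeric(1))
  log2fc <- rowMeans(la) - rowMeans(lb)
  q <- adjust_fdr_bh(p)
  data.frame(
    accession = table$proteins$accession,
    gene = table$proteins$gene,
    log2fc = log2fc, p = p, q = q,
    flag = flag_significance(log2fc, p, q, fc_min = fc_min,
                             alpha = alpha, q_alpha = q_alpha),
    stringsAsFactors = FALSE
  )
}
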