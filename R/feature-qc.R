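#' Coefficient of variation (percent)
#'
#' `100 * sd / mean` with the sample (n-1) standard deviation. Used on
#' pooled-QC injections to flag analytically unstable features.
#'
#' @param values numeric intensities, length >= 2, positive mean.
#' @return CV in percent.
#' @export
compute_cv <- function(values) {
  if (length(values) < 2) stop("CV undefined: fewer than 2 values")
  m <- mean(values)
  if (m <= 0) stop("CV undefined: mean is not positive")
  100 * stats::sd(values) / m
}

#' Sample-to-blank intensity ratio
#'
#' Mean biological-sample intensity relative to the blank (negative
#' control) mean. A zero blank mean is floored at `eps` so blank-absent
#' features obtain a large finite ratio and survive the filter.
#'
#' @param sample_mean mean intensity over biological samples (>= 0).
#' @param blank_mean mean intensity over blank injections (>= 0).
#' @param eps floor applied to `blank_mean` (must be > 0).
#' @return `sample_mean / max(blank_mean, eps)`.
#' @export
blank_ratio <- function(sample_mean, blank_mean, eps = 1e-9) {
  if (sample_mean < 0 || blank_mean < 0) stop("intensities must be >= 0")
  if (eps <= 0) stop("eps must be > 0")
  sample_mean / max(blank_mean, eps)
}

#' Feature-filter thresholds
#'
#' Defaults are the four feature-level removal rules applied before
#' downstream analysis: CV >= 50 percent, sample/blank fold change <= 5,
#' S/N <= 3, peak width < 6 scans. Boundary semantics follow the rules
#' verbatim: CV exactly 50 is removed, width exactly 6 is retained.
#'
#' @param cv_max CV removal threshold in percent (remove if CV >= this).
#' @param blank_ratio_min blank fold-change threshold (remove if <= this).
#' @param snr_min signal/noise threshold (remove if <= this).
#' @param peak_width_min minimum peak width in scans (remove if < this).
#' @return A `filter_thresholds` list.
#' @export
filter_thresholds <- function(cv_max = 50, blank_ratio_min = 5,
                              snr_min = 3, peak_width_min = 6) {
  if (any(c(cv_max, blank_ratio_min, snr_min, peak_width_min) <= 0))
    stop("all thresholds must be positive")
  structure(list(cv_max = cv_max, blank_ratio_min = blank_ratio_min,
                 snr_min = snr_min, peak_width_min = peak_width_min),
            class = "filter_thresholds")
}

#' Apply the four feature-level QC filters
#'
#' One conjunctive pass: a feature is removed if ANY rule fires. Rules:
#' unstable intensity (CV >= `cv_max` over QC injections, or over all
#' biological samples when `cv_source = "biological"`); low fold change
#' vs blanks (sample/blank ratio <= `blank_ratio_min`); low
#' signal-to-noise (snr <= `snr_min`); narrow chromatographic peaks
#' (width < `peak_width_min` scans). The report counts each rule's
#' firings independently, so counts can overlap.
#'
#' @param table a [feature_table()].
#' @param thresholds a [filter_thresholds()].
#' @param cv_source `"QC"` (default; requires >= 2 QC columns) or
#'   `"biological"`.
#' @return List with `table` (surviving features; feature MS2 spectra
#'   carried along) and `report` (per-rule removal counts, totals,
#'   surviving ids).
#' @export
apply_feature_filters <- function(table, thresholds = filter_thresholds(),
                                  cv_source = c("QC", "biological")) {
  stopifnot(inherits(table, "feature_table"),
            inherits(thresholds, "filter_thresholds"))
  cv_source <- match.arg(cv_source)
  bio_cols <- role_columns(table, c("CTRL", "PRE", "POST"))
  blank_cols <- role_columns(table, "BLANK")
  qc_cols <- role_columns(table, "QC")
  if (length(blank_cols) < 1)
    stop("configuration error: blank-ratio filter needs >= 1 BLANK sample")
  if (cv_source == "QC" && length(qc_cols) < 2)
    stop("configuration error: CV over QC needs >= 2 QC samples")
  cv_cols <- if (cv_source == "QC") qc_cols else bio_cols

  cv <- apply(table$intensity[, cv_cols, drop = FALSE], 1, compute_cv)
  sample_means <- rowMeans(table$intensity[, bio_cols, drop = FALSE])
  blank_means <- rowMeans(table$intensity[, blank_cols, drop = FALSE])
  pos <- table$intensity[table$intensity > 0]
  eps <- if (length(pos) > 0) min(pos) * 1e-3 else 1e-9
  ratio <- mapply(blank_ratio, sample_means, blank_means,
                  MoreArgs = list(eps = eps))

  fail_cv <- cv >= thresholds$cv_max
  fail_blank <- ratio <= thresholds$blank_ratio_min
  fail_snr <- table$features$snr <= thresholds$snr_min
  fail_width <- table$features$peak_width < thresholds$peak_width_min
  removed <- fail_cv | fail_blank | fail_snr | fail_width

  out <- table[!removed, ]
  spectra <- attr(table, "spectra")
  if (!is.null(spectra))
    attr(out, "spectra") <-
      spectra[intersect(names(spectra), out$features$feature_id)]

  report <- list(
    n_input = nrow(table$features),
    n_removed = sum(removed),
    n_surviving = sum(!removed),
    removed_by_cv = sum(fail_cv),
    removed_by_blank_ratio = sum(fail_blank),
    removed_by_snr = sum(fail_snr),
    removed_by_peak_width = sum(fail_width),
    surviving_ids = out$features$feature_id
  )
  list(table = out, report = report)
}
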