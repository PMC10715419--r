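#' Construct an LC-MS feature table
#'
#' The central container of the pipeline: per-feature metadata (m/z,
#' retention time, ionization mode, chromatographic peak width,
#' signal-to-noise), a nonnegative intensity matrix (features x samples),
#' and per-sample roles. Roles follow the three-arm dialysis cohort design:
#' healthy controls (`CTRL`), patients before (`PRE`) and after (`POST`) a
#' hemodialysis session, plus pooled quality-control injections (`QC`) and
#' blank injections (`BLANK`). `PRE` and `POST` columns of the same patient
#' share a `subject` identifier, enabling paired testing.
#'
#' @param features data.frame with columns `feature_id`, `mz` (Da, > 0),
#'   `rt` (minutes, >= 0), `mode` (`"positive"` or `"negative"`),
#'   `peak_width` (scans), `snr` (signal-to-noise ratio).
#' @param intensity numeric matrix, rows = features, columns = samples,
#'   all values >= 0.
#' @param samples data.frame with columns `sample_id`, `role` (one of
#'   `CTRL`, `PRE`, `POST`, `QC`, `BLANK`) and `subject` (NA except for
#'   `PRE`/`POST` columns).
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(features, intensity, samples) {
  stopifnot(is.data.frame(features), is.data.frame(samples))
  required <- c("feature_id", "mz", "rt", "mode", "peak_width", "snr")
  missing_cols <- setdiff(required, names(features))
  if (length(missing_cols) > 0)
    stop("features is missing columns: ", paste(missing_cols, collapse = ", "))
  if (!all(c("sample_id", "role") %in% names(samples)))
    stop("samples must have columns sample_id and role")
  if (!"subject" %in% names(samples)) samples$subject <- NA_character_
  intensity <- as.matrix(intensity)
  if (nrow(intensity) != nrow(features))
    stop("intensity rows must match features")
  if (ncol(intensity) != nrow(samples))
    stop("intensity columns must match samples")
  if (anyDuplicated(features$feature_id))
    stop("duplicate feature_id")
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample_id")
  bad_role <- setdiff(unique(samples$role), c("CTRL", "PRE", "POST", "QC", "BLANK"))
  if (length(bad_role) > 0)
    stop("unknown sample role(s): ", paste(bad_role, collapse = ", "))
  if (any(intensity < 0, na.rm = TRUE)) stop("intensities must be >= 0")
  if (any(features$mz <= 0)) stop("mz must be > 0")
  if (any(features$rt < 0)) stop("rt must be >= 0")
  if (!all(features$mode %in% c("positive", "negative")))
    stop("mode must be 'positive' or 'negative'")
  rownames(intensity) <- features$feature_id
  colnames(intensity) <- samples$sample_id
  structure(
    list(features = features, intensity = intensity, samples = samples),
    class = "feature_table"
  )
}

#' @export
print.feature_table <- function(x, ...) {
  tab <- table(x$samples$role)
  cat("feature_table:", nrow(x$features), "features x",
      nrow(x$samples), "samples\n")
  cat("  roles:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  cat("  modes:", paste(names(table(x$features$mode)),
                        table(x$features$mode), sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$intensity)

#' Subset a feature table by feature and/or sample
#'
#' @param x a `feature_table`.
#' @param i feature index (logical, integer, or feature_id character).
#' @param j sample index (logical, integer, or sample_id character).
#' @param ... unused.
#' @return A `feature_table` restricted to the selected rows/columns.
#' @export
`[.feature_table` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$features))
  if (missing(j)) j <- seq_len(nrow(x$samples))
  if (is.character(i)) i <- match(i, x$features$feature_id)
  if (is.character(j)) j <- match(j, x$samples$sample_id)
  feature_table(
    features = x$features[i, , drop = FALSE],
    intensity = x$intensity[i, j, drop = FALSE],
    samples = x$samples[j, , drop = FALSE]
  )
}

#' Columns of a feature table belonging to a role
#'
#' @param x a `feature_table`.
#' @param roles character vector of roles to select.
#' @return Integer column indices.
#' @export
role_columns <- function(x, roles) {
  which(x$samples$role %in% roles)
}

#' Write / read a feature table as TSV
#'
#' The intensity matrix is written with metadata columns
#' (`feature_id`, `mz`, `rt_min`, `mode`, `peak_width_scans`, `snr`)
#' followed by one column per sample; sample roles go to a sidecar TSV
#' (`sample_id`, `role`, `subject`).
#'
#' @param x a `feature_table`.
#' @param path path of the intensity TSV.
#' @param roles_path path of the sample-role sidecar TSV.
#' @return `write_feature_table` returns `path` invisibly;
#'   `read_feature_table` returns a `feature_table`.
#' @export
write_feature_table <- function(x, path, roles_path) {
  df <- data.frame(
    feature_id = x$features$feature_id,
    mz = x$features$mz,
    rt_min = x$features$rt,
    mode = x$features$mode,
    peak_width_scans = x$features$peak_width,
    snr = x$features$snr,
    check.names = FALSE
  )
  df <- cbind(df, as.data.frame(x$intensity, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(x$samples, roles_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path, roles_path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  samples <- utils::read.delim(roles_path, check.names = FALSE,
                               stringsAsFactors = FALSE)
  meta_cols <- c("feature_id", "mz", "rt_min", "mode", "peak_width_scans", "snr")
  features <- data.frame(
    feature_id = df$feature_id, mz = df$mz, rt = df$rt_min, mode = df$mode,
    peak_width = df$peak_width_scans, snr = df$snr,
    stringsAsFactors = FALSE
  )
  intensity <- as.matrix(df[, setdiff(names(df), meta_cols), drop = FALSE])
  feature_table(features, intensity[, samples$sample_id, drop = FALSE], samples)
}
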