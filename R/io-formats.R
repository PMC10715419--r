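#' Write a reference-standard library as MSP
#'
#' One NIST-style MSP record per standard (NAME, PRECURSORMZ,
#' PRECURSORTYPE, FORMULA, RETENTIONTIME, IONMODE, COMMENT with the
#' accession, Num Peaks, then `mz intensity` lines).
#'
#' @param library list of `reference_standard` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_msp <- function(library, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (std in library) {
    pk <- std$spectrum$peaks
    writeLines(c(
      paste0("NAME: ", std$name),
      paste0("PRECURSORMZ: ", format(std$theoretical_mz, digits = 10)),
      paste0("PRECURSORTYPE: ", std$adduct),
      paste0("FORMULA: ", std$formula),
      paste0("RETENTIONTIME: ", std$rt),
      paste0("IONMODE: ", std$mode),
      paste0("COMMENT: ", std$accession),
      paste0("Num Peaks: ", nrow(pk)),
      paste(format(pk$mz, digits = 10), pk$intensity),
      ""
    ), con)
  }
  invisible(path)
}

#' Read a reference-standard library from MSP
#'
#' @param path MSP file written by [write_msp()] (or compatible).
#' @return List of `reference_standard` objects.
#' @export
read_msp <- function(path) {
  lines <- readLines(path)
  out <- list()
  i <- 1
  fields <- list()
  peaks <- NULL
  flush <- function(fields, peaks) {
    if (is.null(fields$NAME)) return(NULL)
    mode <- tolower(fields$IONMODE)
    spec <- ms2_spectrum(as.numeric(fields$PRECURSORMZ), mode,
                         peaks$mz, peaks$intensity)
    structure(
      list(name = fields$NAME, formula = fields$FORMULA,
           adduct = fields$PRECURSORTYPE, mode = mode,
           observed_mz = NA_real_,
           theoretical_mz = as.numeric(fields$PRECURSORMZ),
           rt = as.numeric(fields$RETENTIONTIME),
           accession = fields$COMMENT, spectrum = spec),
      class = "reference_standard"
    )
  }
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (ln == "") {
      std <- flush(fields, peaks)
      if (!is.null(std)) out[[length(out) + 1]] <- std
      fields <- list()
      peaks <- NULL
    } else if (grepl("^Num Peaks:", ln, ignore.case = TRUE)) {
      n <- as.integer(sub("^Num Peaks:\\s*", "", ln, ignore.case = TRUE))
      vals <- lines[(i + 1):(i + n)]
      sp <- strsplit(trimws(vals), "\\s+")
      peaks <- data.frame(
        mz = as.numeric(vapply(sp, `[`, character(1), 1)),
        intensity = as.numeric(vapply(sp, `[`, character(1), 2))
      )
      i <- i + n
    } else if (grepl(":", ln, fixed = TRUE)) {
      key <- toupper(trimws(sub(":.*$", "", ln)))
      val <- trimws(sub("^[^:]*:", "", ln))
      fields[[key]] <- val
    }
    i <- i + 1
  }
  std <- flush(fields, peaks)
  if (!is.null(std)) out[[length(out) + 1]] <- std
  out
}

#' Write feature MS2 spectra as MGF
#'
#' @param spectra named list of `ms2_spectrum` (names = feature ids).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(spectra)) {
    sp <- spectra[[id]]
    charge <- if (sp$mode == "positive") "1+" else "1-"
    writeLines(c(
      "BEGIN IONS",
      paste0("TITLE=", id),
      paste0("PEPMASS=", format(sp$precursor_mz, digits = 10)),
      paste0("CHARGE=", charge),
      paste(format(sp$peaks$mz, digits = 10), sp$peaks$intensity),
      "END IONS",
      ""
    ), con)
  }
  invisible(path)
}

#' Read feature MS2 spectra from MGF
#'
#' @param path MGF file.
#' @return Named list of `ms2_spectrum`.
#' @export
read_mgf <- function(path) {
  lines <- readLines(path)
  out <- list()
  in_block <- FALSE
  title <- NULL
  pepmass <- NULL
  charge <- "1+"
  mzs <- ints <- numeric(0)
  for (ln in trimws(lines)) {
    if (ln == "BEGIN IONS") {
      in_block <- TRUE
      title <- NULL; pepmass <- NULL; charge <- "1+"
      mzs <- ints <- numeric(0)
    } else if (ln == "END IONS") {
      mode <- if (grepl("-", charge, fixed = TRUE)) "negative" else "positive"
      out[[title]] <- ms2_spectrum(pepmass, mode, mzs, ints)
      in_block <- FALSE
    } else if (in_block && grepl("^TITLE=", ln)) {
      title <- sub("^TITLE=", "", ln)
    } else if (in_block && grepl("^PEPMASS=", ln)) {
      pepmass <- as.numeric(strsplit(sub("^PEPMASS=", "", ln), "\\s+")[[1]][1])
    } else if (in_block && grepl("^CHARGE=", ln)) {
      charge <- sub("^CHARGE=", "", ln)
    } else if (in_block && ln != "" && !grepl("=", ln, fixed = TRUE)) {
      parts <- strsplit(ln, "\\s+")[[1]]
      mzs <- c(mzs, as.numeric(parts[1]))
      ints <- c(ints, as.numeric(parts[2]))
    }
  }
  out
}

#' Write / read a TMT protein quantification table as TSV
#'
#' The quantification TSV has `accession`, `gene` and one column per
#' reporter channel; the channel-to-group map goes to a sidecar TSV.
#'
#' @param x a [protein_quant()].
#' @param path quantification TSV path.
#' @param channels_path channel-map TSV path.
#' @return `write_protein_quant` returns `path` invisibly;
#'   `read_protein_quant` a `protein_quant`.
#' @export
write_protein_quant <- function(x, path, channels_path) {
  df <- cbind(x$proteins, as.data.frame(x$intensity, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(x$channels, channels_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_protein_quant
#' @export
read_protein_quant <- function(path, channels_path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  channels <- utils::read.delim(channels_path, stringsAsFactors = FALSE)
  protein_quant(
    intensity = as.matrix(df[, channels$channel_id, drop = FALSE]),
    proteins = df[, c("accession", "gene")],
    channels = channels
  )
}

#' Write association edges as a STITCH-dialect TSV
#'
#' @param edges data.frame with `chemical`, `protein`, `combined_score`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edges <- function(edges, path) {
  utils::write.table(edges[, c("chemical", "protein", "combined_score")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write ground truth emitted by the synthetic generators
#'
#' @param truth data.frame (cohort or proteome ground truth).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
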