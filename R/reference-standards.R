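#' Reference-standard compound table
#'
#' The 21 serum metabolites confirmed against authentic reference
#' standards in the hemodialysis cohort, with molecular formula, observed
#' m/z, average retention time (minutes), RT shift between study sample
#' and standard, adduct type, and database accession. The observed m/z
#' values are instrument readings: the mass gate of the identification
#' stage always compares against the theoretical adduct m/z computed from
#' the formula, never against these printed values.
#'
#' @return data.frame with columns `name`, `formula`, `observed_mz`,
#'   `rt`, `rt_delta`, `adduct`, `accession`.
#' @export
reference_compounds <- function() {
  tab <- data.frame(
    name = c(
      "2,3-Dihydroxybenzoic acid", "4-Hydroxyquinoline", "6-Methylcoumarin",
      "Caffeine", "Creatine anhydrous", "Creatinine", "Famotidine",
      "L-Arginine", "L-Glutamine", "L-Kynurenine", "L-Leucine",
      "L-Phenylalanine", "L-Proline", "L-Tryptophan", "L-Tyrosine",
      "LPC 16:0", "Piperine", "Riboflavin", "Taurine", "Theobromine",
      "Uracil"),
    formula = c(
      "C7H6O4", "C9H7NO", "C10H8O2", "C8H10N4O2", "C4H9N3O2", "C4H7N3O",
      "C8H15N7O2S3", "C6H14N4O2", "C5H10N2O3", "C10H12N2O3", "C6H13NO2",
      "C9H11NO2", "C5H9NO2", "C11H12N2O2", "C9H11NO3", "C24H50NO7P",
      "C17H19NO3", "C17H20N4O6", "C2H7NO3S", "C7H8N4O2", "C4H4N2O2"),
    observed_mz = c(
      153.01921, 146.05943, 161.05898, 195.08676, 132.07625, 114.06605,
      338.05096, 175.1183, 147.07596, 209.09135, 132.10136, 166.08556,
      116.07044, 205.09622, 182.08064, 496.3385, 286.1423, 375.13385,
      124.00748, 181.07126, 113.03434),
    rt = c(31.0, 18.6, 24.9, 15.0, 0.8, 0.4, 10.3, 0.2, 1.3, 11.5, 4.5,
           10.4, 2.9, 12.3, 4.3, 35.5, 31.3, 15.5, 1.3, 12.2, 7.5),
    rt_delta = c(0.4, -0.8, -0.1, 0.7, 0.2, 0.5, 1.5, 2.0, -0.4, -0.9,
                 -0.7, 0.3, 1.8, 0.2, 0.7, 0.5, -0.7, 0.1, 0.7, 1.7, -0.8),
    adduct = c(
      "[M-H]-", "[M+H]+", "[M+H]+", "[M+H]+", "[M+H]+", "[M+H]+",
      "[M+H]+", "[M+H]+", "[M+H]+", "[M+H]+", "[M+H]+", "[M+H]+",
      "[M+H]+", "[M+H]+", "[M+H]+", "[M+H]+", "[M+H]+", "[M-H]-",
      "[M-H]-", "[M+H]+", "[M+H]+"),
    accession = c(
      "HMDB0000397", "PUBCHEMCID69141", "HMDB0032394", "HMDB0001847",
      "HMDB0000064", "HMDB0000562", "HMDB0001919", "HMDB0000517",
      "HMDB0000641", "HMDB0000684", "HMDB0000687", "HMDB0000159",
      "HMDB0000162", "HMDB0000929", "HMDB0000158", "HMDB0010382",
      "HMDB0029377", "HMDB0000244", "HMDB0000251", "HMDB0002825",
      "HMDB0000300"),
    stringsAsFactors = FALSE
  )
  tab
}

#' Generate a reference-standard library with synthetic MS2 spectra
#'
#' Builds `reference_standard` objects for the named compounds from the
#' built-in confirmed-compound table. Real fragmentation spectra are not
#' distributed with the package, so each standard receives a synthetic MS2
#' fragment list: `n_fragments` fragments at reproducible (seeded) m/z
#' positions below the precursor with log-uniform intensities. The spectra
#' are internally consistent — a feature generated from the same standard
#' carries the identical spectrum, so self-matching scores 1.
#'
#' @param names compound names; defaults to all 21 confirmed standards.
#' @param n_fragments fragments per synthetic spectrum (default 8).
#' @param seed RNG seed for fragment placement (default 1).
#' @return List of `reference_standard` objects, each with `name`,
#'   `formula`, `adduct`, `mode`, `observed_mz`, `theoretical_mz`, `rt`,
#'   `accession` and an `ms2_spectrum`.
#' @export
generate_reference_library <- function(names = reference_compounds()$name,
                                       n_fragments = 8, seed = 1) {
  tab <- reference_compounds()
  if (length(names) == 0) return(list())
  unknown <- setdiff(names, tab$name)
  if (length(unknown) > 0)
    stop("unknown compound name(s): ", paste(unknown, collapse = ", "))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  lapply(names, function(nm) {
    row <- tab[tab$name == nm, ]
    theo <- adduct_mz(monoisotopic_mass(row$formula), row$adduct)
    mode <- adduct_mode(row$adduct)
    # fragments: precursor survivor + random neutral losses
    frag_mz <- sort(c(theo, theo * stats::runif(n_fragments - 1, 0.15, 0.95)))
    frag_int <- 10^stats::runif(n_fragments, 3, 6)
    structure(
      list(
        name = row$name, formula = row$formula, adduct = row$adduct,
        mode = mode, observed_mz = row$observed_mz, theoretical_mz = theo,
        rt = row$rt, accession = row$accession,
        spectrum = ms2_spectrum(theo, mode, frag_mz, frag_int)
      ),
      class = "reference_standard"
    )
  })
}

#' @export
print.reference_standard <- function(x, ...) {
  cat("reference_standard:", x$name, "(", x$formula, x$adduct, ")",
      "m/z", format(x$theoretical_mz), "RT", x$rt, "min\n")
  invisible(x)
}

#' Perturb an MS2 spectrum
#'
#' Stress input for the spectral-matching score: drops
#' `floor(drop_frac * n)` randomly chosen fragments and jitters each
#' remaining fragment m/z by a uniform shift in `[-jitter_da, jitter_da]`.
#' The precursor m/z is unchanged.
#'
#' @param spectrum an `ms2_spectrum`.
#' @param jitter_da maximum absolute m/z shift per fragment (Da).
#' @param drop_frac fraction of fragments to drop, in `[0, 1)`.
#' @param seed RNG seed.
#' @return A perturbed `ms2_spectrum`.
#' @export
perturb_spectrum <- function(spectrum, jitter_da = 0, drop_frac = 0,
                             seed = 1) {
  stopifnot(inherits(spectrum, "ms2_spectrum"),
            drop_frac >= 0, drop_frac < 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  pk <- spectrum$peaks
  n <- nrow(pk)
  n_drop <- floor(drop_frac * n)
  keep <- seq_len(n)
  if (n_drop > 0) keep <- sort(sample(n, n - n_drop))
  mz <- pk$mz[keep] + stats::runif(length(keep), -jitter_da, jitter_da)
  ms2_spectrum(spectrum$precursor_mz, spectrum$mode, mz, pk$intensity[keep])
}

# Save/restore the global RNG state so seeded generators do not disturb
# the caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
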