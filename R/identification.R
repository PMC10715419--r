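# Monoisotopic masses of the most abundant isotope per element (Da).
# Values from the NIST atomic mass compilation; enough coverage for
# serum metabolites (CHNOPS) plus common hetero-atoms.
.element_masses <- c(
  H = 1.00782503207,
  C = 12.0,
  N = 14.0030740048,
  O = 15.9949146196,
  P = 30.97376163,
  S = 31.97207100,
  Na = 22.9897692809,
  K = 38.96370668,
  Cl = 34.96885268,
  F = 18.99840322,
  Br = 78.9183371,
  I = 126.904473
)

.proton_mass <- 1.00727646

#' Monoisotopic mass of a molecular formula
#'
#' Sums most-abundant-isotope masses over the parsed elemental composition.
#' Formulas use Hill-style element counts, e.g. `"C4H7N3O"` (creatinine).
#'
#' @param formula character scalar, e.g. `"C2H7NO3S"`. An empty string
#'   yields mass 0.
#' @return Monoisotopic mass in Da.
#' @examples
#' monoisotopic_mass("H2O")      # 18.010565
#' monoisotopic_mass("C4H7N3O")  # creatinine, 113.058912
#' @export
monoisotopic_mass <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1)
  formula <- gsub("\\s", "", formula)
  if (nchar(formula) == 0) return(0)
  m <- gregexpr("([A-Z][a-z]?)(\\d*)", formula)[[1]]
  tokens <- regmatches(formula, list(m))[[1]]
  tokens <- tokens[nchar(tokens) > 0]
  if (sum(nchar(tokens)) != nchar(formula))
    stop("cannot parse formula: ", formula)
  total <- 0
  for (tok in tokens) {
    el <- sub("\\d+$", "", tok)
    n <- sub("^[A-Za-z]+", "", tok)
    n <- if (nchar(n) == 0) 1L else as.integer(n)
    if (!el %in% names(.element_masses))
      stop("unknown element '", el, "' in formula ", formula)
    total <- total + .element_masses[[el]] * n
  }
  total
}

#' Theoretical adduct m/z
#'
#' Protonation/deprotonation adducts observed in ESI:
#' `[M+H]+` adds and `[M-H]-` subtracts one proton mass (1.007276 Da).
#'
#' @param mass neutral monoisotopic mass (Da, > 0 for real molecules).
#' @param adduct `"[M+H]+"` or `"[M-H]-"`.
#' @return m/z of the singly charged adduct ion.
#' @export
adduct_mz <- function(mass, adduct) {
  adduct <- normalize_adduct(adduct)
  switch(adduct,
    "[M+H]+" = mass + .proton_mass,
    "[M-H]-" = mass - .proton_mass,
    stop("unsupported adduct: ", adduct)
  )
}

# Accept typographic variants ("[M + H]+", unicode minus).
normalize_adduct <- function(adduct) {
  a <- gsub("\\s", "", adduct)
  a <- gsub("−", "-", a)
  if (!a %in% c("[M+H]+", "[M-H]-"))
    stop("unsupported adduct: ", adduct)
  a
}

#' Ionization mode implied by an adduct
#' @param adduct adduct string.
#' @return `"positive"` or `"negative"`.
#' @export
adduct_mode <- function(adduct) {
  if (normalize_adduct(adduct) == "[M+H]+") "positive" else "negative"
}

#' Relative mass deviation in parts per million
#'
#' @param observed observed m/z (Da).
#' @param theoretical theoretical m/z (Da, > 0).
#' @return `|observed - theoretical| / theoretical * 1e6`.
#' @export
ppm_error <- function(observed, theoretical) {
  if (any(theoretical <= 0)) stop("theoretical m/z must be > 0")
  abs(observed - theoretical) / theoretical * 1e6
}

#' Construct an MS2 spectrum
#'
#' @param precursor_mz precursor ion m/z (Da).
#' @param mode ionization mode, `"positive"` or `"negative"`.
#' @param mz fragment m/z values (Da).
#' @param intensity fragment intensities (>= 0), same length as `mz`.
#' @return An object of class `ms2_spectrum` with peaks sorted by m/z.
#' @export
ms2_spectrum <- function(precursor_mz, mode, mz, intensity) {
  stopifnot(length(mz) == length(intensity), length(mz) >= 1)
  if (any(intensity < 0)) stop("fragment intensities must be >= 0")
  ord <- order(mz)
  structure(
    list(precursor_mz = precursor_mz, mode = mode,
         peaks = data.frame(mz = mz[ord], intensity = intensity[ord])),
    class = "ms2_spectrum"
  )
}

#' @export
print.ms2_spectrum <- function(x, ...) {
  cat("ms2_spectrum: precursor", format(x$precursor_mz), x$mode, "mode,",
      nrow(x$peaks), "fragments\n")
  invisible(x)
}

#' MS2 spectral similarity (square-root-intensity cosine)
#'
#' Fragments of the two spectra are paired greedily by ascending m/z
#' distance within `frag_tol` (each fragment used at most once; ties broken
#' toward the lower-m/z pair). The score is the cosine between
#' square-root-intensity vectors laid out over the union of matched pairs
#' and unmatched fragments, so missing fragments dilute the score rather
#' than being ignored. Symmetric in its arguments and invariant to uniform
#' intensity scaling.
#'
#' @param a,b `ms2_spectrum` objects.
#' @param frag_tol fragment m/z matching tolerance in Da (default 0.05, the
#'   MS2 ion tolerance used for library search).
#' @return Similarity score in \[0, 1\].
#' @export
spectral_similarity <- function(a, b, frag_tol = 0.05) {
  stopifnot(inherits(a, "ms2_spectrum"), inherits(b, "ms2_spectrum"))
  pa <- a$peaks
  pb <- b$peaks
  na <- nrow(pa)
  nb <- nrow(pb)
  # candidate pairs within tolerance, greedy by ascending |delta mz|
  dmat <- abs(outer(pa$mz, pb$mz, "-"))
  cand <- which(dmat <= frag_tol, arr.ind = TRUE)
  used_a <- logical(na)
  used_b <- logical(nb)
  match_a <- integer(0)
  match_b <- integer(0)
  if (nrow(cand) > 0) {
    d <- dmat[cand]
    # ties toward the lower-m/z pair
    ord <- order(d, pa$mz[cand[, 1]], pb$mz[cand[, 2]])
    for (k in ord) {
      i <- cand[k, 1]
      j <- cand[k, 2]
      if (!used_a[i] && !used_b[j]) {
        used_a[i] <- TRUE
        used_b[j] <- TRUE
        match_a <- c(match_a, i)
        match_b <- c(match_b, j)
      }
    }
  }
  sa <- sqrt(pa$intensity)
  sb <- sqrt(pb$intensity)
  # aligned vectors over matched dims + unmatched dims of each side
  va <- c(sa[match_a], sa[!used_a], rep(0, sum(!used_b)))
  vb <- c(sb[match_b], rep(0, sum(!used_a)), sb[!used_b])
  denom <- sqrt(sum(va^2)) * sqrt(sum(vb^2))
  if (denom == 0) return(0)
  min(1, max(0, sum(va * vb) / denom))
}

#' Match a feature to a reference standard
#'
#' Confirmation requires all three of the criteria used for the 21
#' reference-standard identifications: accurate mass within a
#' mode-dependent ppm tolerance of the theoretical adduct m/z (1 ppm
#' positive, 2 ppm negative), retention time within `rt_window`, and MS2
#' similarity at or above `score_min`. The standard's printed observed m/z
#' is not used for the mass gate; the theoretical adduct m/z computed from
#' its formula is.
#'
#' @param feature_mz observed feature m/z (Da).
#' @param feature_rt observed feature retention time (minutes).
#' @param feature_mode ionization mode of the feature.
#' @param feature_spectrum `ms2_spectrum` of the feature, or `NULL`.
#' @param standard a `reference_standard` (see
#'   [generate_reference_library()]).
#' @param rt_window maximum |RT shift| in minutes (default 2.0, the largest
#'   shift observed across the confirmed standards).
#' @param tol_pos,tol_neg ppm tolerances for positive / negative mode.
#' @param score_min minimum MS2 similarity score (default 0.7).
#' @param frag_tol fragment tolerance passed to [spectral_similarity()].
#' @param allow_no_ms2 if `TRUE`, a feature without an MS2 spectrum can be
#'   confirmed on mass + RT alone; by default MS2 evidence is required.
#' @return A one-row data.frame (`match_result`): standard name, ppm error,
#'   RT delta, MS2 score and the three gate flags plus `confirmed`.
#' @export
match_feature_to_standard <- function(feature_mz, feature_rt, feature_mode,
                                      feature_spectrum, standard,
                                      rt_window = 2.0,
                                      tol_pos = 1, tol_neg = 2,
                                      score_min = 0.7, frag_tol = 0.05,
                                      allow_no_ms2 = FALSE) {
  stopifnot(inherits(standard, "reference_standard"))
  if (feature_mode != standard$mode)
    stop("polarity mismatch: feature is ", feature_mode,
         ", standard '", standard$name, "' is ", standard$mode)
  theo <- adduct_mz(monoisotopic_mass(standard$formula), standard$adduct)
  ppm <- ppm_error(feature_mz, theo)
  tol <- if (feature_mode == "positive") tol_pos else tol_neg
  mass_ok <- ppm <= tol
  rt_delta <- feature_rt - standard$rt
  rt_ok <- abs(rt_delta) <= rt_window
  if (is.null(feature_spectrum)) {
    ms2_score <- NA_real_
    ms2_ok <- allow_no_ms2
  } else {
    ms2_score <- spectral_similarity(feature_spectrum, standard$spectrum,
                                     frag_tol = frag_tol)
    ms2_ok <- ms2_score >= score_min
  }
  data.frame(
    standard = standard$name,
    theoretical_mz = theo,
    ppm_error = ppm,
    rt_delta = rt_delta,
    ms2_score = ms2_score,
    mass_ok = mass_ok,
    rt_ok = rt_ok,
    ms2_ok = ms2_ok,
    confirmed = mass_ok && rt_ok && ms2_ok,
    stringsAsFactors = FALSE
  )
}

#' Confirm planted identities in a feature table against a library
#'
#' Runs [match_feature_to_standard()] for every feature that carries an MS2
#' spectrum, against every same-polarity standard, and keeps the best
#' (highest-scoring) match per feature.
#'
#' @param table a `feature_table` whose `spectra` attribute (named list of
#'   `ms2_spectrum`, names = feature ids) holds feature MS2 data.
#' @param library list of `reference_standard` objects.
#' @param ... tolerances forwarded to [match_feature_to_standard()].
#' @return data.frame of match results, one row per (feature, standard)
#'   best pairing; zero rows if nothing matches.
#' @export
identify_features <- function(table, library, ...) {
  spectra <- attr(table, "spectra")
  if (is.null(spectra) || length(spectra) == 0 || length(library) == 0)
    return(empty_match_results())
  out <- list()
  for (fid in names(spectra)) {
    i <- match(fid, table$features$feature_id)
    if (is.na(i)) next
    best <- NULL
    for (std in library) {
      if (std$mode != table$features$mode[i]) next
      res <- match_feature_to_standard(
        feature_mz = table$features$mz[i],
        feature_rt = table$features$rt[i],
        feature_mode = table$features$mode[i],
        feature_spectrum = spectra[[fid]],
        standard = std, ...
      )
      if (is.null(best) ||
          isTRUE(res$ms2_score > best$ms2_score))
        best <- res
    }
    if (!is.null(best)) {
      best$feature_id <- fid
      out[[fid]] <- best
    }
  }
  if (length(out) == 0) return(empty_match_results())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("feature_id", setdiff(names(res), "feature_id"))]
}

empty_match_results <- function() {
  data.frame(
    feature_id = character(0), standard = character(0),
    theoretical_mz = numeric(0), ppm_error = numeric(0),
    rt_delta = numeric(0), ms2_score = numeric(0),
    mass_ok = logical(0), rt_ok = logical(0), ms2_ok = logical(0),
    confirmed = logical(0), stringsAsFactors = FALSE
  )
}
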