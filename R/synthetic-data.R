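#' Configuration for the synthetic dialysis cohort generator
#'
#' Defaults emulate the three-arm study design: n = 10 healthy controls
#' (CTRL) and a matched cohort of 10 ESKD patients sampled before (PRE)
#' and after (POST) one hemodialysis session, with pooled QC injections
#' and blank injections. Planted effect classes follow the
#' dialysis-clearance taxonomy: category I (elevated pre-dialysis,
#' cleared by dialysis), category II (elevated, not cleared), category
#' III (decreased in ESKD). Default planted fractions (0.08 / 0.055 /
#' 0.022) reproduce the observed proportions of changed features among
#' all detected serum features.
#'
#' @param n_per_group samples per biological group (default 10).
#' @param n_features number of LC-MS features (default 2000).
#' @param frac_catI,frac_catII,frac_catIII planted fractions of features
#'   per category; must sum to <= 1 (remainder is unchanged).
#' @param effect_fc_up fold elevation of category I/II features in PRE vs
#'   CTRL (default 8); category III is reduced by the same fold.
#' @param clearance_fc fold reduction of category I features POST vs PRE
#'   (default 4).
#' @param noise_sigma residual SD on the log2 scale (default 0.25). The
#'   per-subject random effect shared by a patient's PRE and POST samples
#'   uses the same SD; QC-pool injection noise uses half of it.
#' @param n_qc pooled QC injections (default 3).
#' @param n_blank blank injections (default 3).
#' @param seed RNG seed.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_per_group = 10, n_features = 2000,
                         frac_catI = 0.08, frac_catII = 0.055,
                         frac_catIII = 0.022,
                         effect_fc_up = 8, clearance_fc = 4,
                         noise_sigma = 0.25, n_qc = 3, n_blank = 3,
                         seed = 1) {
  cfg <- list(
    n_per_group = n_per_group, n_features = n_features,
    frac_catI = frac_catI, frac_catII = frac_catII,
    frac_catIII = frac_catIII,
    effect_fc_up = effect_fc_up, clearance_fc = clearance_fc,
    noise_sigma = noise_sigma, n_qc = n_qc, n_blank = n_blank, seed = seed
  )
  counts <- c(cfg$n_per_group, cfg$n_features, cfg$n_qc, cfg$n_blank)
  if (any(counts < 0)) stop("counts must be >= 0")
  fracs <- c(cfg$frac_catI, cfg$frac_catII, cfg$frac_catIII)
  if (any(fracs < 0)) stop("category fractions must be >= 0")
  if (sum(fracs) > 1)
    stop("category fractions sum to ", sum(fracs), " (> 1): invalid config")
  if (cfg$effect_fc_up <= 0 || cfg$clearance_fc <= 0)
    stop("fold changes must be > 0")
  if (cfg$noise_sigma < 0) stop("noise_sigma must be >= 0")
  structure(cfg, class = "synth_config")
}

#' Generate a synthetic three-arm dialysis cohort with ground truth
#'
#' Intensities are log-normal: each feature has a baseline log2 mean, each
#' biological sample adds Gaussian noise on the log2 scale, and each ESKD
#' patient has a subject effect shared between their PRE and POST columns
#' (matched-pair structure). Planted effects: category I features gain
#' `log2(effect_fc_up)` in PRE vs CTRL and lose `log2(clearance_fc)` in
#' POST vs PRE; category II gains the elevation but is unchanged by
#' dialysis; category III is reduced by `log2(effect_fc_up)` in both PRE
#' and POST vs CTRL. QC columns are noisy re-injections of the pooled mean
#' of all biological samples; blank columns sit at 1/50 of the mean sample
#' intensity, so compliant features pass the default blank-ratio filter.
#' Peak width (8-30 scans) and S/N (10-100) are drawn so that default QC
#' thresholds retain every feature.
#'
#' If a reference `library` is supplied, planted elevated features (category
#' I first, then II) take the m/z, RT, ionization mode and MS2 spectrum of
#' successive standards; their spectra are attached as the `spectra`
#' attribute of the returned table and their names recorded in the ground
#' truth.
#'
#' @param config a [synth_config()].
#' @param library optional list of `reference_standard` objects to plant
#'   as identified features.
#' @return List with elements `table` (a [feature_table()]) and `truth`
#'   (data.frame: `feature_id`, `planted_category`,
#'   `planted_log2fc_pre_ctrl`, `planted_log2fc_post_pre`,
#'   `planted_identity`).
#' @export
generate_cohort <- function(config = synth_config(), library = NULL) {
  stopifnot(inherits(config, "synth_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)

  nf <- config$n_features
  n <- config$n_per_group
  n1 <- round(nf * config$frac_catI)
  n2 <- round(nf * config$frac_catII)
  n3 <- round(nf * config$frac_catIII)
  category <- rep(c("I", "II", "III", "unchanged"),
                  c(n1, n2, n3, nf - n1 - n2 - n3))

  up <- log2(config$effect_fc_up)
  clear <- log2(config$clearance_fc)
  d_pre <- ifelse(category %in% c("I", "II"), up,
                  ifelse(category == "III", -up, 0))
  d_post_pre <- ifelse(category == "I", -clear, 0)

  feature_id <- sprintf("F%04d", seq_len(nf))
  mz <- stats::runif(nf, 70, 1000)
  rt <- stats::runif(nf, 0.2, 45)
  mode <- sample(c("positive", "negative"), nf, replace = TRUE)
  spectra <- NULL
  identity <- rep(NA_character_, nf)
  if (!is.null(library) && length(library) > 0) {
    slots <- which(category %in% c("I", "II"))
    slots <- slots[seq_len(min(length(slots), length(library)))]
    spectra <- list()
    for (k in seq_along(slots)) {
      std <- library[[k]]
      i <- slots[k]
      mz[i] <- std$theoretical_mz
      rt[i] <- std$rt
      mode[i] <- std$mode
      identity[i] <- std$name
      spectra[[feature_id[i]]] <- std$spectrum
    }
  }

  mu <- stats::runif(nf, 12, 20)   # baseline log2 abundance
  sig <- config$noise_sigma
  rnoise <- function(nc) matrix(stats::rnorm(nf * nc, 0, sig), nf, nc)
  # per-subject, per-feature baseline shared between a patient's PRE and
  # POST columns: pairs the matched samples without coupling features
  subj <- rnoise(n)
  ctrl <- 2^(mu + rnoise(n))
  pre <- 2^(mu + d_pre + subj + rnoise(n))
  post <- 2^(mu + d_pre + d_post_pre + subj + rnoise(n))

  bio <- cbind(ctrl, pre, post)
  pooled <- rowMeans(bio)
  qc <- if (config$n_qc > 0)
    pooled * 2^matrix(stats::rnorm(nf * config$n_qc, 0, sig / 2),
                      nf, config$n_qc)
  else matrix(numeric(0), nf, 0)
  blank <- if (config$n_blank > 0)
    (pooled / 50) * 2^matrix(stats::rnorm(nf * config$n_blank, 0, sig / 2),
                             nf, config$n_blank)
  else matrix(numeric(0), nf, 0)

  samples <- data.frame(
    sample_id = c(sprintf("CTRL%02d", seq_len(n)),
                  sprintf("PRE%02d", seq_len(n)),
                  sprintf("POST%02d", seq_len(n)),
                  if (config$n_qc > 0) sprintf("QC%02d", seq_len(config$n_qc)),
                  if (config$n_blank > 0)
                    sprintf("BLANK%02d", seq_len(config$n_blank))),
    role = rep(c("CTRL", "PRE", "POST", "QC", "BLANK"),
               c(n, n, n, config$n_qc, config$n_blank)),
    subject = c(rep(NA_character_, n),
                sprintf("S%02d", seq_len(n)),
                sprintf("S%02d", seq_len(n)),
                rep(NA_character_, config$n_qc + config$n_blank)),
    stringsAsFactors = FALSE
  )

  features <- data.frame(
    feature_id = feature_id, mz = mz, rt = rt, mode = mode,
    peak_width = sample(8:30, nf, replace = TRUE),
    snr = stats::runif(nf, 10, 100),
    stringsAsFactors = FALSE
  )

  tab <- feature_table(features, cbind(bio, qc, blank), samples)
  attr(tab, "spectra") <- spectra

  truth <- data.frame(
    feature_id = feature_id,
    planted_category = category,
    planted_log2fc_pre_ctrl = d_pre,
    planted_log2fc_post_pre = d_post_pre,
    planted_identity = identity,
    stringsAsFactors = FALSE
  )
  list(table = tab, truth = truth)
}

#' Generate a synthetic TMT serum proteome with planted differentials
#'
#' Emulates a 15-channel TMT experiment (five channels per condition:
#' healthy, pre- and post-dialysis). The first `n_diff` proteins are
#' planted elevated by `fc` in both PRE and POST channels relative to
#' CTRL (hemodialysis barely alters circulating protein levels), with
#' log-normal reporter noise; the geometric-mean PRE/CTRL ratio of a
#' planted protein is `fc` in expectation. Defaults match the study
#' scale: 665 serum proteins, 83 differential.
#'
#' @param n_proteins total proteins (default 665).
#' @param n_diff planted differential proteins (default 83); must be
#'   <= `n_proteins`.
#' @param fc planted fold change (default 2).
#' @param n_channels_per_group TMT channels per condition (default 5).
#' @param noise_sigma log2-scale reporter SD (default 0.2).
#' @param seed RNG seed.
#' @return List with `table` (a `protein_quant`: intensity matrix,
#'   protein annotations, channel->group map) and `truth` (data.frame
#'   `accession`, `planted_diff`, `planted_log2fc`).
#' @export
generate_tmt_proteome <- function(n_proteins = 665, n_diff = 83, fc = 2,
                                  n_channels_per_group = 5,
                                  noise_sigma = 0.2, seed = 1) {
  if (n_diff > n_proteins) stop("n_diff must be <= n_proteins")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  k <- n_channels_per_group
  groups <- rep(c("CTRL", "PRE", "POST"), each = k)
  channels <- data.frame(
    channel_id = paste0(groups, rep(seq_len(k), 3)),
    group = groups, stringsAsFactors = FALSE
  )
  accession <- sprintf("P%05d", seq_len(n_proteins))
  gene <- sprintf("GENE%d", seq_len(n_proteins))
  planted <- seq_len(n_proteins) <= n_diff
  # log-normal abundance: serum protein intensities span orders of
  # magnitude with a dense core and sparse tails
  mu <- stats::rnorm(n_proteins, 18, 2)
  shift <- ifelse(planted, log2(fc), 0)
  logint <- matrix(mu, n_proteins, 3 * k) +
    outer(shift, ifelse(groups == "CTRL", 0, 1)) +
    matrix(stats::rnorm(n_proteins * 3 * k, 0, noise_sigma),
           n_proteins, 3 * k)
  intensity <- 2^logint
  rownames(intensity) <- accession
  colnames(intensity) <- channels$channel_id
  table <- protein_quant(
    intensity = intensity,
    proteins = data.frame(accession = accession, gene = gene,
                          stringsAsFactors = FALSE),
    channels = channels
  )
  truth <- data.frame(
    accession = accession, planted_diff = planted,
    planted_log2fc = shift, stringsAsFactors = FALSE
  )
  list(table = table, truth = truth)
}

#' Generate a synthetic metabolite-protein association edge table
#'
#' Emulates a STITCH-style extract: every planted pair is present with a
#' high confidence score; each remaining metabolite x protein pair is
#' included independently with probability `density` and a random score
#' in (0, 1].
#'
#' @param metabolite_ids,protein_ids node vocabularies.
#' @param density probability of a random (non-planted) edge, in `[0,1]`.
#' @param planted_pairs optional data.frame with columns `chemical` and
#'   `protein`; always included with score 0.95.
#' @param seed RNG seed.
#' @return data.frame with STITCH-dialect columns `chemical`, `protein`,
#'   `combined_score`.
#' @export
generate_association_edges <- function(metabolite_ids, protein_ids,
                                       density = 0.02,
                                       planted_pairs = NULL, seed = 1) {
  stopifnot(density >= 0, density <= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  grid <- expand.grid(chemical = metabolite_ids, protein = protein_ids,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  keep <- stats::runif(nrow(grid)) < density
  edges <- grid[keep, , drop = FALSE]
  edges$combined_score <- stats::runif(nrow(edges), 0.15, 1)
  if (!is.null(planted_pairs) && nrow(planted_pairs) > 0) {
    planted <- data.frame(chemical = planted_pairs$chemical,
                          protein = planted_pairs$protein,
                          combined_score = 0.95,
                          stringsAsFactors = FALSE)
    edges <- rbind(planted, edges)
    # planted score wins for duplicated pairs
    edges <- edges[!duplicated(edges[, c("chemical", "protein")]), ,
                   drop = FALSE]
  }
  rownames(edges) <- NULL
  edges
}

#' Generate synthetic pathway sets (GMT-style)
#'
#' Random compound sets over a universe, optionally with one planted set
#' concentrated in a supplied query so that enrichment ranks it first.
#'
#' @param universe character vector of compound identifiers.
#' @param n_sets number of random pathway sets (default 10).
#' @param set_size members per random set (default 10).
#' @param planted optional character vector: members of a planted
#'   enriched set, included as `planted_name`.
#' @param planted_name name for the planted set.
#' @param seed RNG seed.
#' @return Named list of character vectors.
#' @export
generate_pathway_sets <- function(universe, n_sets = 10, set_size = 10,
                                  planted = NULL,
                                  planted_name = "planted_pathway",
                                  seed = 1) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  sets <- lapply(seq_len(n_sets), function(i) {
    sample(universe, min(set_size, length(universe)))
  })
  names(sets) <- sprintf("pathway_%02d", seq_len(n_sets))
  if (!is.null(planted)) sets[[planted_name]] <- unique(planted)
  sets
}

#' Generate a synthetic dose-viability table
#'
#' Responses follow a four-parameter logistic curve
#' `bottom + (top - bottom) / (1 + (dose/ic50)^hill)` plus Gaussian
#' noise, emulating a WST-1 viability assay normalized to vehicle
#' control. The default dose series is the study's dilution ladder
#' (100, 10, 1, 0.1, 0.01 uM) with five replicates.
#'
#' @param ic50 half-maximal concentration (uM, > 0).
#' @param hill Hill slope (positive = viability falls with dose).
#' @param top,bottom upper/lower viability asymptotes.
#' @param doses dose series in uM, all > 0.
#' @param n_replicates replicates per dose (default 5).
#' @param noise_sd Gaussian response noise SD (default 0).
#' @param compound compound label.
#' @param seed RNG seed.
#' @return data.frame with columns `compound`, `dose_uM`, `replicate`,
#'   `response`.
#' @export
generate_dose_response <- function(ic50, hill = 1, top = 1, bottom = 0,
                                   doses = c(100, 10, 1, 0.1, 0.01),
                                   n_replicates = 5, noise_sd = 0,
                                   compound = "compound", seed = 1) {
  stopifnot(ic50 > 0, all(doses > 0))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  grid <- expand.grid(replicate = seq_len(n_replicates), dose_uM = doses,
                      KEEP.OUT.ATTRS = FALSE)
  y <- four_param_logistic(grid$dose_uM, top, bottom, hill, ic50)
  data.frame(
    compound = compound,
    dose_uM = grid$dose_uM,
    replicate = grid$replicate,
    response = y + stats::rnorm(nrow(grid), 0, noise_sd)
  )
}
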