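#' Pipeline configuration with study-default thresholds
#'
#' Collects every stage threshold at its study default: QC filters
#' (CV 50, blank ratio 5, S/N 3, width 6 scans), differential thresholds
#' (p 0.05, FDR 0.05, metabolite FC 2, protein FC 1.5, highlighted-solute
#' FC 5), clearance FC 2, identification tolerances (1 ppm positive,
#' 2 ppm negative, RT window 2 min, MS2 score 0.7), and network score
#' cutoff 0.4. Override any element by name; `yaml_path` loads overrides
#' from a YAML file first (requires the `yaml` package).
#'
#' @param ... named overrides of the defaults.
#' @param yaml_path optional YAML file with overrides.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(..., yaml_path = NULL) {
  cfg <- list(
    seed = 1,
    synth = list(),                 # overrides for synth_config()
    cv_max = 50, blank_ratio_min = 5, snr_min = 3, peak_width_min = 6,
    alpha = 0.05, q_alpha = 0.05,
    elev_fc = 2, clear_fc = 2, protein_fc = 1.5, highlight_fc = 5,
    ppm_pos = 1, ppm_neg = 2, rt_window = 2.0, score_min = 0.7,
    edge_score_min = 0.4,
    n_pathways = 10, pathway_size = 10,
    out_dir = NULL
  )
  if (!is.null(yaml_path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml package required for yaml_path")
    cfg <- utils::modifyList(cfg, yaml::read_yaml(yaml_path))
  }
  overrides <- list(...)
  if (length(overrides) > 0) {
    bad <- setdiff(names(overrides), names(cfg))
    if (length(bad) > 0)
      stop("unknown config key(s): ", paste(bad, collapse = ", "))
    cfg <- utils::modifyList(cfg, overrides)
  }
  structure(cfg, class = "pipeline_config")
}

#' Run the full synthetic-cohort pipeline end to end
#'
#' Stages: simulate (cohort with planted reference standards, TMT
#' proteome, association edges, pathway sets) -> feature QC -> median
#' normalization -> differential testing of the three contrasts ->
#' dialysis-clearance classification -> reference-standard confirmation
#' -> differential proteins -> pathway over-representation of elevated
#' identified metabolites -> metabolite-protein disease network. Each
#' stage writes a TSV under `out_dir`; a JSON summary and a plain-text
#' log (thresholds, seed, versions) complete the run directory.
#'
#' @param config a [pipeline_config()].
#' @return List with all stage outputs (`cohort`, `qc`, `records`,
#'   `calls`, `summary`, `matches`, `proteins`, `enrichment`, `network`)
#'   plus `summary_json` (the written summary as a list).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  if (is.null(out_dir))
    out_dir <- file.path(tempdir(),
                         paste0("uremicomics_run_", config$seed))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "simulate"
  result <- tryCatch({
    # --- simulate ---------------------------------------------------
    library <- generate_reference_library(seed = config$seed)
    synth_args <- utils::modifyList(list(seed = config$seed), config$synth)
    scfg <- do.call(synth_config, synth_args)
    cohort <- generate_cohort(scfg, library = library)
    proteome <- generate_tmt_proteome(seed = config$seed)
    write_feature_table(cohort$table,
                        file.path(out_dir, "features_raw.tsv"),
                        file.path(out_dir, "sample_roles.tsv"))
    write_ground_truth(cohort$truth,
                       file.path(out_dir, "ground_truth_features.tsv"))
    spectra <- attr(cohort$table, "spectra")
    if (!is.null(spectra) && length(spectra) > 0)
      write_mgf(spectra, file.path(out_dir, "feature_spectra.mgf"))
    write_msp(library, file.path(out_dir, "standards.msp"))

    # --- feature QC -------------------------------------------------
    stage <- "qc"
    thresholds <- filter_thresholds(
      cv_max = config$cv_max, blank_ratio_min = config$blank_ratio_min,
      snr_min = config$snr_min, peak_width_min = config$peak_width_min
    )
    qc <- apply_feature_filters(cohort$table, thresholds)
    write_feature_table(qc$table,
                        file.path(out_dir, "features_filtered.tsv"),
                        file.path(out_dir, "sample_roles.tsv"))

    # --- differential -----------------------------------------------
    stage <- "diff"
    normalized <- normalize_intensities(qc$table)
    records <- run_differential(normalized)
    utils::write.table(records, file.path(out_dir, "differential.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    # --- classify ---------------------------------------------------
    stage <- "classify"
    calls <- classify_features(records, elev_fc = config$elev_fc,
                               clear_fc = config$clear_fc,
                               alpha = config$alpha,
                               q_alpha = config$q_alpha)
    summary <- summarize_categories(calls)
    utils::write.table(calls, file.path(out_dir, "category_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    # --- identify ---------------------------------------------------
    stage <- "identify"
    matches <- identify_features(normalized, library,
                                 rt_window = config$rt_window,
                                 tol_pos = config$ppm_pos,
                                 tol_neg = config$ppm_neg,
                                 score_min = config$score_min)
    utils::write.table(matches, file.path(out_dir, "identifications.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    # --- proteomics -------------------------------------------------
    stage <- "proteo"
    proteins <- test_differential_proteins(
      proteome$table, fc_min = config$protein_fc, alpha = config$alpha,
      q_alpha = config$q_alpha
    )
    utils::write.table(proteins,
                       file.path(out_dir, "differential_proteins.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    # --- enrichment -------------------------------------------------
    stage <- "enrich"
    # ORA of elevated metabolites over all classified features; the
    # synthetic pathway sets include one planted set drawn from the query
    universe <- calls$feature_id
    query <- calls$feature_id[calls$category %in% c("I", "II")]
    enrichment <- NULL
    if (length(query) > 0 && length(universe) > 1) {
      pathways <- generate_pathway_sets(
        universe, n_sets = config$n_pathways,
        set_size = config$pathway_size,
        planted = query[seq_len(min(15, length(query)))],
        seed = config$seed
      )
      enrichment <- enrich_all(query, pathways, universe)
      utils::write.table(enrichment, file.path(out_dir, "enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }

    # --- network ----------------------------------------------------
    stage <- "network"
    diff_prot <- proteins$accession[proteins$flag != "ns"]
    elevated_ids <- calls$feature_id[calls$category %in% c("I", "II")]
    edges <- generate_association_edges(
      metabolite_ids = elevated_ids,
      protein_ids = proteins$accession,
      density = 0.001,
      planted_pairs = if (length(elevated_ids) > 0 && length(diff_prot) > 0)
        data.frame(
          chemical = rep(elevated_ids[1],
                         min(6, length(diff_prot))),
          protein = diff_prot[seq_len(min(6, length(diff_prot)))]
        )
      else NULL,
      seed = config$seed
    )
    write_edges(edges, file.path(out_dir, "association_edges.tsv"))
    edges_kept <- clean_edges(edges, config$edge_score_min)
    network <- build_disease_network(elevated_ids, diff_prot, edges_kept)
    export_network(network, file.path(out_dir, "disease_network.sif"),
                   format = "sif")
    export_network(network, file.path(out_dir, "disease_network.graphml"),
                   format = "graphml")

    # --- summary + log ----------------------------------------------
    stage <- "summary"
    summary_json <- list(
      seed = config$seed,
      n_features_input = qc$report$n_input,
      n_features_surviving = qc$report$n_surviving,
      category_counts = as.list(summary$counts),
      total_changed = summary$total_changed,
      category_fractions = as.list(summary$fractions),
      n_confirmed_standards = sum(matches$confirmed),
      n_differential_proteins = length(diff_prot),
      network_nodes = nrow(network$nodes),
      network_edges = nrow(network$edges)
    )
    jsonlite::write_json(summary_json, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(c(
      paste("uremicomics", as.character(utils::packageVersion("uremicomics"))),
      R.version.string,
      paste("seed:", config$seed),
      paste("thresholds:",
            paste(sprintf("%s=%s",
                          setdiff(names(config), c("synth", "out_dir")),
                          vapply(config[setdiff(names(config),
                                                c("synth", "out_dir"))],
                                 function(v) paste(format(v), collapse = ","),
                                 character(1))),
                  collapse = " "))
    ), file.path(out_dir, "run_log.txt"))

    list(out_dir = out_dir, cohort = cohort, qc = qc, records = records,
         calls = calls, summary = summary, matches = matches,
         proteins = proteins, enrichment = enrichment, network = network,
         summary_json = summary_json)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  result
}
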