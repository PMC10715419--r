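#!/usr/bin/env Rscript
# Simulate every input of the hemodialysis multi-omics analysis with
# known ground truth: a three-arm LC-MS feature cohort (10 healthy
# controls, 10 matched ESKD patients pre- and post-dialysis, pooled QC
# and blank injections) with 21 reference standards planted among the
# elevated features, a 15-channel TMT serum proteome (665 proteins, 83
# planted 2-fold up), and the reference-standard MSP library.
#
# Usage: Rscript analysis/01_simulate.R [seed]   (default seed 1)

suppressMessages(library(uremicomics))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 1L
out <- "results/analysis"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

library <- generate_reference_library(seed = seed)
cohort <- generate_cohort(synth_config(seed = seed), library = library)
proteome <- generate_tmt_proteome(seed = seed)

write_feature_table(cohort$table,
                    file.path(out, "features_raw.tsv"),
                    file.path(out, "sample_roles.tsv"))
write_ground_truth(cohort$truth, file.path(out, "ground_truth_features.tsv"))
write_mgf(attr(cohort$table, "spectra"), file.path(out, "feature_spectra.mgf"))
write_msp(library, file.path(out, "standards.msp"))
write_protein_quant(proteome$table,
                    file.path(out, "proteome_raw.tsv"),
                    file.path(out, "proteome_channels.tsv"))
write_ground_truth(proteome$truth,
                   file.path(out, "ground_truth_proteins.tsv"))

cat(sprintf(
  "Simulated (seed %d): %d features x %d samples (%s planted I/II/III),\n  %d-standard library, %d proteins x 15 TMT channels (%d planted up).\n",
  seed, nrow(cohort$table$features), nrow(cohort$table$samples),
  paste(table(cohort$truth$planted_category)[c("I", "II", "III")],
        collapse = "/"),
  length(library), nrow(proteome$table$proteins),
  sum(proteome$truth$planted_diff)))
cat("Inputs written under", out, "\n")
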