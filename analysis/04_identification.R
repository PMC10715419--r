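#!/usr/bin/env Rscript
# Confirm candidate features against the reference-standard library by
# accurate mass (1 ppm positive / 2 ppm negative vs the theoretical
# adduct m/z), retention time (2-min window) and MS2 spectral similarity
# (sqrt-intensity cosine >= 0.7).
#
# Usage: Rscript analysis/04_identification.R

suppressMessages(library(uremicomics))
out <- "results/analysis"

tab <- read_feature_table(file.path(out, "features_filtered.tsv"),
                          file.path(out, "sample_roles.tsv"))
attr(tab, "spectra") <- read_mgf(file.path(out, "feature_spectra.mgf"))
library <- read_msp(file.path(out, "standards.msp"))

matches <- identify_features(tab, library)
write.table(matches, file.path(out, "identifications.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("Confirmed %d/%d features with MS2 evidence against %d standards.\n",
            sum(matches$confirmed), nrow(matches), length(library)))
cat(sprintf("Median |ppm error| %.3g, median MS2 score %.3f.\n",
            median(matches$ppm_error), median(matches$ms2_score)))
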