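#!/usr/bin/env Rscript
# Feature-level quality control: remove unstable features (CV >= 50% over
# pooled-QC injections), features near blank level (sample/blank <= 5),
# low signal-to-noise (<= 3) and narrow peaks (< 6 scans), then median-
# normalize the surviving intensities.
#
# Usage: Rscript analysis/02_feature_qc.R

suppressMessages(library(uremicomics))
out <- "results/analysis"

tab <- read_feature_table(file.path(out, "features_raw.tsv"),
                          file.path(out, "sample_roles.tsv"))
attr(tab, "spectra") <- read_mgf(file.path(out, "feature_spectra.mgf"))

qc <- apply_feature_filters(tab, filter_thresholds())
r <- qc$report
cat(sprintf(
  "QC: %d/%d features survive (removed: CV %d, blank ratio %d, S/N %d, peak width %d; rules overlap).\n",
  r$n_surviving, r$n_input, r$removed_by_cv, r$removed_by_blank_ratio,
  r$removed_by_snr, r$removed_by_peak_width))

normalized <- normalize_intensities(qc$table)
write_feature_table(normalized,
                    file.path(out, "features_filtered.tsv"),
                    file.path(out, "sample_roles.tsv"))
cat("Median-normalized filtered table written.\n")
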