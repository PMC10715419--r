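#!/usr/bin/env Rscript
# TMT serum proteomics: log2-transform and quantile-normalize the
# 15-channel reporter intensities, then call differential proteins
# pre-dialysis vs healthy control at FC > 1.5, p < 0.05, FDR < 0.05.
#
# Usage: Rscript analysis/05_proteomics.R

suppressMessages(library(uremicomics))
out <- "results/analysis"

proteome <- read_protein_quant(file.path(out, "proteome_raw.tsv"),
                               file.path(out, "proteome_channels.tsv"))
res <- test_differential_proteins(proteome)
write.table(res, file.path(out, "differential_proteins.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

truth <- read.delim(file.path(out, "ground_truth_proteins.tsv"))
truth <- truth[match(res$accession, truth$accession), ]
cat(sprintf("Differential proteins: %d up, %d down of %d.\n",
            sum(res$flag == "up"), sum(res$flag == "down"), nrow(res)))
cat(sprintf("Recall of planted 2-fold proteins: %.1f%% (FPR %.2f%%).\n",
            100 * mean(res$flag[truth$planted_diff] == "up"),
            100 * mean(res$flag[!truth$planted_diff] != "ns")))
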