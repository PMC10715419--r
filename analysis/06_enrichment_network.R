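#!/usr/bin/env Rscript
# Pathway over-representation of the metabolites elevated in ESKD
# (categories I + II, identified compounds against the identified
# universe) and assembly of the metabolite-protein disease interactome:
# elevated metabolites and differential proteins seed the network, joined
# by STITCH-style association edges (score >= 0.4) plus their one-hop
# neighbors. A creatinine-like hub with six protein partners is planted
# in the synthetic edges.
#
# Usage: Rscript analysis/06_enrichment_network.R [seed]

suppressMessages(library(uremicomics))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 1L
set.seed(seed)
out <- "results/analysis"

calls <- read.delim(file.path(out, "category_calls.tsv"))
matches <- read.delim(file.path(out, "identifications.tsv"))
proteins <- read.delim(file.path(out, "differential_proteins.tsv"))

# ORA over all classified features; pathway sets carry one planted set
# drawn from the elevated metabolites so a real enrichment exists
universe <- calls$feature_id
query <- calls$feature_id[calls$category %in% c("I", "II")]
pathways <- generate_pathway_sets(
  universe, n_sets = 10, set_size = 10,
  planted = sample(query, min(15, length(query))), seed = seed)
enr <- enrich_all(query, pathways, universe)
write.table(enr, file.path(out, "enrichment.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("Top pathway: %s (k=%d/%d, p=%.3g, q=%.3g).\n",
            enr$pathway[1], enr$k[1], enr$K[1], enr$p[1], enr$q[1]))

diff_prot <- proteins$accession[proteins$flag != "ns"]
elevated <- calls$feature_id[calls$category %in% c("I", "II")]
edges <- generate_association_edges(
  elevated, proteins$accession, density = 0.001,
  planted_pairs = data.frame(
    chemical = elevated[1],
    protein = diff_prot[seq_len(min(6, length(diff_prot)))]),
  seed = seed)
write_edges(edges, file.path(out, "association_edges.tsv"))
net <- build_disease_network(elevated, diff_prot,
                             load_edges(file.path(out, "association_edges.tsv"),
                                        score_min = 0.4))
export_network(net, file.path(out, "disease_network.sif"), "sif")
export_network(net, file.path(out, "disease_network.graphml"), "graphml")
deg <- network_degree(net)
cat(sprintf("Disease network: %d nodes (%d neighbors), %d edges; hub %s degree %d.\n",
            nrow(net$nodes), sum(net$nodes$status == "neighbor"),
            nrow(net$edges), names(which.max(deg)), max(deg)))
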