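#' Load metabolite-protein association edges from a STITCH-style TSV
#'
#' Expects columns `chemical`, `protein`, `combined_score`. Edges below
#' `score_min` are dropped; duplicate pairs are collapsed keeping the
#' maximum score; self loops are rejected. The default cutoff 0.4 is the
#' conventional medium-confidence threshold for such association scores.
#'
#' @param path TSV file path.
#' @param score_min minimum combined score (default 0.4).
#' @return data.frame of `association_edge` rows: `chemical`, `protein`,
#'   `combined_score`.
#' @export
load_edges <- function(path, score_min = 0.4) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("chemical", "protein", "combined_score")
  if (!all(needed %in% names(df)))
    stop("edge file must have columns: ", paste(needed, collapse = ", "))
  bad <- which(is.na(df$combined_score) | df$chemical == "" |
                 df$protein == "")
  if (length(bad) > 0)
    stop("malformed edge row at line ", bad[1] + 1)
  clean_edges(df, score_min)
}

# Score filter + duplicate collapse (max score) + self-loop check,
# shared by load_edges and build_disease_network.
clean_edges <- function(edges, score_min = 0) {
  if (any(edges$chemical == edges$protein))
    stop("self loop in edge table")
  edges <- edges[edges$combined_score >= score_min, , drop = FALSE]
  if (nrow(edges) == 0) {
    rownames(edges) <- NULL
    return(edges)
  }
  key <- paste(edges$chemical, edges$protein, sep = "\r")
  best <- tapply(edges$combined_score, key, max)
  first <- !duplicated(key)
  out <- edges[first, , drop = FALSE]
  out$combined_score <- as.numeric(best[paste(out$chemical, out$protein,
                                              sep = "\r")])
  out <- out[order(out$chemical, out$protein), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble the disease interactome subnetwork
#'
#' Joins the seed sets — metabolites elevated in ESKD (categories I + II)
#' and differential serum proteins — with a metabolite-protein edge table.
#' Seeds are always retained, even when isolated. With
#' `include_neighbors = TRUE` every node exactly one hop from a seed is
#' added with status `neighbor`; edges are then restricted to the
#' retained node set.
#'
#' @param metabolite_ids seed metabolite identifiers.
#' @param protein_ids seed protein identifiers.
#' @param edges data.frame as returned by [load_edges()].
#' @param include_neighbors add one-hop neighbors (default TRUE).
#' @param metabolite_status,protein_status seed status labels (e.g.
#'   `"seed-up"` / `"seed-down"`), recycled over the seed vectors.
#' @return A `disease_network`: list with `nodes` (data.frame `id`,
#'   `kind`, `status`) and `edges` (chemical, protein, combined_score).
#' @export
build_disease_network <- function(metabolite_ids, protein_ids, edges,
                                  include_neighbors = TRUE,
                                  metabolite_status = "seed-up",
                                  protein_status = "seed-up") {
  edges <- clean_edges(edges)
  seeds <- data.frame(
    id = c(metabolite_ids, protein_ids),
    kind = rep(c("metabolite", "protein"),
               c(length(metabolite_ids), length(protein_ids))),
    status = c(rep_len(metabolite_status, length(metabolite_ids)),
               rep_len(protein_status, length(protein_ids))),
    stringsAsFactors = FALSE
  )
  seeds <- seeds[!duplicated(seeds$id), , drop = FALSE]
  touches_seed <- edges$chemical %in% seeds$id | edges$protein %in% seeds$id
  nodes <- seeds
  if (include_neighbors) {
    adj <- edges[touches_seed, , drop = FALSE]
    nb_chem <- setdiff(adj$chemical, seeds$id)
    nb_prot <- setdiff(adj$protein, seeds$id)
    if (length(nb_chem) + length(nb_prot) > 0) {
      nodes <- rbind(nodes, data.frame(
        id = c(nb_chem, nb_prot),
        kind = rep(c("metabolite", "protein"),
                   c(length(nb_chem), length(nb_prot))),
        status = "neighbor", stringsAsFactors = FALSE
      ))
    }
  }
  # induced subgraph on the retained node set
  keep <- edges$chemical %in% nodes$id & edges$protein %in% nodes$id
  net_edges <- edges[keep, , drop = FALSE]
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  rownames(nodes) <- rownames(net_edges) <- NULL
  structure(list(nodes = nodes, edges = net_edges),
            class = "disease_network")
}

#' @export
print.disease_network <- function(x, ...) {
  cat("disease_network:", nrow(x$nodes), "nodes,",
      nrow(x$edges), "edges\n")
  st <- table(x$nodes$status)
  cat("  status:", paste(names(st), st, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Node degrees of a disease network
#' @param net a `disease_network`.
#' @return Named integer vector over all nodes.
#' @export
network_degree <- function(net) {
  d <- table(c(net$edges$chemical, net$edges$protein))
  out <- stats::setNames(integer(nrow(net$nodes)), net$nodes$id)
  out[names(d)] <- as.integer(d)
  out
}

#' Export / import a disease network
#'
#' Formats: `sif` (one line per edge `source interacts target`, plus one
#' line per isolated node), `graphml` (via igraph, node attributes
#' preserved), `tsv` (edge table plus a `<path>.nodes.tsv` sidecar).
#' `read_network()` round-trips all three: node and edge sets are
#' recovered exactly (SIF drops `kind`/`status`/score annotations, which
#' is inherent to the format).
#'
#' @param net a `disease_network`.
#' @param path output path.
#' @param format `"sif"`, `"graphml"`, or `"tsv"`.
#' @return `export_network` returns `path` invisibly; `read_network`
#'   returns a `disease_network` (with `NA` annotations for SIF).
#' @export
export_network <- function(net, path, format = c("sif", "graphml", "tsv")) {
  format <- match.arg(format)
  if (format == "sif") {
    deg <- network_degree(net)
    edge_lines <- if (nrow(net$edges) > 0)
      paste(net$edges$chemical, "interacts", net$edges$protein, sep = "\t")
    else character(0)
    isolated <- net$nodes$id[deg[net$nodes$id] == 0]
    writeLines(c(edge_lines, isolated), path)
  } else if (format == "graphml") {
    g <- igraph::graph_from_data_frame(
      d = if (nrow(net$edges) > 0)
        data.frame(from = net$edges$chemical, to = net$edges$protein,
                   combined_score = net$edges$combined_score)
      else data.frame(from = character(0), to = character(0),
                      combined_score = numeric(0)),
      directed = FALSE, vertices = net$nodes
    )
    igraph::write_graph(g, path, format = "graphml")
  } else {
    utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(net$nodes, paste0(path, ".nodes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname export_network
#' @export
read_network <- function(path, format = c("sif", "graphml", "tsv")) {
  format <- match.arg(format)
  if (format == "sif") {
    lines <- readLines(path)
    parts <- strsplit(lines, "\t")
    is_edge <- lengths(parts) == 3
    edges <- data.frame(
      chemical = vapply(parts[is_edge], `[`, character(1), 1),
      protein = vapply(parts[is_edge], `[`, character(1), 3),
      combined_score = NA_real_, stringsAsFactors = FALSE
    )
    ids <- sort(unique(c(edges$chemical, edges$protein,
                         unlist(parts[!is_edge]))))
    nodes <- data.frame(id = ids, kind = NA_character_,
                        status = NA_character_, stringsAsFactors = FALSE)
  } else if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    vattr <- igraph::as_data_frame(g, what = "vertices")
    eattr <- igraph::as_data_frame(g, what = "edges")
    nodes <- data.frame(id = vattr$name, kind = vattr$kind,
                        status = vattr$status, stringsAsFactors = FALSE)
    edges <- data.frame(chemical = eattr$from, protein = eattr$to,
                        combined_score = eattr$combined_score,
                        stringsAsFactors = FALSE)
  } else {
    edges <- utils::read.delim(path, stringsAsFactors = FALSE,
                               colClasses = c(chemical = "character",
                                              protein = "character"))
    nodes <- utils::read.delim(paste0(path, ".nodes.tsv"),
                               stringsAsFactors = FALSE)
  }
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  if (nrow(edges) > 0)
    edges <- edges[order(edges$chemical, edges$protein), , drop = FALSE]
  rownames(nodes) <- rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "disease_network")
}
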