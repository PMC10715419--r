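edge_df <- function(...) {
  rows <- list(...)
  data.frame(
    chemical = vapply(rows, `[[`, character(1), 1),
    protein = vapply(rows, `[[`, character(1), 2),
    combined_score = vapply(rows, function(r) as.numeric(r[[3]]), numeric(1)),
    stringsAsFactors = FALSE
  )
}

test_that("edge loading filters by score and collapses duplicates to the max", {
  path <- tempfile(fileext = ".tsv")
  write_edges(edge_df(list("m1", "p1", 0.4), list("m1", "p1", 0.9),
                      list("m2", "p2", 0.3)), path)
  edges <- load_edges(path, score_min = 0.5)
  expect_equal(nrow(edges), 1)
  expect_equal(edges$combined_score, 0.9)
  all_edges <- load_edges(path, score_min = 0)
  expect_equal(nrow(all_edges), 2)
  # empty file (header only)
  empty_path <- tempfile(fileext = ".tsv")
  write_edges(edge_df()[0, ], empty_path)
  expect_equal(nrow(load_edges(empty_path, 0)), 0)
})

test_that("one-hop construction labels seeds and neighbors correctly", {
  edges <- edge_df(list("m1", "p1", 0.8), list("m9", "p9", 0.8))
  net <- build_disease_network("m1", character(0), edges)
  expect_setequal(net$nodes$id, c("m1", "p1"))
  expect_equal(net$nodes$status[net$nodes$id == "p1"], "neighbor")
  expect_equal(nrow(net$edges), 1)
  # seeds retained even when isolated
  net2 <- build_disease_network(c("m1", "lonely"), character(0), edges)
  expect_true("lonely" %in% net2$nodes$id)
  expect_equal(unname(network_degree(net2)["lonely"]), 0L)
  # neighbors off: induced subgraph on seeds only
  net3 <- build_disease_network("m1", character(0), edges,
                                include_neighbors = FALSE)
  expect_equal(net3$nodes$id, "m1")
  expect_equal(nrow(net3$edges), 0)
})

test_that("a planted creatinine-like hub keeps its six protein partners", {
  partners <- c("CST3", "MB", "ALB", "ACE", "CFH", "CACNA2D1")
  planted <- data.frame(chemical = "creatinine", protein = partners)
  edges <- generate_association_edges("creatinine", c(partners, "OTHER"),
                                      density = 0, planted_pairs = planted,
                                      seed = 71)
  net <- build_disease_network("creatinine", character(0), edges)
  expect_equal(unname(network_degree(net)["creatinine"]), 6L)
})

test_that("network is independent of edge-row order and one hop exactly", {
  set.seed(72)
  edges <- generate_association_edges(sprintf("m%02d", 1:15),
                                      sprintf("p%02d", 1:15),
                                      density = 0.15, seed = 72)
  seeds_m <- c("m01", "m02")
  seeds_p <- "p01"
  net <- build_disease_network(seeds_m, seeds_p, edges)
  net_shuffled <- build_disease_network(
    seeds_m, seeds_p, edges[sample(nrow(edges)), ])
  expect_equal(net, net_shuffled)
  # every neighbor is adjacent to >= 1 seed; nothing further away appears
  seeds <- c(seeds_m, seeds_p)
  nb <- net$nodes$id[net$nodes$status == "neighbor"]
  adjacency <- paste(edges$chemical, edges$protein)
  touches_seed <- function(v) {
    any(edges$chemical == v & edges$protein %in% seeds) ||
      any(edges$protein == v & edges$chemical %in% seeds)
  }
  expect_true(all(vapply(nb, touches_seed, logical(1))))
  # removing a seed never adds nodes
  net_smaller <- build_disease_network(seeds_m[1], seeds_p, edges)
  expect_true(all(net_smaller$nodes$id %in% net$nodes$id))
})

test_that("exports round-trip nodes and edges across formats", {
  edges <- generate_association_edges(sprintf("m%d", 1:6),
                                      sprintf("p%d", 1:6),
                                      density = 0.3, seed = 73)
  net <- build_disease_network(c("m1", "m2", "isolated"), "p1", edges)
  # SIF: line count = edges + isolated nodes; ids round-trip
  sif <- tempfile(fileext = ".sif")
  export_network(net, sif, "sif")
  deg <- network_degree(net)
  expect_length(readLines(sif), nrow(net$edges) + sum(deg == 0))
  back_sif <- read_network(sif, "sif")
  expect_setequal(back_sif$nodes$id, net$nodes$id)
  expect_equal(back_sif$edges[, c("chemical", "protein")],
               net$edges[, c("chemical", "protein")])
  # GraphML preserves annotations
  gml <- tempfile(fileext = ".graphml")
  export_network(net, gml, "graphml")
  back_gml <- read_network(gml, "graphml")
  expect_equal(back_gml$nodes, net$nodes)
  expect_equal(back_gml$edges$combined_score, net$edges$combined_score,
               tolerance = 1e-9)
  # TSV round-trips everything
  tsv <- tempfile(fileext = ".tsv")
  export_network(net, tsv, "tsv")
  back_tsv <- read_network(tsv, "tsv")
  expect_equal(back_tsv$nodes, net$nodes)
  expect_equal(back_tsv$edges, net$edges, tolerance = 1e-9)
  # empty network still exports
  empty <- build_disease_network(character(0), character(0), edges[0, ])
  sif2 <- tempfile(fileext = ".sif")
  export_network(empty, sif2, "sif")
  expect_length(readLines(sif2), 0)
  expect_error(export_network(net, tempfile(), "dot"), "arg")
})
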