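#' Hypergeometric over-representation test for one pathway set
#'
#' Upper-tail hypergeometric probability of drawing at least `k` pathway
#' members in a query of size `n` from a universe of size `N` containing
#' `K` pathway members (the standard ORA convention). The pathway is
#' intersected with the universe before testing; the query must be a
#' subset of the universe.
#'
#' @param query character vector of query identifiers (e.g. metabolites
#'   elevated in ESKD, categories I + II).
#' @param pathway character vector of pathway member identifiers.
#' @param universe character vector: the background set.
#' @return One-row data.frame: `k` (overlap), `K` (pathway size in
#'   universe), `n` (query size), `N` (universe size), `p`.
#' @export
overrepresentation_test <- function(query, pathway, universe) {
  universe <- unique(universe)
  query <- unique(query)
  if (length(universe) == 0) stop("empty universe")
  if (length(query) == 0) stop("empty query")
  if (!all(query %in% universe))
    stop("query must be a subset of the universe")
  members <- unique(intersect(pathway, universe))
  k <- length(intersect(query, members))
  K <- length(members)
  n <- length(query)
  N <- length(universe)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  data.frame(k = k, K = K, n = n, N = N, p = p)
}

#' Rank pathway sets by over-representation
#'
#' Runs [overrepresentation_test()] on every set, BH-adjusts across
#' pathways, and sorts ascending by p (ties broken alphabetically by
#' pathway name, so the order is deterministic).
#'
#' @param query,universe as in [overrepresentation_test()].
#' @param pathways named list of character vectors (e.g. from
#'   [read_gmt()]).
#' @return data.frame with `pathway`, `k`, `K`, `n`, `N`, `p`, `q`,
#'   sorted by (p, pathway).
#' @export
enrich_all <- function(query, pathways, universe) {
  if (length(pathways) == 0) stop("need at least one pathway set")
  if (is.null(names(pathways)) || any(names(pathways) == ""))
    stop("pathway sets must be named")
  rows <- lapply(names(pathways), function(nm) {
    res <- overrepresentation_test(query, pathways[[nm]], universe)
    cbind(pathway = nm, res, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- adjust_fdr_bh(out$p)
  out <- out[order(out$p, out$pathway), ]
  rownames(out) <- NULL
  out
}

#' Read pathway sets from a GMT file
#'
#' @param path GMT file (name, description, tab-separated members).
#' @return Named list of unique member vectors.
#' @export
read_gmt <- function(path) {
  sets <- fgsea::gmtPathways(path)
  lapply(sets, unique)
}

#' Write pathway sets to a GMT file
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description description field (recycled; default `"na"`).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "na") {
  stopifnot(!is.null(names(sets)))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, description, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
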