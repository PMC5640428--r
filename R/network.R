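#' Canonicalise an undirected protein-interaction edge table
#'
#' Drops self loops, orders each pair lexicographically and collapses
#' duplicate edges (e.g. the same interaction reported by several provenance
#' databases) to a single undirected edge.
#'
#' @param edges Data frame with columns `node_a`, `node_b` and optionally
#'   `provenance`.
#' @return A tibble of unique undirected edges.
#' @export
as_edges <- function(edges) {
  assert_columns(edges, c("node_a", "node_b"), what = "edge list")
  if (!"provenance" %in% names(edges)) edges$provenance <- NA_character_
  a <- as.character(edges$node_a)
  b <- as.character(edges$node_b)
  keep <- a != b
  lo <- pmin(a[keep], b[keep])
  hi <- pmax(a[keep], b[keep])
  out <- tibble(node_a = lo, node_b = hi,
                provenance = as.character(edges$provenance)[keep])
  dplyr::distinct(out, .data$node_a, .data$node_b, .keep_all = TRUE)
}

# igraph object from an edge tibble plus optional isolated nodes.
build_graph <- function(edges, nodes = NULL) {
  edges <- as_edges(edges)
  nodes <- union(as.character(nodes %||% character(0)),
                 c(edges$node_a, edges$node_b))
  igraph::graph_from_data_frame(edges[, c("node_a", "node_b")],
                                directed = FALSE,
                                vertices = data.frame(name = nodes))
}

#' Local clustering coefficient of one node
#'
#' Watts-Strogatz local coefficient `2 T(v) / (k(v) (k(v) - 1))` where `T(v)`
#' counts triangles through `v` and `k(v)` is its degree; defined as 0 for
#' nodes of degree below 2.
#'
#' @param edges Edge table (see [as_edges()]).
#' @param node Node identity.
#' @param nodes Optional full node set (to include isolated nodes).
#' @return Clustering coefficient in `[0, 1]`.
#' @export
local_clustering <- function(edges, node, nodes = NULL) {
  g <- build_graph(edges, nodes)
  if (!node %in% igraph::V(g)$name) {
    abort(sprintf("node '%s' not in graph", node),
          class = "baitprey_validation_error")
  }
  cc <- igraph::transitivity(g, type = "local", vids = node, isolates = "zero")
  as.numeric(cc)
}

#' Average clustering coefficient of a graph
#'
#' Mean of the local Watts-Strogatz coefficients over nodes.  By default
#' nodes of degree below 2 contribute 0 and are included in the mean
#' (the convention under which the published 0.63 is only a reference value,
#' the original tool's convention being unstated); set
#' `include_low_degree = FALSE` to average over nodes of degree >= 2 only.
#'
#' @param edges Edge table.
#' @param nodes Optional full node set.
#' @param include_low_degree Include degree-<2 nodes as zeros; default TRUE.
#' @return Average clustering coefficient in `[0, 1]`.
#' @export
average_clustering <- function(edges, nodes = NULL,
                               include_low_degree = TRUE) {
  g <- build_graph(edges, nodes)
  if (igraph::vcount(g) == 0) {
    abort("graph is empty", class = "baitprey_validation_error")
  }
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  if (!include_low_degree) {
    cc <- cc[igraph::degree(g) >= 2]
    if (length(cc) == 0) return(NaN)
  }
  mean(cc)
}

#' Average number of neighbours (mean degree)
#'
#' `2 |E| / |V|` for an undirected graph.
#'
#' @param edges Edge table.
#' @param nodes Optional full node set (isolated nodes lower the mean).
#' @return Non-negative mean degree.
#' @export
average_neighbors <- function(edges, nodes = NULL) {
  g <- build_graph(edges, nodes)
  if (igraph::vcount(g) == 0) {
    abort("graph is empty", class = "baitprey_validation_error")
  }
  mean(igraph::degree(g))
}

#' Induced subgraph on a node subset
#'
#' @param edges Edge table.
#' @param node_subset Nodes to keep.
#' @return Edge tibble of the induced subgraph (edges with both endpoints in
#'   `node_subset`).
#' @export
subnetwork_extract <- function(edges, node_subset) {
  edges <- as_edges(edges)
  keep <- edges$node_a %in% node_subset & edges$node_b %in% node_subset
  edges[keep, ]
}

#' Summary statistics of an interaction network
#'
#' @param edges Edge table.
#' @param nodes Optional full node set.
#' @return One-row tibble: `n_nodes`, `n_edges`, `average_neighbors`,
#'   `average_clustering`.
#' @export
network_summary <- function(edges, nodes = NULL) {
  g <- build_graph(edges, nodes)
  tibble(
    n_nodes = igraph::vcount(g),
    n_edges = igraph::ecount(g),
    average_neighbors = average_neighbors(edges, nodes),
    average_clustering = average_clustering(edges, nodes)
  )
}
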