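#' Newman-Girvan modularity of a partition
#'
#' `Q = sum_c ( e_c/m - (d_c/(2m))^2 )` with `e_c` the number of edges inside
#' community `c` and `d_c` its degree sum.
#'
#' @param g undirected igraph graph with at least one edge.
#' @param membership integer community label per vertex.
#' @return modularity value in `[-0.5, 1]`.
#' @export
graph_modularity <- function(g, membership) {
  check_graph(g)
  if (igraph::ecount(g) < 1) stop_data("modularity needs at least one edge")
  memb <- check_partition(g, membership)
  igraph::modularity(g, memb)
}

#' Detect communities by modularity maximization
#'
#' A Louvain-style heuristic (local moving plus graph aggregation until no
#' move improves modularity), as implemented by
#' [igraph::cluster_louvain()]. Isolated nodes end up in singleton
#' communities, and the result never scores below the all-singletons
#' partition. Deterministic for a fixed seed. Any externally supplied
#' partition can be used in its place throughout the package: detection is a
#' pluggable first step, not a baked-in dependency.
#'
#' @param g undirected igraph graph.
#' @param seed optional integer seed.
#' @return integer membership vector with labels `1..k`.
#' @export
detect_communities <- function(g, seed = NULL) {
  check_graph(g)
  if (!is.null(seed)) set.seed(seed)
  if (igraph::vcount(g) == 0) return(integer(0))
  if (igraph::ecount(g) == 0) return(seq_len(igraph::vcount(g)))
  cl <- igraph::cluster_louvain(g)
  canonical_membership(as.integer(igraph::membership(cl)))
}
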