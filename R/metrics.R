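#' Gini coefficient of a degree sequence
#'
#' With the sequence sorted ascending, `G = sum((2i - n - 1) x_i) /
#' (n sum(x_i))`. Zero for a regular graph, approaching one under extreme
#' hub dominance; invariant under permutation and under scaling all degrees
#' by a constant.
#'
#' @param degrees non-negative numeric sequence, not all zero.
#' @return Gini coefficient in `[0, 1]`.
#' @export
gini_coefficient <- function(degrees) {
  if (!length(degrees)) stop_data("empty degree sequence")
  if (all(degrees == 0)) stop_data("all-zero degree sequence")
  x <- sort(degrees)
  n <- length(x)
  sum((2 * seq_len(n) - n - 1) * x) / (n * sum(x))
}

#' Average local clustering coefficient
#'
#' Mean over all nodes of `triangles(u) / choose(deg(u), 2)`, with nodes of
#' degree below two contributing zero.
#'
#' @param g undirected simple igraph graph.
#' @return value in `[0, 1]`.
#' @export
avg_local_clustering <- function(g) {
  check_graph(g)
  if (igraph::vcount(g) == 0) stop_data("empty graph")
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  mean(cc)
}

largest_component <- function(g) {
  comp <- igraph::components(g)
  big <- which.max(comp$csize)
  igraph::induced_subgraph(g, which(comp$membership == big))
}

#' Diameter of the largest connected component
#'
#' Exact eccentricity-based diameter, computed on the largest component
#' only so that small satellite components do not mask the small-world
#' scale of the giant component.
#'
#' @param g undirected igraph graph with at least one edge.
#' @return integer diameter.
#' @export
diameter_lcc <- function(g) {
  check_graph(g)
  if (igraph::ecount(g) < 1) stop_data("diameter needs at least one edge")
  lcc <- largest_component(g)
  as.integer(igraph::diameter(lcc, unconnected = FALSE))
}

#' Effective diameter of the largest connected component
#'
#' The smallest integer `D` such that at least a fraction `q` (default 90%)
#' of distinct node pairs in the largest component are within distance `D`.
#' Distances are exact breadth-first-search distances, accumulated in source
#' blocks so the full distance matrix is never held at once.
#'
#' @param g undirected igraph graph whose largest component has at least two
#'   nodes.
#' @param q pair fraction, default 0.9.
#' @return integer effective diameter; always `<=` [diameter_lcc()].
#' @export
effective_diameter <- function(g, q = 0.9) {
  check_graph(g)
  lcc <- largest_component(g)
  nl <- igraph::vcount(lcc)
  if (nl < 2) stop_data("largest component needs at least two nodes")
  counts <- numeric(0)
  block <- 256L
  for (start in seq(1L, nl, by = block)) {
    vs <- start:min(start + block - 1L, nl)
    dmat <- igraph::distances(lcc, v = vs)
    tab <- tabulate(dmat[dmat > 0] + 1L)
    if (length(tab) > length(counts))
      counts <- c(counts, numeric(length(tab) - length(counts)))
    counts[seq_along(tab)] <- counts[seq_along(tab)] + tab
  }
  counts <- counts / 2  # each unordered pair seen from both endpoints
  total <- nl * (nl - 1) / 2
  cum <- cumsum(counts)
  as.integer(which(cum >= q * total)[1] - 1L)
}

#' Number of non-trivial communities
#'
#' The community count minus the number of connected components other than
#' the largest: small satellite components each trivially form their own
#' community, and counting them would overstate the detected structure of
#' the giant component.
#'
#' @param g undirected igraph graph.
#' @param membership community label per vertex.
#' @return integer count.
#' @export
count_nontrivial_communities <- function(g, membership) {
  check_graph(g)
  memb <- check_partition(g, membership)
  k <- length(unique(memb))
  ncomp <- igraph::components(g)$no
  k - max(ncomp - 1L, 0L)
}

#' Scalar realism profile of a graph
#'
#' The metric vector used to compare an original with its replicas: edge
#' count, maximum degree, Gini coefficient of the degree sequence, average
#' local clustering, diameter of the largest component, number of
#' components, and number of non-trivial communities (detected with the
#' given seed).
#'
#' @param g undirected simple igraph graph with at least one edge.
#' @param seed optional integer seed for community detection.
#' @param membership optional partition; detected when absent.
#' @return named numeric vector of class `metric_vector`.
#' @export
metric_vector <- function(g, seed = NULL, membership = NULL) {
  check_graph(g)
  if (igraph::ecount(g) < 1) stop_data("metric vector needs >= 1 edge")
  if (is.null(membership)) membership <- detect_communities(g, seed = seed)
  deg <- igraph::degree(g)
  structure(c(m = as.numeric(igraph::ecount(g)),
              d_max = max(deg),
              gini = gini_coefficient(deg),
              avg_cc = avg_local_clustering(g),
              diameter = diameter_lcc(g),
              n_components = as.numeric(igraph::components(g)$no),
              n_communities = count_nontrivial_communities(g, membership)),
            class = "metric_vector")
}

#' Relative deviation of replica metrics from the original
#'
#' Componentwise ratios `x_replica / x_original`; a zero original value
#' yields `NA` (an undefined marker) rather than an infinite ratio.
#'
#' @param orig,repl metric vectors from [metric_vector()].
#' @return named numeric vector of ratios.
#' @export
relative_deviation <- function(orig, repl) {
  stopifnot(identical(names(orig), names(repl)))
  out <- ifelse(unclass(orig) == 0, NA_real_, unclass(repl) / unclass(orig))
  names(out) <- names(orig)
  out
}
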