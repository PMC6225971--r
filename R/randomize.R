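#' Degree-preserving edge-switch randomization
#'
#' Replaces uniformly chosen edge pairs `{u,v}, {y,z}` by `{u,z}, {y,v}`
#' whenever the result stays simple (no self-loop, no duplicate), after a fair
#' coin on the pairing orientation. Every node keeps its degree exactly. The
#' budget is `ceiling(multiplier * m)` *attempts*, rejections included;
#' `multiplier = 10` is enough in practice for the result to be an
#' (approximately) uniform draw from all simple graphs with the given degree
#' sequence.
#'
#' @param g undirected simple igraph graph.
#' @param multiplier switch attempts per edge (default 10).
#' @param seed optional integer seed; when `NULL` the current RNG state is
#'   used, so `set.seed()` upstream gives reproducibility either way.
#' @return the randomized graph, with graph attributes `switch_attempts` and
#'   `switch_applied`. Graphs with fewer than two edges are returned
#'   unchanged.
#' @export
randomize_edges <- function(g, multiplier = 10, seed = NULL) {
  check_graph(g)
  if (!is.null(seed)) set.seed(seed)
  n <- igraph::vcount(g)
  m <- igraph::ecount(g)
  if (m < 2) {
    g$switch_attempts <- 0
    g$switch_applied <- 0
    return(g)
  }
  e <- igraph::as_edgelist(g, names = FALSE)
  res <- cpp_switch_randomize(e, n, ceiling(multiplier * m),
                              draw_master_seed())
  out <- igraph::make_empty_graph(n, directed = FALSE)
  out <- igraph::add_edges(out, t(res$edges))
  out$switch_attempts <- res$attempts
  out$switch_applied <- res$applied
  out
}

#' A single edge-switch attempt
#'
#' Mainly useful for inspecting the chain one step at a time; bulk
#' randomization should go through [randomize_edges()].
#'
#' @inheritParams randomize_edges
#' @return list with `graph` and logical `applied`.
#' @export
attempt_edge_switch <- function(g, seed = NULL) {
  check_graph(g)
  if (igraph::ecount(g) < 2) stop_data("need at least two edges to switch")
  if (!is.null(seed)) set.seed(seed)
  res <- cpp_switch_randomize(igraph::as_edgelist(g, names = FALSE),
                              igraph::vcount(g), 1, draw_master_seed())
  out <- igraph::make_empty_graph(igraph::vcount(g), directed = FALSE)
  out <- igraph::add_edges(out, t(res$edges))
  list(graph = out, applied = res$applied == 1)
}

#' Realize a graphical degree sequence as a random simple graph
#'
#' Havel-Hakimi construction followed (by default) by edge-switch
#' randomization with the standard budget, so the result is close to a
#' uniform draw rather than the deterministic greedy graph.
#'
#' @param degrees non-negative integer degree per node.
#' @param randomize run the switch chain after construction (default TRUE).
#' @inheritParams randomize_edges
#' @return igraph graph with exactly the requested degrees.
#' @export
realize_degree_sequence <- function(degrees, randomize = TRUE,
                                    multiplier = 10, seed = NULL) {
  degrees <- as.integer(degrees)
  check_graphical(degrees)
  n <- length(degrees)
  e <- cpp_havel_hakimi(degrees)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  g <- igraph::add_edges(g, t(e))
  if (randomize) g <- randomize_edges(g, multiplier, seed)
  g
}

#' Rewire forbidden edges out of a graph by targeted switches
#'
#' Each sweep pairs every forbidden edge with a uniformly chosen partner edge
#' and applies the switch (trying both orientations) only when the result is
#' simple and the number of forbidden edges among the four involved strictly
#' decreases. Degrees and the edge count are invariant throughout. Used by
#' the replica generator to push inter-community edges that landed inside a
#' community back out.
#'
#' @param g undirected simple igraph graph.
#' @param forbidden either an integer membership vector (an edge is forbidden
#'   when both endpoints share a label) or a predicate `function(u, v)`
#'   returning TRUE for forbidden edges (vertex ids 1-based).
#' @param max_sweeps sweep limit (default 100; few are needed in practice).
#' @inheritParams randomize_edges
#' @return list with `graph`, `residual` (forbidden edges remaining) and
#'   `sweeps`. A non-zero residual raises a structured warning; the caller
#'   decides whether that is fatal.
#' @export
rewire_forbidden <- function(g, forbidden, max_sweeps = 100, seed = NULL) {
  check_graph(g)
  if (!is.null(seed)) set.seed(seed)
  n <- igraph::vcount(g)
  e <- igraph::as_edgelist(g, names = FALSE)
  if (is.function(forbidden)) {
    res <- rewire_forbidden_pred(e, n, forbidden, max_sweeps)
  } else {
    memb <- check_partition(g, forbidden)
    if (nrow(e) == 0) {
      res <- list(edges = e, residual = 0, sweeps = 0L)
    } else {
      res <- cpp_rewire_forbidden(e, n, memb, max_sweeps, draw_master_seed())
    }
  }
  out <- igraph::make_empty_graph(n, directed = FALSE)
  out <- igraph::add_edges(out, t(res$edges))
  if (res$residual > 0)
    warning(structure(
      class = c("reconet_residual_forbidden", "warning", "condition"),
      list(message = paste0(res$residual,
                            " forbidden edge(s) remain after ",
                            res$sweeps, " sweep(s)"),
           call = sys.call(-1))))
  list(graph = out, residual = as.numeric(res$residual),
       sweeps = res$sweeps)
}

# Pure-R sweep loop for arbitrary predicates; fine at test scale.
rewire_forbidden_pred <- function(e, n, pred, max_sweeps) {
  has <- function(u, v) any(e[, 1] == pmin(u, v) & e[, 2] == pmax(u, v))
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  m <- nrow(e)
  sweeps <- 0L
  repeat {
    bad <- which(vapply(seq_len(m), function(i) pred(e[i, 1], e[i, 2]), TRUE))
    if (!length(bad) || sweeps >= max_sweeps || m < 2) break
    sweeps <- sweeps + 1L
    for (i in sample(bad)) {
      u <- e[i, 1]; v <- e[i, 2]
      if (!pred(u, v)) next
      j <- sample(setdiff(seq_len(m), i), 1)
      y <- e[j, 1]; z <- e[j, 2]
      before <- pred(u, v) + pred(y, z)
      for (o in sample(1:2)) {
        yy <- if (o == 1) y else z
        zz <- if (o == 1) z else y
        if (u == zz || yy == v) next
        if (has(u, zz) || has(yy, v)) next
        if (pred(u, zz) + pred(yy, v) >= before) next
        e[i, ] <- c(min(u, zz), max(u, zz))
        e[j, ] <- c(min(yy, v), max(yy, v))
        break
      }
    }
  }
  bad <- which(vapply(seq_len(m), function(i) pred(e[i, 1], e[i, 2]), TRUE))
  list(edges = e, residual = length(bad), sweeps = sweeps)
}
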