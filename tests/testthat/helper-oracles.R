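# Independent brute-force oracles, deliberately kept off the implementation
# paths they check.

library(igraph)

# canonical string for a labeled graph's edge set
canon_edges <- function(g) {
  e <- igraph::as_edgelist(g, names = FALSE)
  if (!nrow(e)) return("")
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- e[order(e[, 1], e[, 2]), , drop = FALSE]
  paste(paste(e[, 1], e[, 2], sep = "-"), collapse = ";")
}

# all labeled simple graphs on n nodes with the exact degree sequence d,
# by exhaustive enumeration of edge subsets (small n only)
oracle_realizations <- function(d) {
  n <- length(d)
  pairs <- t(combn(n, 2))
  m <- sum(d) / 2
  out <- character(0)
  for (idx in combn(nrow(pairs), m, simplify = FALSE)) {
    sel <- pairs[idx, , drop = FALSE]
    if (all(tabulate(c(sel), nbins = n) == d)) {
      sel <- sel[order(sel[, 1], sel[, 2]), , drop = FALSE]
      out <- c(out, paste(paste(sel[, 1], sel[, 2], sep = "-"),
                          collapse = ";"))
    }
  }
  sort(out)
}

# all set partitions of 1..n (for brute-force modularity optima)
oracle_set_partitions <- function(n) {
  if (n == 1) return(list(list(1L)))
  out <- list()
  for (p in oracle_set_partitions(n - 1L)) {
    for (i in seq_along(p)) {
      q <- p
      q[[i]] <- c(q[[i]], n)
      out[[length(out) + 1L]] <- q
    }
    out[[length(out) + 1L]] <- c(p, list(n))
  }
  out
}

partition_to_membership <- function(p, n) {
  memb <- integer(n)
  for (i in seq_along(p)) memb[p[[i]]] <- i
  memb
}

# hand evaluation of Newman-Girvan modularity from its formula
oracle_modularity <- function(g, memb) {
  m <- igraph::ecount(g)
  e <- igraph::as_edgelist(g, names = FALSE)
  deg <- igraph::degree(g)
  q <- 0
  for (c in unique(memb)) {
    ec <- sum(memb[e[, 1]] == c & memb[e[, 2]] == c)
    dc <- sum(deg[memb == c])
    q <- q + ec / m - (dc / (2 * m))^2
  }
  q
}

# Floyd-Warshall all-pairs distances on an adjacency matrix
oracle_distances <- function(adj) {
  n <- nrow(adj)
  d <- ifelse(adj > 0, 1, Inf)
  diag(d) <- 0
  for (k in seq_len(n)) d <- pmin(d, outer(d[, k], d[k, ], `+`))
  d
}

# mean local clustering by matrix triangle counting
oracle_avg_clustering <- function(adj) {
  deg <- rowSums(adj)
  tri <- diag(adj %*% adj %*% adj) / 2
  denom <- deg * (deg - 1) / 2
  mean(ifelse(deg < 2, 0, tri / denom))
}

# Gini by the pairwise mean-absolute-difference formula
oracle_gini <- function(x) {
  n <- length(x)
  sum(abs(outer(x, x, `-`))) / (2 * n^2 * mean(x))
}

make_tri <- function() igraph::make_graph(c(1, 2, 2, 3, 3, 1),
                                          directed = FALSE)

# two triangles joined by one bridge (nodes 3 and 4)
make_bridged_triangles <- function() {
  igraph::make_graph(c(1, 2, 2, 3, 3, 1, 4, 5, 5, 6, 6, 4, 3, 4),
                     directed = FALSE)
}
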