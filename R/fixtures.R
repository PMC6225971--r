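# Synthetic test networks emulating the statistical structure of the
# corpora the replication workflow targets: clustered social graphs (planted
# partition), skewed degree sequences (truncated power law), and sparse
# hub-and-satellite contact networks.

#' Planted-partition (stochastic block model) fixture
#'
#' `blocks` equal-sized groups; node pairs are connected independently with
#' probability `p_in` inside a block and `p_out` across blocks. With
#' `p_in >> p_out` this gives a clear community structure whose planted
#' blocks a detector should recover.
#'
#' @param blocks number of blocks.
#' @param block_size nodes per block.
#' @param p_in,p_out within/between-block edge probabilities,
#'   `0 <= p_out <= p_in <= 1`.
#' @param seed optional integer seed.
#' @return list with `graph` and the planted `membership`.
#' @export
planted_partition <- function(blocks, block_size, p_in, p_out, seed = NULL) {
  if (is.na(p_in) || is.na(p_out) || p_out < 0 || p_in > 1 || p_out > p_in)
    stop_data("need 0 <= p_out <= p_in <= 1")
  if (!is.null(seed)) set.seed(seed)
  pref <- matrix(p_out, blocks, blocks)
  diag(pref) <- p_in
  g <- igraph::sample_sbm(blocks * block_size, pref.matrix = pref,
                          block.sizes = rep(block_size, blocks))
  list(graph = g, membership = rep(seq_len(blocks), each = block_size))
}

#' Sample a degree sequence from a truncated power law
#'
#' i.i.d. draws with `P(k) proportional to k^gamma` on `d_min..d_max`; when
#' the sum comes out odd, one node's degree is incremented so the sequence
#' has an even sum (a node below `d_max` is preferred).
#'
#' @param n sequence length.
#' @param gamma exponent (typically negative).
#' @param d_min,d_max integer support bounds.
#' @param seed optional integer seed.
#' @return integer degree sequence of length `n` with even sum.
#' @export
powerlaw_degree_sample <- function(n, gamma, d_min, d_max, seed = NULL) {
  if (d_min > d_max || d_min < 1) stop_data("need 1 <= d_min <= d_max")
  if (!is.null(seed)) set.seed(seed)
  k <- seq(d_min, d_max)
  d <- if (length(k) == 1) rep(k, n)
       else sample(k, n, replace = TRUE, prob = k^gamma)
  if (sum(d) %% 2 == 1) {
    i <- which(d < d_max)[1]
    if (is.na(i)) i <- 1L
    d[i] <- d[i] + 1L
  }
  as.integer(d)
}

#' Hub-and-satellite tree fixture
#'
#' A uniform random spanning tree over the hubs, each hub carrying
#' `satellites_per_hub` degree-1 satellite nodes. Emulates the tree-like,
#' hub-dominated shape of sparse contact networks.
#'
#' @param hubs number of hub nodes, `>= 1`.
#' @param satellites_per_hub degree-1 nodes attached to each hub.
#' @param seed optional integer seed.
#' @return igraph tree on `hubs * (1 + satellites_per_hub)` nodes.
#' @export
hub_satellite <- function(hubs, satellites_per_hub, seed = NULL) {
  if (hubs < 1) stop_data("need at least one hub")
  if (!is.null(seed)) set.seed(seed)
  g <- if (hubs == 1) {
    igraph::make_empty_graph(1, directed = FALSE)
  } else {
    igraph::sample_tree(hubs)
  }
  if (satellites_per_hub > 0) {
    sats <- hubs + seq_len(hubs * satellites_per_hub)
    owners <- rep(seq_len(hubs), each = satellites_per_hub)
    g <- igraph::add_vertices(g, hubs * satellites_per_hub)
    g <- igraph::add_edges(g, rbind(owners, sats))
  }
  g
}
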