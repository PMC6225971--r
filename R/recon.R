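#' Extract a network signature
#'
#' The signature is the sufficient statistic the replica generator works
#' from: for every node its community id, internal degree (neighbors inside
#' the community) and external degree (neighbors outside). It contains no
#' edges, which makes the file exportable as an anonymized summary of a
#' sensitive network.
#'
#' @param g undirected simple igraph graph.
#' @param membership integer community label per vertex.
#' @return a `recon_signature`: data frame with columns `node` (1-based
#'   internal id), `community`, `internal_degree`, `external_degree`, plus
#'   attributes `source_n` and `scale`.
#' @export
extract_signature <- function(g, membership) {
  check_graph(g)
  memb <- canonical_membership(check_partition(g, membership))
  n <- igraph::vcount(g)
  e <- igraph::as_edgelist(g, names = FALSE)
  internal <- integer(n)
  external <- integer(n)
  if (nrow(e)) {
    same <- memb[e[, 1]] == memb[e[, 2]]
    internal <- tabulate(c(e[same, 1], e[same, 2]), nbins = n)
    external <- tabulate(c(e[!same, 1], e[!same, 2]), nbins = n)
  }
  new_signature(data.frame(node = seq_len(n), community = memb,
                           internal_degree = internal,
                           external_degree = external),
                source_n = n, scale = 1L)
}

new_signature <- function(df, source_n, scale) {
  validate_signature(df)
  structure(df, class = c("recon_signature", "data.frame"),
            source_n = source_n, scale = scale)
}

validate_signature <- function(df) {
  need <- c("node", "community", "internal_degree", "external_degree")
  if (!all(need %in% names(df)))
    stop_data("signature needs columns ", paste(need, collapse = ", "))
  sizes <- table(df$community)
  int_sum <- tapply(df$internal_degree, df$community, sum)
  odd <- names(int_sum)[int_sum %% 2 != 0]
  if (length(odd))
    stop_data("community ", odd[1], " has an odd internal-degree sum")
  if (sum(df$external_degree) %% 2 != 0)
    stop_data("total external-degree sum is odd")
  over <- df$internal_degree > as.integer(sizes[as.character(df$community)]) - 1L
  if (any(over))
    stop_data("node ", df$node[over][1],
              ": internal degree exceeds community size - 1")
  invisible(df)
}

#' Scale a signature by an integer factor
#'
#' Produces `x` disjoint copies of every community with identical per-node
#' internal and external degrees; a replica generated from the scaled
#' signature has `x*n` nodes and `x*m` edges.
#'
#' @param sig a `recon_signature`.
#' @param x positive integer scaling factor.
#' @return the scaled `recon_signature`.
#' @export
scale_signature <- function(sig, x) {
  x <- as.integer(x)
  if (is.na(x) || x < 1L) stop_data("x must be a positive integer")
  if (x == 1L) return(sig)
  n <- nrow(sig)
  k <- max(sig$community)
  idx <- rep(seq_len(n), x)
  copy <- rep(seq_len(x) - 1L, each = n)
  out <- data.frame(node = copy * n + sig$node[idx],
                    community = copy * k + sig$community[idx],
                    internal_degree = sig$internal_degree[idx],
                    external_degree = sig$external_degree[idx])
  new_signature(out, source_n = attr(sig, "source_n") %||% n, scale = x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a graph from a network signature
#'
#' Each community's internal subgraph is realized independently from its
#' internal-degree sequence (Havel-Hakimi plus edge-switch randomization with
#' the standard 10 attempts-per-edge budget); the inter-community graph is
#' realized globally from the external-degree sequence the same way, and
#' edges that landed inside a community ("forbidden") are then switched out
#' by [rewire_forbidden()]. Per-community RNG sub-streams are derived from
#' the master seed and the community index, so results do not depend on
#' processing order.
#'
#' @param sig a `recon_signature`.
#' @param seed optional integer seed.
#' @param strict if TRUE (default), residual forbidden edges after
#'   `max_sweeps` are an error; if FALSE they are dropped from a warning
#'   count and any resulting duplicate edges removed.
#' @param multiplier switch attempts per edge.
#' @param max_sweeps rewiring sweep limit.
#' @return igraph graph with vertex attribute `community`; graph attribute
#'   `residual_forbidden` records the rewiring residual (0 in strict mode).
#' @export
generate_from_signature <- function(sig, seed = NULL, strict = TRUE,
                                    multiplier = 10, max_sweeps = 100) {
  validate_signature(sig)
  if (!is.null(seed)) set.seed(seed)
  master <- draw_master_seed()
  n <- nrow(sig)
  ord <- order(sig$node)
  comm <- integer(n)
  comm[sig$node[ord]] <- sig$community[ord]
  dint <- integer(n); dint[sig$node] <- sig$internal_degree
  dext <- integer(n); dext[sig$node] <- sig$external_degree

  groups <- split(seq_len(n), comm)
  edge_parts <- vector("list", length(groups) + 1L)
  for (i in seq_along(groups)) {
    nodes <- groups[[i]]
    d <- dint[nodes]
    if (sum(d) == 0) next
    check_graphical(d, context = paste0("community ", names(groups)[i],
                                        " internal-degree sequence"))
    em <- cpp_havel_hakimi(d)
    mc <- nrow(em)
    res <- cpp_switch_randomize(em, length(nodes),
                                ceiling(multiplier * mc),
                                derive_seed(master, i))
    le <- res$edges
    edge_parts[[i]] <- cbind(nodes[le[, 1]], nodes[le[, 2]])
  }

  residual <- 0
  if (sum(dext) > 0) {
    check_graphical(dext, context = "external-degree sequence")
    em <- cpp_havel_hakimi(dext)
    me <- nrow(em)
    res <- cpp_switch_randomize(em, n, ceiling(multiplier * me),
                                derive_seed(master, 0L))
    rw <- cpp_rewire_forbidden(res$edges, n, comm, max_sweeps,
                               derive_seed(master, -1L))
    residual <- rw$residual
    ext <- rw$edges
    if (residual > 0) {
      if (strict)
        stop_contract(residual, " forbidden inter-community edge(s) could",
                      " not be rewired within ", max_sweeps, " sweeps")
      warning(residual, " forbidden edge(s) remain; replica kept in",
              " lenient mode")
    }
    edge_parts[[length(groups) + 1L]] <- ext
  }

  edges <- do.call(rbind, edge_parts)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (!is.null(edges) && nrow(edges)) g <- igraph::add_edges(g, t(edges))
  if (igraph::any_multiple(g)) {
    # only reachable in lenient mode when a residual intra-community external
    # edge coincides with an internal edge
    g <- igraph::simplify(g)
    warning("duplicate edges between internal and residual external",
            " placements were merged")
  }
  igraph::V(g)$community <- comm
  g$residual_forbidden <- as.numeric(residual)
  g
}

#' Replicate (and optionally scale) a network
#'
#' The full pipeline: detect a community structure (unless one is supplied),
#' extract the per-node internal/external-degree signature, scale it by `x`,
#' and generate a fresh graph from the scaled signature. The replica has
#' exactly `x*n` nodes, `x*m` edges, and the x-fold degree multiset of the
#' original; communities keep their internal edge counts exactly, while
#' edges within and between communities are randomized.
#'
#' @param g undirected simple igraph graph.
#' @param x positive integer scaling factor (1 = same-size replica).
#' @param membership optional partition; detected with
#'   [detect_communities()] when absent.
#' @param seed optional integer seed controlling detection and generation.
#' @inheritParams generate_from_signature
#' @return igraph replica with vertex attribute `community`.
#' @export
recon_replicate <- function(g, x = 1L, membership = NULL, seed = NULL,
                            strict = TRUE, multiplier = 10,
                            max_sweeps = 100) {
  check_graph(g)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(membership)) membership <- detect_communities(g)
  sig <- extract_signature(g, membership)
  sig <- scale_signature(sig, x)
  generate_from_signature(sig, seed = NULL, strict = strict,
                          multiplier = multiplier, max_sweeps = max_sweeps)
}

#' Write / read a signature file
#'
#' Format: header `#recon-signature v1`, then one
#' `node community internal_degree external_degree` line per node (0-based
#' node and community ids). The file contains no edges.
#'
#' @param sig a `recon_signature`.
#' @param path output path, or `NULL` to return the text.
#' @return `write_signature`: the text, invisibly when written;
#'   `read_signature`: a `recon_signature`.
#' @export
write_signature <- function(sig, path = NULL) {
  validate_signature(sig)
  txt <- c("#recon-signature v1",
           paste(sig$node - 1L, sig$community - 1L,
                 sig$internal_degree, sig$external_degree))
  if (is.null(path)) return(paste(txt, collapse = "\n"))
  writeLines(txt, path)
  invisible(paste(txt, collapse = "\n"))
}

#' @rdname write_signature
#' @export
read_signature <- function(path) {
  lines <- input_lines(path, "signature")
  if (!length(lines) || !grepl("^#recon-signature v1", lines[1]))
    stop_data("missing '#recon-signature v1' header")
  body <- lines[-1]
  body <- body[!grepl("^\\s*#", body) & nzchar(trimws(body))]
  toks <- strsplit(trimws(body), "\\s+")
  if (any(vapply(toks, length, 1L) != 4L))
    stop_data("signature lines need 4 fields")
  mat <- matrix(as.integer(unlist(toks)), ncol = 4, byrow = TRUE)
  df <- data.frame(node = mat[, 1] + 1L, community = mat[, 2] + 1L,
                   internal_degree = mat[, 3], external_degree = mat[, 4])
  df <- df[order(df$node), ]
  rownames(df) <- NULL
  if (!identical(df$node, seq_len(nrow(df))))
    stop_data("signature node ids must cover 0..n-1")
  new_signature(df, source_n = nrow(df), scale = 1L)
}
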