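#' Read an undirected simple graph from a whitespace-separated edge list
#'
#' Lines starting with `#` are comments; a `#n=<count>` header may declare the
#' node count so isolated nodes survive the round trip. Duplicate edges and
#' self-loops are dropped with a message. When node ids (after the indexing
#' shift) are not already contiguous `0..n-1` they are compacted in order of
#' first appearance, so that already-canonical files read back unchanged.
#'
#' @param path file path, connection, or a character vector of lines.
#' @param indexing `"zero"` (default) or `"one"`: base of the node ids in the
#'   file. Internally vertices are always `1..n`.
#' @return an undirected simple [igraph][igraph::make_graph] graph.
#' @export
read_edge_list <- function(path, indexing = c("zero", "one")) {
  indexing <- match.arg(indexing)
  lines <- input_lines(path, "edge-list")
  declared_n <- NA_integer_
  hdr <- grep("^#n=", lines, value = TRUE)
  if (length(hdr))
    declared_n <- suppressWarnings(as.integer(sub("^#n=", "", hdr[1])))
  body <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(body) == 0 && is.na(declared_n))
    stop_data("empty edge-list input")
  ends <- matrix(integer(0), 0, 2)
  if (length(body)) {
    toks <- strsplit(trimws(body), "\\s+")
    bad <- which(vapply(toks, length, 1L) != 2L)
    if (length(bad))
      stop_data("malformed edge-list line ", bad[1], ": '", body[bad[1]], "'")
    u <- suppressWarnings(as.integer(vapply(toks, `[`, "", 1L)))
    v <- suppressWarnings(as.integer(vapply(toks, `[`, "", 2L)))
    if (anyNA(u) || anyNA(v)) {
      bad <- which(is.na(u) | is.na(v))[1]
      stop_data("malformed edge-list line ", bad, ": '", body[bad], "'")
    }
    if (indexing == "one") { u <- u - 1L; v <- v - 1L }
    if (any(c(u, v) < 0L))
      stop_data("negative node id after indexing shift; check --indexing")
    ids <- unique(c(rbind(u, v)))
    contiguous <- max(ids) == length(ids) - 1L ||
      (!is.na(declared_n) && max(ids) < declared_n)
    if (!contiguous) {
      u <- match(u, ids) - 1L
      v <- match(v, ids) - 1L
    }
    n <- max(max(u, v) + 1L, if (is.na(declared_n)) 0L else declared_n)
    loops <- u == v
    if (any(loops)) message("dropped ", sum(loops), " self-loop(s)")
    u2 <- pmin(u[!loops], v[!loops])
    v2 <- pmax(u[!loops], v[!loops])
    dup <- duplicated(cbind(u2, v2))
    if (any(dup)) message("dropped ", sum(dup), " duplicate edge(s)")
    ends <- cbind(u2[!dup], v2[!dup]) + 1L
  } else {
    n <- declared_n
  }
  g <- igraph::graph_from_edgelist(ends, directed = FALSE)
  igraph::add_vertices(g, max(n - igraph::vcount(g), 0L))
}

#' Write a graph as a canonical edge list
#'
#' Emits a `#n=` header followed by one `u v` line per edge, 0-based,
#' endpoints ascending within a line, lines in ascending order; reading the
#' result back reproduces the graph exactly.
#'
#' @param g undirected igraph graph.
#' @param path optional output path; if `NULL` the text is returned.
#' @return the text, invisibly when written to `path`.
#' @export
write_edge_list <- function(g, path = NULL) {
  check_graph(g)
  e <- igraph::as_edgelist(g, names = FALSE) - 1L
  if (nrow(e)) {
    e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    e <- e[order(e[, 1], e[, 2]), , drop = FALSE]
  }
  txt <- c(paste0("#n=", igraph::vcount(g)),
           if (nrow(e)) paste(e[, 1], e[, 2]))
  if (is.null(path)) return(paste(txt, collapse = "\n"))
  writeLines(txt, path)
  invisible(paste(txt, collapse = "\n"))
}

#' Read a node-to-community partition file
#'
#' One `node_id community_id` pair per line, 0-based node ids, `#` comments
#' allowed. Every node id in `0..max` must appear exactly once.
#'
#' @param path file path or character vector of lines.
#' @return integer membership vector (labels `1..k` in order of first
#'   appearance), indexed by internal vertex id.
#' @export
read_partition <- function(path) {
  lines <- input_lines(path, "partition")
  body <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(body)) stop_data("empty partition input")
  toks <- strsplit(trimws(body), "\\s+")
  if (any(vapply(toks, length, 1L) != 2L))
    stop_data("malformed partition line: expected 'node community' pairs")
  node <- as.integer(vapply(toks, `[`, "", 1L))
  comm <- as.integer(vapply(toks, `[`, "", 2L))
  if (anyNA(node) || anyNA(comm)) stop_data("non-integer partition entry")
  if (anyDuplicated(node))
    stop_data("node ", node[duplicated(node)][1], " assigned more than once")
  n <- max(node) + 1L
  if (length(node) != n)
    stop_data("node(s) missing a community: expected ids 0..", n - 1L)
  out <- integer(n)
  out[node + 1L] <- comm
  canonical_membership(out)
}

#' Write a partition file
#'
#' @param membership integer membership vector (one label per vertex).
#' @param path optional output path.
#' @return the text, invisibly when written.
#' @export
write_partition <- function(membership, path = NULL) {
  comm <- canonical_membership(membership) - 1L
  txt <- paste(seq_along(comm) - 1L, comm)
  if (is.null(path)) return(paste(txt, collapse = "\n"))
  writeLines(txt, path)
  invisible(paste(txt, collapse = "\n"))
}

#' Disjoint union of x copies of a graph (and its partition)
#'
#' Copy `i` (0-based) maps vertex `v` to `i*n + v`; each copy carries its own
#' copy of the community structure, so a `k`-community partition becomes an
#' `x*k`-community one.
#'
#' @param g undirected igraph graph.
#' @param membership optional membership vector to copy along.
#' @param x number of copies, `>= 1`.
#' @return list with `graph` and (if supplied) `membership`.
#' @export
disjoint_union_copies <- function(g, membership = NULL, x = 1L) {
  check_graph(g)
  x <- as.integer(x)
  if (is.na(x) || x < 1L) stop_data("x must be a positive integer")
  n <- igraph::vcount(g)
  e <- igraph::as_edgelist(g, names = FALSE)
  shift <- rep((seq_len(x) - 1L) * n, each = nrow(e))
  ee <- cbind(rep(e[, 1], x) + shift, rep(e[, 2], x) + shift)
  h <- igraph::make_empty_graph(n * x, directed = FALSE)
  h <- igraph::add_edges(h, t(ee))
  out <- list(graph = h)
  if (!is.null(membership)) {
    memb <- check_partition(g, membership)
    memb <- canonical_membership(memb)
    k <- max(memb)
    out$membership <- rep(memb, x) + rep((seq_len(x) - 1L) * k, each = n)
  }
  out
}

#' Connected components as vertex-id sets
#'
#' @param g igraph graph.
#' @return list of integer vertex-id vectors, ordered by decreasing size with
#'   ties broken by smallest member id.
#' @export
graph_components <- function(g) {
  check_graph(g)
  comp <- igraph::components(g)
  sets <- unname(split(seq_len(igraph::vcount(g)), comp$membership))
  sizes <- lengths(sets)
  mins <- vapply(sets, min, 1L)
  sets[order(-sizes, mins)]
}
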