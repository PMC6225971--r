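# Condition helpers: the CLI maps these classes to exit codes
# (usage -> 1, data -> 2, contract -> 3).

stop_usage <- function(...) {
  stop(structure(class = c("reconet_usage_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_data <- function(...) {
  stop(structure(class = c("reconet_data_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_contract <- function(...) {
  stop(structure(class = c("reconet_contract_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

# Accept a file path, a connection, inline text (single string, possibly
# multi-line), or a character vector of lines.
input_lines <- function(path, what = "input") {
  if (!is.character(path)) return(readLines(path))
  if (length(path) == 0) stop_data("empty ", what)
  if (length(path) > 1) return(path)
  if (file.exists(path)) return(readLines(path))
  if (grepl("[\n #]", path)) return(strsplit(path, "\n", fixed = TRUE)[[1]])
  stop_data(what, " file not found: ", path)
}

check_graph <- function(g) {
  if (!igraph::is_igraph(g)) stop_data("expected an igraph object")
  if (igraph::is_directed(g)) stop_data("graph must be undirected")
  invisible(g)
}

# Membership vector: one positive integer community label per vertex.
check_partition <- function(g, membership) {
  n <- igraph::vcount(g)
  if (length(membership) != n)
    stop_data("partition covers ", length(membership),
              " nodes but the graph has ", n)
  if (anyNA(membership)) stop_data("every node needs a community")
  m <- as.integer(membership)
  if (any(m < 1L)) stop_data("community labels must be positive integers")
  invisible(m)
}

# Relabel community ids to 1..k in order of first appearance.
canonical_membership <- function(membership) {
  match(membership, unique(membership))
}

# Derive a reproducible sub-stream seed below 2^31 from a master seed and a
# stage index; keeps per-community realizations independent of processing
# order.
derive_seed <- function(master, index) {
  as.integer((as.numeric(master) + 2654435761 * (index + 2)) %% 2147483629) + 1L
}

# Draw a master seed from R's RNG so that set.seed() upstream controls all
# C++ sub-streams.
draw_master_seed <- function() {
  sample.int(2147483640L, 1L)
}

# Erdos-Gallai test; errors name the first violated inequality.
check_graphical <- function(d, context = "degree sequence") {
  d <- as.integer(d)
  if (any(d < 0)) stop_data(context, ": negative degree")
  s <- sum(d)
  if (s %% 2L != 0L)
    stop_data(context, " is not graphical: degree sum ", s, " is odd")
  ds <- sort(d, decreasing = TRUE)
  n <- length(ds)
  if (n == 0L || s == 0L) return(invisible(TRUE))
  if (ds[1] > n - 1L)
    stop_data(context, " is not graphical: degree ", ds[1],
              " exceeds n-1 = ", n - 1L)
  lhs <- cumsum(ds)
  for (k in seq_len(n)) {
    rhs <- k * (k - 1L) + if (k < n) sum(pmin(ds[(k + 1L):n], k)) else 0L
    if (lhs[k] > rhs)
      stop_data(context, " is not graphical: Erdos-Gallai inequality fails",
                " at k = ", k, " (", lhs[k], " > ", rhs, ")")
  }
  invisible(TRUE)
}
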