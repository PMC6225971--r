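#' Expected average degree of a truncated discrete power law
#'
#' For `P(k) proportional to k^gamma` on the integer support
#' `d_min..d_max`, returns `sum(k * k^gamma) / sum(k^gamma)`. Strictly
#' increasing in `gamma` whenever `d_min < d_max`, which is what makes the
#' bisection fit below well-posed.
#'
#' @param gamma power-law exponent (typically negative).
#' @param d_min,d_max integer support bounds, `1 <= d_min <= d_max`.
#' @return the expected value, a number in `[d_min, d_max]`.
#' @export
expected_avg_degree <- function(gamma, d_min, d_max) {
  if (d_min < 1) stop_data("d_min must be >= 1")
  if (d_min > d_max) stop_data("d_min must not exceed d_max")
  k <- seq(d_min, d_max)
  w <- k^gamma
  sum(k * w) / sum(w)
}

#' Fit a power-law exponent by average-degree bisection
#'
#' Finds `gamma` in `[-6, -1]` such that a degree sequence sampled from
#' `P(k) proportional to k^gamma` on `d_min..d_max` has the requested
#' expected average degree, by bisection until the bracket is narrower than
#' `tol` (default `1e-3`). Targets outside the range achievable on the
#' search interval return the nearer endpoint with `clamped = TRUE`; a
#' single-point support (`d_min == d_max`) is degenerate and returns `-1`
#' clamped.
#'
#' @param d_min,d_max integer support bounds.
#' @param target_avg the average degree to match; must lie in
#'   `[d_min, d_max]`.
#' @param tol bracket-width stopping tolerance on the exponent.
#' @param range search interval for the exponent.
#' @return a `powerlaw_fit`: list with `exponent`, `d_min`, `d_max`,
#'   `achieved_avg` and logical `clamped`.
#' @export
fit_powerlaw_exponent <- function(d_min, d_max, target_avg, tol = 1e-3,
                                  range = c(-6, -1)) {
  if (d_min > d_max) stop_data("d_min must not exceed d_max")
  if (target_avg < d_min || target_avg > d_max)
    stop_data("target average ", target_avg, " lies outside [",
              d_min, ", ", d_max, "]")
  mk <- function(expo, clamped) {
    structure(list(exponent = expo, d_min = as.integer(d_min),
                   d_max = as.integer(d_max),
                   achieved_avg = expected_avg_degree(expo, d_min, d_max),
                   clamped = clamped),
              class = "powerlaw_fit")
  }
  if (d_min == d_max) return(mk(range[2], TRUE))
  lo <- range[1]; hi <- range[2]
  if (target_avg <= expected_avg_degree(lo, d_min, d_max))
    return(mk(lo, TRUE))
  if (target_avg >= expected_avg_degree(hi, d_min, d_max))
    return(mk(hi, TRUE))
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (expected_avg_degree(mid, d_min, d_max) < target_avg) lo <- mid
    else hi <- mid
  }
  mk((lo + hi) / 2, FALSE)
}

plfit_degrees <- function(degrees) {
  d_min <- max(1L, min(degrees))
  d_max <- max(degrees)
  fit_powerlaw_exponent(d_min, d_max, mean(degrees))
}

new_model_params <- function(model, params) {
  obj <- structure(list(model = model, params = params),
                   class = "reconet_model_params")
  validate_model_params(obj)
  obj
}

validate_model_params <- function(obj) {
  p <- obj$params
  switch(obj$model,
    er = {
      if (p$p < 0 || p$p > 1) stop_data("ER: p must lie in [0,1]")
    },
    rmat = {
      if (abs(p$a + p$b + p$c + p$d - 1) > 1e-9)
        stop_data("R-MAT: initiator (a,b,c,d) must sum to 1")
      if (p$s < 1) stop_data("R-MAT: s must be >= 1")
    },
    hud = {
      if (p$gamma < 2.1) stop_data("HUD: gamma must be >= 2.1")
    },
    lfr = {
      literal <- identical(p$mixing, "intra_over_inter")
      if (p$mu < 0 || (!literal && p$mu > 1))
        stop_data("LFR: mu must lie in [0,1]")
      if (p$c_min > p$c_max) stop_data("LFR: c_min must not exceed c_max")
    })
  invisible(obj)
}

#' Fit a baseline generative model to a graph
#'
#' Parametrizes one of the classical generators from the input graph so that
#' a draw from the model targets `x*n` nodes and (in expectation) `x*m`
#' edges:
#' \describe{
#'   \item{er}{Erdos-Renyi: `n' = x*n`, `p = 2m / (x*n*(n-1))`.}
#'   \item{ba}{Barabasi-Albert: `n' = x*n`, `k = floor(m/n)` edges per new
#'     node.}
#'   \item{cl, esmc}{Chung-Lu / edge-switching Markov chain: the degree
#'     sequence is the x-fold concatenation of the original one.}
#'   \item{rmat}{`s = ceiling(log2(x*n))`, `e = floor(m/n)`; the
#'     `(a,b,c,d)` initiator must be supplied (likelihood-based initiator
#'     estimation is out of scope).}
#'   \item{hud}{hyperbolic unit-disk: `n' = x*n`, mean degree `2*(m/n)`,
#'     and a power-law exponent fitted by bisection, floored at 2.1 as the
#'     generator requires an exponent above 2.}
#' }
#'
#' @param g undirected simple igraph graph with `n >= 2`, `m >= 1`.
#' @param model one of `"er"`, `"ba"`, `"cl"`, `"esmc"`, `"rmat"`, `"hud"`.
#' @param x positive integer scaling factor.
#' @param initiator numeric `(a,b,c,d)` for `model = "rmat"`.
#' @return a `reconet_model_params` object.
#' @export
fit_baseline <- function(g, model = c("er", "ba", "cl", "esmc", "rmat",
                                      "hud"),
                         x = 1L, initiator = NULL) {
  model <- match.arg(model)
  check_graph(g)
  n <- igraph::vcount(g)
  m <- igraph::ecount(g)
  if (n < 2 || m < 1) stop_data("fitting needs n >= 2 and m >= 1")
  x <- as.integer(x)
  if (is.na(x) || x < 1L) stop_data("x must be a positive integer")
  deg <- igraph::degree(g)
  params <- switch(model,
    er = list(n = x * n, p = 2 * m / (x * n * (n - 1))),
    ba = list(n = x * n, k = floor(m / n)),
    cl = list(degrees = rep(deg, x)),
    esmc = list(degrees = rep(deg, x)),
    rmat = {
      if (is.null(initiator))
        stop_usage("model rmat needs an (a,b,c,d) initiator")
      if (length(initiator) != 4) stop_usage("initiator must have 4 entries")
      list(s = ceiling(log2(x * n)), e = floor(m / n),
           a = initiator[1], b = initiator[2], c = initiator[3],
           d = initiator[4], n = x * n, avg_deg = 2 * m / n)
    },
    hud = {
      fit <- plfit_degrees(deg)
      list(n = x * n, avg_deg = 2 * (m / n),
           gamma = max(2.1, abs(fit$exponent)))
    })
  new_model_params(model, params)
}

#' Fit the BTER model (degree distribution + clustering per degree)
#'
#' `n_d` counts the nodes of each occurring degree (scaled by `x` for a
#' scaled replica); `c_d` is the mean local clustering coefficient among
#' degree-`d` nodes and is left unchanged under scaling. Parameters are
#' export-only: generation is out of scope.
#'
#' @param g undirected simple igraph graph.
#' @param x positive integer scaling factor.
#' @return a `reconet_model_params` with named vectors `n_d` and `c_d`.
#' @export
fit_bter <- function(g, x = 1L) {
  check_graph(g)
  x <- as.integer(x)
  if (is.na(x) || x < 1L) stop_data("x must be a positive integer")
  deg <- igraph::degree(g)
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  ds <- sort(unique(deg))
  n_d <- vapply(ds, function(d) sum(deg == d) * x, 1)
  c_d <- vapply(ds, function(d) mean(cc[deg == d]), 1)
  names(n_d) <- names(c_d) <- ds
  new_model_params("bter", list(n_d = n_d, c_d = c_d))
}

#' Fit the LFR benchmark parameters to a graph and partition
#'
#' Degree parameters come from the average-degree bisection on the original
#' degree sequence. Community sizes are fitted the same way (`plfit*`): if
#' the size-exponent fit clamps at the `-1` boundary while the expected
#' average community size is still below the observed one, the minimum size
#' `c_min` is raised by integer binary search until they match; and the
#' maximum community size is enlarged to 5% above the maximum internal
#' degree when needed, since no community can host a node whose internal
#' degree exceeds the community size. The mixing parameter is by default the
#' fraction of edges running between communities.
#'
#' @param g undirected simple igraph graph with `m >= 1`.
#' @param membership community label per vertex.
#' @param x positive integer scaling factor (`n' = x*n`; distribution
#'   parameters are unchanged under scaling).
#' @param mixing `"inter_over_total"` (default, standard LFR convention) or
#'   `"intra_over_inter"` for the literal intra/inter ratio.
#' @return a `reconet_model_params` (export-only; generation out of scope).
#' @export
fit_lfr <- function(g, membership, x = 1L,
                    mixing = c("inter_over_total", "intra_over_inter")) {
  mixing <- match.arg(mixing)
  check_graph(g)
  m <- igraph::ecount(g)
  if (m < 1) stop_data("LFR fitting needs at least one edge")
  memb <- canonical_membership(check_partition(g, membership))
  x <- as.integer(x)
  if (is.na(x) || x < 1L) stop_data("x must be a positive integer")
  deg <- igraph::degree(g)
  dfit <- plfit_degrees(deg)

  sizes <- as.integer(table(memb))
  degenerate <- length(sizes) == 1L
  c_min <- min(sizes); c_max <- max(sizes)
  sfit <- fit_powerlaw_exponent(c_min, c_max, mean(sizes))
  if (!degenerate && sfit$clamped && sfit$exponent == -1 &&
      sfit$achieved_avg < mean(sizes)) {
    lo <- c_min; hi <- c_max
    while (lo < hi) {
      mid <- (lo + hi) %/% 2L
      if (expected_avg_degree(-1, mid, c_max) < mean(sizes)) lo <- mid + 1L
      else hi <- mid
    }
    c_min <- lo
    sfit <- fit_powerlaw_exponent(c_min, c_max, mean(sizes))
  }
  sig <- extract_signature(g, memb)
  max_int <- max(sig$internal_degree)
  c_max <- max(c_max, ceiling(1.05 * max_int))

  e <- igraph::as_edgelist(g, names = FALSE)
  inter <- sum(memb[e[, 1]] != memb[e[, 2]])
  mu <- if (mixing == "inter_over_total") {
    inter / m
  } else {
    if (inter == 0) 0 else (m - inter) / inter
  }
  if (degenerate)
    warning("single-community partition: mu = 0 and the community-size",
            " fit is degenerate")
  new_model_params("lfr", list(
    n = x * igraph::vcount(g),
    gamma = dfit$exponent, d_min = dfit$d_min, d_max = dfit$d_max,
    beta = sfit$exponent, c_min = as.integer(c_min),
    c_max = as.integer(c_max), mu = mu, mixing = mixing,
    degenerate = degenerate))
}

#' Generate a graph from fitted model parameters
#'
#' Supports the natively generable models: Erdos-Renyi (`er`),
#' Barabasi-Albert preferential attachment seeded with a k-clique (`ba`),
#' Chung-Lu (`cl`: pair `{u,v}` present independently with probability
#' `min(1, d_u d_v / sum(d))`), the edge-switching Markov chain (`esmc`:
#' exact degree-sequence realization plus randomization), and R-MAT
#' (`rmat`: recursive quadrant sampling on a `2^s` grid with `2^s - n`
#' random nodes deleted, accepted edges counted until the surviving nodes
#' reach the target average degree). `hud`, `bter` and `lfr` parameters are
#' export-only and raise an error.
#'
#' @param params a `reconet_model_params`.
#' @param seed optional integer seed.
#' @return an igraph graph.
#' @export
generate_model <- function(params, seed = NULL) {
  if (!inherits(params, "reconet_model_params"))
    stop_data("expected a reconet_model_params object")
  if (!is.null(seed)) set.seed(seed)
  p <- params$params
  switch(params$model,
    er = igraph::sample_gnp(p$n, p$p),
    ba = {
      k <- p$k
      if (k < 1) return(igraph::make_empty_graph(p$n, directed = FALSE))
      igraph::sample_pa(p$n, m = k, directed = FALSE,
                        start.graph = igraph::make_full_graph(k))
    },
    cl = generate_chung_lu(p$degrees),
    esmc = realize_degree_sequence(p$degrees),
    rmat = generate_rmat(p),
    stop_usage("model '", params$model, "' is fit-only here; generable",
               " models: er, ba, cl, esmc, rmat"))
}

generate_chung_lu <- function(degrees) {
  n <- length(degrees)
  total <- sum(degrees)
  if (total == 0) return(igraph::make_empty_graph(n, directed = FALSE))
  parts <- vector("list", n - 1L)
  for (u in seq_len(n - 1L)) {
    v <- (u + 1L):n
    prob <- pmin(1, degrees[u] * degrees[v] / total)
    hit <- v[runif(length(v)) < prob]
    if (length(hit)) parts[[u]] <- cbind(u, hit)
  }
  e <- do.call(rbind, parts)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (!is.null(e)) g <- igraph::add_edges(g, t(e))
  g
}

generate_rmat <- function(p) {
  n_r <- p$n %||% 2^p$s
  target_avg <- p$avg_deg %||% (2 * p$e)
  grid <- 2^p$s
  keep <- sort(sample.int(grid, n_r))
  target_edges <- target_avg * n_r / 2
  res <- cpp_rmat_sample(p$s, p$a, p$b, p$c, p$d, keep, target_avg,
                         check_every = max(1L, as.integer(n_r)),
                         max_draws = max(1e5, 400 * target_edges),
                         seed = draw_master_seed())
  e <- res$edges
  g <- igraph::make_empty_graph(n_r, directed = FALSE)
  if (nrow(e)) {
    e <- matrix(match(as.vector(e), keep), ncol = 2)
    g <- igraph::add_edges(g, t(e))
  }
  if (igraph::ecount(g) < floor(target_edges))
    warning("R-MAT sampling stopped before reaching the target average",
            " degree (", igraph::ecount(g), " of ~", round(target_edges),
            " edges); initiator may concentrate mass too narrowly")
  g
}

#' Serialize / parse fitted model parameters as JSON
#'
#' The fit artifact: a small versioned JSON document that `cmd_fit` writes
#' and `cmd_generate` consumes.
#'
#' @param params a `reconet_model_params`.
#' @param path output path, or `NULL` to return the JSON text.
#' @return `write_model_params`: JSON text (invisibly when written);
#'   `read_model_params`: a `reconet_model_params`.
#' @export
write_model_params <- function(params, path = NULL) {
  validate_model_params(params)
  pp <- params$params
  for (nm in c("n_d", "c_d"))  # keep degree keys: atomic names drop in JSON
    if (!is.null(pp[[nm]])) pp[[nm]] <- as.list(pp[[nm]])
  doc <- list(format = "reconet-params", version = 1L,
              model = params$model, params = pp)
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(as.character(txt))
  writeLines(txt, path)
  invisible(as.character(txt))
}

#' @rdname write_model_params
#' @export
read_model_params <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(doc$format) || doc$format != "reconet-params")
    stop_data("not a reconet-params JSON document")
  p <- doc$params
  if (!is.null(p$degrees)) p$degrees <- as.integer(p$degrees)
  if (!is.null(p$n_d)) p$n_d <- unlist(p$n_d)
  if (!is.null(p$c_d)) p$c_d <- unlist(p$c_d)
  new_model_params(doc$model, p)
}
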