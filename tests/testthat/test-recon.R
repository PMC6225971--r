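test_that("signature extraction counts internal and external degrees", {
  g <- make_bridged_triangles()
  memb <- c(1, 1, 1, 2, 2, 2)
  sig <- extract_signature(g, memb)
  expect_equal(sig$internal_degree, rep(2L, 6))
  expect_equal(sig$external_degree, c(0L, 0L, 1L, 1L, 0L, 0L))
  expect_equal(sig$internal_degree + sig$external_degree,
               as.integer(igraph::degree(g)))

  all_in_one <- extract_signature(g, rep(1, 6))
  expect_equal(all_in_one$external_degree, rep(0L, 6))

  edgeless <- igraph::make_empty_graph(3, directed = FALSE)
  sig0 <- extract_signature(edgeless, 1:3)
  expect_equal(sig0$internal_degree, rep(0L, 3))
  expect_equal(sig0$external_degree, rep(0L, 3))
})

test_that("signature scaling copies communities with their quotas", {
  g <- make_bridged_triangles()
  sig <- extract_signature(g, c(1, 1, 1, 2, 2, 2))
  s2 <- scale_signature(sig, 2)
  expect_equal(nrow(s2), 12)
  expect_equal(length(unique(s2$community)), 4)
  expect_equal(sum(s2$internal_degree), 24)  # quota 12 edges
  expect_equal(sum(s2$external_degree), 4)
  expect_identical(scale_signature(sig, 1), sig)
  expect_error(scale_signature(sig, 0), "positive")

  tri_sig <- extract_signature(make_tri(), rep(1, 3))
  s5 <- scale_signature(tri_sig, 5)
  expect_equal(length(unique(s5$community)), 5)
  expect_equal(tapply(s5$internal_degree, s5$community, sum),
               setNames(rep(6, 5), 1:5), ignore_attr = TRUE)
  expect_equal(sum(s5$external_degree), 0)
})

test_that("generation from a signature realizes it exactly", {
  tri_sig <- extract_signature(make_tri(), rep(1, 3))
  expect_equal(canon_edges(generate_from_signature(tri_sig, seed = 1)),
               "1-2;1-3;2-3")

  g <- make_bridged_triangles()
  sig <- extract_signature(g, c(1, 1, 1, 2, 2, 2))
  r1 <- generate_from_signature(sig, seed = 2)
  expect_true(igraph::isomorphic(g, r1))

  r2 <- generate_from_signature(scale_signature(sig, 2), seed = 3)
  expect_equal(igraph::vcount(r2), 12)
  expect_equal(igraph::ecount(r2), 14)
  memb2 <- igraph::V(r2)$community
  e <- igraph::as_edgelist(r2)
  # each community is a triangle, external edges form a cross-community
  # matching on the 4 stub nodes
  for (c in unique(memb2)) {
    sub <- igraph::induced_subgraph(r2, which(memb2 == c))
    expect_equal(igraph::ecount(sub), 3)
  }
  ext <- e[memb2[e[, 1]] != memb2[e[, 2]], , drop = FALSE]
  expect_equal(nrow(ext), 2)
  expect_equal(anyDuplicated(c(ext)), 0)
})

test_that("replicas obey the conservation laws", {
  set.seed(31)
  fx <- planted_partition(3, 12, 0.45, 0.04, seed = 8)
  g <- fx$graph
  for (x in c(1, 4)) {
    r <- recon_replicate(g, x = x, seed = 17)
    expect_equal(igraph::vcount(r), x * igraph::vcount(g))
    expect_equal(igraph::ecount(r), x * igraph::ecount(g))
    expect_equal(sort(igraph::degree(r)),
                 sort(rep(igraph::degree(g), x)))
    expect_true(igraph::is_simple(r))
    expect_equal(r$residual_forbidden, 0)
  }
  expect_true(igraph::isomorphic(recon_replicate(make_tri(), 1, seed = 5),
                                 make_tri()))
})

test_that("replication is random but seed-reproducible", {
  fx <- planted_partition(4, 25, 0.5, 0.05, seed = 12)
  differ <- 0L
  for (s in 1:100) {
    a <- recon_replicate(fx$graph, 1, membership = fx$membership,
                         seed = 2 * s)
    b <- recon_replicate(fx$graph, 1, membership = fx$membership,
                         seed = 2 * s + 1)
    if (!identical(canon_edges(a), canon_edges(b))) differ <- differ + 1L
  }
  expect_gte(differ, 99L)
  r1 <- recon_replicate(fx$graph, 2, seed = 77)
  r2 <- recon_replicate(fx$graph, 2, seed = 77)
  expect_identical(canon_edges(r1), canon_edges(r2))
})

test_that("signature files round-trip and carry no edges", {
  g <- make_bridged_triangles()
  sig <- extract_signature(g, c(1, 1, 1, 2, 2, 2))
  txt <- write_signature(sig)
  expect_match(txt, "^#recon-signature v1")
  back <- read_signature(txt)
  expect_equal(back$community, sig$community)
  expect_equal(back$internal_degree, sig$internal_degree)
  expect_equal(back$external_degree, sig$external_degree)
  expect_error(read_signature("0 0 2 0\n1 0 2 0"), "header")
  # invalid signatures are rejected
  bad <- data.frame(node = 1:2, community = c(1L, 1L),
                    internal_degree = c(1L, 2L),
                    external_degree = c(0L, 0L))
  expect_error(reconet:::validate_signature(bad), "odd|exceeds")
})

test_that("strict mode errors on unresolvable forbidden edges", {
  # a community of two degree-0-internal nodes whose external degrees force
  # an intra-community placement: nodes {1,2} in one community, both with
  # external degree 1, and no other stubs to pair with
  sig <- structure(data.frame(node = 1:2, community = c(1L, 1L),
                              internal_degree = c(0L, 0L),
                              external_degree = c(1L, 1L)),
                   class = c("recon_signature", "data.frame"))
  expect_error(generate_from_signature(sig, seed = 1, strict = TRUE),
               class = "reconet_contract_error")
  expect_warning(r <- generate_from_signature(sig, seed = 1, strict = FALSE),
                 "forbidden")
  expect_equal(igraph::ecount(r), 1)
})
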