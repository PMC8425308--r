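test_that("edge-list loading filters by score and collapses to a simple graph", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# comment", "a\tb\t400", "b\tc\t300"), tsv)
  net <- read_edge_list(tsv, score_threshold = 350, quiet = TRUE)
  expect_equal(net$n_edges, 1L)
  expect_setequal(net$nodes, c("a", "b", "c"))
  expect_equal(unname(net$degree[c("a", "b", "c")]), c(1L, 1L, 0L))

  # duplicates, reversed duplicates and self-loops collapse
  net2 <- make_net(c("a", "b", "a"), c("b", "a", "a"))
  expect_equal(net2$n_edges, 1L)
  expect_equal(net2$n_nodes, 2L)

  tsv3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("a\tb", "b\tc", "c\ta", "a\tb"), tsv3)
  expect_equal(read_edge_list(tsv3, quiet = TRUE)$n_edges, 3L)
})

test_that("edge-list loading reports malformed lines and empty results", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("a\tb\t400", "b\tc\toops"), tsv)
  expect_error(read_edge_list(tsv, quiet = TRUE), "line 2")
  tsv2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines("a\tb\t100", tsv2)
  expect_error(read_edge_list(tsv2, score_threshold = 350, quiet = TRUE),
               "no edges")
})

test_that("network invariants hold on random graphs", {
  for (seed in 1:5) {
    net <- rand_net(25, 0.15, seed)
    A <- net$adjacency
    expect_true(Matrix::isSymmetric(A))
    expect_equal(sum(Matrix::diag(A)), 0)
    expect_equal(as.integer(Matrix::rowSums(A)), unname(net$degree))
    expect_equal(sum(A) / 2, net$n_edges)
  }
})

test_that("column normalization is column-stochastic with dangling columns zero", {
  star <- star_net(3)
  W <- as.matrix(column_normalize(star))
  expect_equal(unname(W[c("leaf1", "leaf2", "leaf3"), "hub"]), rep(1 / 3, 3))
  expect_equal(unname(W["hub", "leaf1"]), 1)

  net <- make_net("a", "b")
  expect_equal(as.matrix(column_normalize(net)),
               matrix(c(0, 1, 1, 0), 2, dimnames = list(c("a", "b"), c("a", "b"))))

  for (seed in 1:5) {
    net <- rand_net(30, 0.1, seed)
    cs <- Matrix::colSums(column_normalize(net))
    expect_true(all(abs(cs[net$degree > 0] - 1) < 1e-12))
  }
})

test_that("symmetric normalization matches A_ij / sqrt(k_i k_j)", {
  e <- make_net("a", "b")
  expect_equal(as.matrix(symmetric_normalize(e$adjacency)),
               as.matrix(e$adjacency))
  star <- star_net(3)
  S <- as.matrix(symmetric_normalize(star$adjacency))
  expect_equal(unname(S["hub", "leaf1"]), 1 / sqrt(3))
  expect_true(isSymmetric(S))

  Z <- matrix(0, 3, 3)
  expect_equal(as.matrix(symmetric_normalize(Z)), Z)
  expect_error(symmetric_normalize(matrix(c(0, 1, 0, 0), 2)), "symmetric")
})

test_that("two-community modularity matches the direct double-sum oracle", {
  two_edges <- make_net(c("a", "c"), c("b", "d"))
  expect_equal(two_community_modularity(two_edges, c("a", "b"))$Q, 0.625)
  expect_equal(two_community_modularity(two_edges, character())$Q, 0.125)

  for (seed in 1:5) {
    net <- rand_net(20, 0.2, seed)
    pathway <- sample(net$nodes, 7)
    expect_equal(two_community_modularity(net, pathway)$Q,
                 modularity_oracle(net, pathway), tolerance = 1e-12)
    expect_equal(two_community_modularity(net, pathway, diagonal = "standard")$Q,
                 modularity_oracle(net, pathway, zero_diag = FALSE),
                 tolerance = 1e-12)
    # complement symmetry: s -> -s leaves Q unchanged
    expect_equal(two_community_modularity(net, pathway)$Q,
                 two_community_modularity(net, setdiff(net$nodes, pathway))$Q)
  }
})

test_that("zero-diagonal and standard modularity differ by sum(k^2)/(8 m^2)", {
  net <- rand_net(15, 0.25, 9)
  q0 <- two_community_modularity(net, net$nodes[1:5])$Q
  qs <- two_community_modularity(net, net$nodes[1:5], diagonal = "standard")$Q
  expect_equal(q0 - qs, sum(net$degree^2) / (8 * net$n_edges^2))
})

test_that("tie-aware ranking averages tied positions and preserves rank sums", {
  rt <- rank_scores(tibble::tibble(gene = letters[1:4],
                                   score = c(0.5, 0.3, 0.3, 0.1)))
  expect_equal(rt$rank, c(1, 2.5, 2.5, 4))

  all_tied <- rank_scores(tibble::tibble(gene = letters[1:5], score = rep(1, 5)))
  expect_equal(all_tied$rank, rep(3, 5))

  set.seed(42)
  for (i in 1:10) {
    n <- sample(3:40, 1)
    scores <- sample(round(stats::runif(n), 1), n, replace = TRUE)
    rt <- rank_scores(tibble::tibble(gene = sprintf("g%02d", 1:n), score = scores))
    expect_equal(sum(rt$rank), n * (n + 1) / 2)
  }

  expect_error(rank_scores(tibble::tibble(gene = "a", score = NaN)), "finite")
  rt <- rank_scores(tibble::tibble(gene = c("a", "b", "c"), score = c(3, 2, 1)),
                    exclude = "a")
  expect_equal(rt$gene, c("b", "c"))
  expect_equal(rt$rank, c(1, 2))
})

test_that("degree baseline ranks by degree, independent of seeds", {
  star <- star_net(4)
  rt <- rank_scores(degree_baseline(star))
  expect_equal(rt$rank[rt$gene == "hub"], 1)
  expect_equal(unname(rt$rank[rt$gene != "hub"]), rep(3.5, 4))

  tri <- triangle_net()  # 2-regular
  expect_equal(rank_scores(degree_baseline(tri))$rank, rep(2, 3))

  expect_identical(degree_baseline(star, seeds = "leaf1"),
                   degree_baseline(star, seeds = c("leaf2", "hub")))
})

test_that("centrality profile reproduces hand-computed values on small graphs", {
  p <- centrality_profile(path_net(), c("a", "b", "c"))
  expect_equal(p$degree[p$vertex == "b"], 1)
  expect_equal(p$degree[p$vertex == "a"], 0.5)
  expect_equal(p$betweenness[p$vertex == "b"], 1)
  expect_equal(p$clustering[p$vertex %in% c("a", "b", "c")], rep(0, 3))

  tri <- centrality_profile(triangle_net(), c("a", "b"))
  expect_equal(tri$clustering[tri$vertex %in% c("a", "b")], rep(1, 2))

  k4 <- make_net(c("a", "a", "a", "b", "b", "c"),
                 c("b", "c", "d", "c", "d", "d"))
  pk4 <- centrality_profile(k4, k4$nodes)
  expect_equal(pk4$closeness[1:4], rep(1, 4))

  expect_error(centrality_profile(path_net(), c("a", "zzz")), "zzz")
})

test_that("pairwise seed distances: geodesics symmetric, walk affinity as derived", {
  tri <- triangle_net()
  d <- pairwise_seed_distance(tri, c("a", "b"))
  expect_equal(unname(diag(d)), c(0, 0))
  expect_equal(d["a", "b"], 1)
  expect_true(isSymmetric(d))

  two_comp <- make_net(c("a", "c"), c("b", "d"))
  d2 <- pairwise_seed_distance(two_comp, c("a", "c"))
  expect_equal(d2["a", "c"], Inf)

  e <- make_net("a", "b")
  aff <- pairwise_seed_distance(e, c("a", "b"), metric = "rwr", r = 0.5)
  expect_equal(aff["a", "b"], 1 / 3, tolerance = 1e-7)
})
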