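cycle_net <- function(n = 8) {
  ids <- sprintf("c%02d", seq_len(n))
  make_net(ids, ids[c(2:n, 1)])
}

two_clique_net <- function(size = 20) {
  ids1 <- sprintf("x%02d", seq_len(size))
  ids2 <- sprintf("y%02d", seq_len(size))
  edges <- function(ids) {
    pr <- utils::combn(ids, 2)
    tibble::tibble(source = pr[1, ], target = pr[2, ])
  }
  network_from_edges(dplyr::bind_rows(edges(ids1), edges(ids2)), quiet = TRUE)
}

test_that("walks have the requested shape and are seed-deterministic", {
  net <- cycle_net(8)
  wp <- walk_params(n_walks = 4, walk_length = 5, rng_seed = 3)
  walks <- sample_walks(net, wp)
  expect_length(walks, 4 * 8)
  expect_true(all(lengths(walks) == 5))
  # every step follows an edge
  A <- as.matrix(net$adjacency)
  ok <- vapply(walks, function(w) {
    all(A[cbind(w[-length(w)], w[-1])] == 1)
  }, logical(1))
  expect_true(all(ok))

  expect_identical(walks, sample_walks(net, wp))
  expect_false(identical(walks,
                         sample_walks(net, walk_params(4, 5, rng_seed = 4))))
})

test_that("unbiased walks leave a hub uniformly over its neighbours", {
  star <- star_net(4)
  walks <- sample_walks(star, walk_params(n_walks = 200, walk_length = 21,
                                          p = 1, q = 1, rng_seed = 1))
  steps_from_hub <- unlist(lapply(walks, function(w) {
    w[which(w[-length(w)] == "hub") + 1]
  }))
  counts <- table(factor(steps_from_hub, paste0("leaf", 1:4)))
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)
})

test_that("return bias p steers the walk back to the previous node", {
  net <- cycle_net(10)
  backtrack_rate <- function(p) {
    walks <- sample_walks(net, walk_params(n_walks = 30, walk_length = 20,
                                           p = p, q = 1, rng_seed = 5))
    mean(unlist(lapply(walks, function(w) {
      if (length(w) < 3) return(numeric(0))
      w[3:length(w)] == w[1:(length(w) - 2)]
    })))
  }
  expect_gt(backtrack_rate(0.1), backtrack_rate(10) + 0.2)
})

test_that("skip-gram training: shape, determinism, node coverage check", {
  net <- cycle_net(8)
  walks <- sample_walks(net, walk_params(5, 10, rng_seed = 2))
  emb <- train_embedding(walks, dim = 16, window = 3, epochs = 2, rng_seed = 4)
  expect_equal(dim(emb$vectors), c(8, 16))
  expect_true(all(is.finite(emb$vectors)))
  emb2 <- train_embedding(walks, dim = 16, window = 3, epochs = 2, rng_seed = 4)
  expect_identical(emb$vectors, emb2$vectors)

  expect_error(train_embedding(walks, dim = 8, nodes = c("c01", "ghost")),
               "ghost")
})

test_that("embedding separates two planted cliques", {
  net <- two_clique_net(20)
  walks <- sample_walks(net, walk_params(10, 20, rng_seed = 6))
  emb <- train_embedding(walks, dim = 32, window = 5, epochs = 3, rng_seed = 6)
  U <- emb$vectors / sqrt(rowSums(emb$vectors^2))
  sim <- U %*% t(U)
  in1 <- startsWith(rownames(U), "x")
  within <- mean(sim[in1, in1][upper.tri(sim[in1, in1])])
  across <- mean(sim[in1, !in1])
  expect_gt(within, across)
})

test_that("max-cosine scoring obeys its closed-form anchors", {
  V <- rbind(s = c(1, 0), o = c(0, 1), m = c(-1, 0), d = c(1, 1))
  model <- structure(list(vectors = V, dim = 2, meta = list()),
                     class = "node_embedding")
  sc <- n2v_score(model, "s")
  expect_equal(sc$score[sc$gene == "s"], 1)
  expect_equal(sc$score[sc$gene == "o"], 0)
  expect_equal(sc$score[sc$gene == "m"], -1)
  expect_equal(sc$score[sc$gene == "d"], cos(pi / 4), tolerance = 1e-7)
  expect_true(all(sc$score >= -1 & sc$score <= 1))

  V0 <- rbind(s = c(1, 0), z = c(0, 0))
  model0 <- structure(list(vectors = V0, dim = 2, meta = list()),
                      class = "node_embedding")
  expect_error(n2v_score(model0, "s"), "zero-norm")
})

test_that("seeded clique members outrank the other clique", {
  successes <- 0L
  reps <- 10L
  for (rep in seq_len(reps)) {
    net <- two_clique_net(20)
    seeds <- sprintf("x%02d", 1:5)
    scores <- n2v(net, seeds, walk = walk_params(10, 20, rng_seed = rep),
                  dim = 32, window = 5, epochs = 3, rng_seed = rep)
    rt <- rank_scores(scores, exclude = seeds)
    worst_in <- max(rt$rank[startsWith(rt$gene, "x")])
    best_out <- min(rt$rank[startsWith(rt$gene, "y")])
    if (worst_in < best_out) successes <- successes + 1L
  }
  expect_gte(successes, reps - 1L)
})

test_that("embeddings round-trip through TSV", {
  net <- cycle_net(6)
  walks <- sample_walks(net, walk_params(3, 8, rng_seed = 9))
  emb <- train_embedding(walks, dim = 8, window = 2, epochs = 1, rng_seed = 9)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_embedding(emb, tsv)
  back <- read_embedding(tsv)
  expect_equal(back$vectors, emb$vectors, tolerance = 1e-12)
})

test_that("heterogeneous embedding walks the expanded graph and returns gene scores", {
  fix <- simulate_hetero_fixture(n_genes = 40, module_sizes = 10,
                                 n_diseases = 5, n_seeds = 4, rng_seed = 13)
  sc <- n2v(fix$hnet, fix$seeds, walk = walk_params(5, 15, rng_seed = 13),
            dim = 16, window = 3, epochs = 2, rng_seed = 13)
  expect_setequal(sc$gene, fix$net$nodes)
  expect_true(all(sc$score[sc$gene %in% fix$seeds] == 1))
})
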