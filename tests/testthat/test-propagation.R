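test_that("restart walk: identity at r = 1 and the two-node closed form", {
  e <- make_net("a", "b")
  p1 <- rwr(e, "a", rwr_params(restart = 1))
  expect_equal(p1$score, c(1, 0))

  p <- rwr(e, "a", rwr_params(restart = 0.5))
  expect_equal(p$score, c(2 / 3, 1 / 3), tolerance = 1e-7)
})

test_that("iterative restart walk matches the dense closed-form solve", {
  for (seed in 1:10) {
    net <- rand_net(sample(10:50, 1), 0.15, seed)
    seeds <- sample(net$nodes, sample(1:3, 1))
    r <- sample(rwr_grid(), 1)
    p0 <- as.numeric(net$nodes %in% seeds) / length(seeds)
    expected <- rwr_oracle(column_normalize(net), p0, r)
    got <- rwr(net, seeds, rwr_params(restart = r))$score
    expect_equal(got, expected, tolerance = 1e-6)
  }
})

test_that("converged walk is a fixed point and approaches p0 as r -> 1", {
  net <- rand_net(30, 0.12, 3)
  seeds <- net$nodes[1:3]
  W <- column_normalize(net)
  p0 <- as.numeric(net$nodes %in% seeds) / 3
  params <- rwr_params(restart = 0.4)
  p <- rwr(net, seeds, params)$score
  residual <- sum(abs((1 - 0.4) * as.numeric(W %*% p) + 0.4 * p0 - p))
  expect_lt(residual, params$tolerance)
  expect_equal(sum(p), 1, tolerance = 1e-9)

  dev <- vapply(c(0.5, 0.8, 0.95, 0.999), function(r) {
    sum(abs(rwr(net, seeds, rwr_params(restart = r))$score - p0))
  }, numeric(1))
  expect_true(all(diff(dev) < 0))
  expect_lt(dev[4], 0.01)
})

test_that("restart walk errors on unknown seeds and non-convergence", {
  net <- rand_net(10, 0.3, 1)
  expect_error(rwr(net, "nope"), "not in network")
  expect_error(rwr(net, net$nodes[1], rwr_params(restart = 0.1, max_iter = 2)),
               "converge")
})

test_that("heterogeneous walk: dimensions, block reduction and dense oracle", {
  net <- make_net(c("a", "b", "c", "d", "a"), c("b", "c", "d", "e", "c"))
  gda <- tibble::tibble(gene = net$nodes[1:2], disease = c("d1", "d2"))
  dsim <- tibble::tibble(a = "d1", b = "d2")
  hnet <- hetero_network(net, gda, dsim)
  expect_equal(dim(hnet$expanded), c(7, 7))
  expect_true(Matrix::isSymmetric(hnet$expanded))
  expect_equal(as.matrix(hnet$expanded[1:5, 1:5]), as.matrix(net$adjacency))
  expect_equal(as.matrix(hnet$expanded[1:5, 6:7]), as.matrix(hnet$gda))

  # empty cross-layer blocks: gene scores identical to the plain walk
  empty <- hetero_network(net, tibble::tibble(gene = character(),
                                              disease = character()),
                          disease_ids = c("d1", "d2"))
  seeds <- net$nodes[1:2]
  expect_equal(rwrh(empty, seeds)$score, rwr(net, seeds)$score,
               tolerance = 1e-12)

  # dense oracle on the expanded matrix
  W <- column_normalize(hnet$expanded)
  p0 <- c(as.numeric(net$nodes %in% seeds) / 2, 0, 0)
  expected <- rwr_oracle(W, p0, 0.5)
  got <- rwrh(hnet, seeds, params = rwr_params(restart = 0.5))
  expect_equal(got$score, expected[1:5], tolerance = 1e-6)
  expect_equal(unname(attr(got, "disease_scores")), expected[6:7],
               tolerance = 1e-6)
})

test_that("heterogeneous walk validates disease ids and restart split", {
  net <- rand_net(6, 0.4, 5)
  hnet <- hetero_network(net, tibble::tibble(gene = net$nodes[1],
                                             disease = "d1"))
  expect_error(rwrh(hnet, net$nodes[1], disease = "dX"), "dX")
  expect_error(rwrh(hnet, net$nodes[1], disease_weight = 0.3), "disease")
  withdw <- rwrh(hnet, net$nodes[1], disease = "d1", disease_weight = 0.3)
  expect_equal(sum(withdw$score) + sum(attr(withdw, "disease_scores")), 1,
               tolerance = 1e-9)
})

test_that("dual label propagation: trivial coefficients return the seed indicator", {
  fix <- simulate_hetero_fixture(n_genes = 30, module_sizes = 8,
                                 n_diseases = 5, n_seeds = 4, rng_seed = 11)
  y <- idlp(fix$hnet, fix$seeds,
            idlp_params(alpha = 0, beta = 1, gamma = 0,
                        alpha2 = 0, beta2 = 1, gamma2 = 0, n_iter = 3))
  expect_equal(y$score, as.numeric(y$gene %in% fix$seeds))
})

test_that("dual label propagation change sequence settles after burn-in", {
  fix <- simulate_hetero_fixture(n_genes = 30, module_sizes = 8,
                                 n_diseases = 5, n_seeds = 4, rng_seed = 7)
  y <- idlp(fix$hnet, fix$seeds, idlp_params(n_iter = 12))
  delta <- attr(y, "delta")
  expect_length(delta, 12)
  expect_true(all(diff(delta[3:12]) <= 1e-8))
  expect_true(all(is.finite(y$score)))
})

test_that("dual label propagation is reproducible via the recorded init seed", {
  fix <- simulate_hetero_fixture(n_genes = 25, module_sizes = 6,
                                 n_diseases = 4, n_seeds = 3, rng_seed = 2)
  p <- idlp_params(n_iter = 4, init_seed = 99L)
  expect_identical(idlp(fix$hnet, fix$seeds, p)$score,
                   idlp(fix$hnet, fix$seeds, p)$score)
})
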