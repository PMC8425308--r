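test_that("degree-baseline cross-validation is seed-independent", {
  net <- rand_net(40, 0.12, 2)
  seeds <- sample(net$nodes, 10)
  res <- loocv(net, seeds, "degree")
  expect_equal(nrow(res$folds), 10)
  # expected fold rank: the seed's degree rank among itself + non-seeds
  expected <- vapply(seeds, function(g) {
    rt <- rank_scores(degree_baseline(net), exclude = setdiff(seeds, g))
    rt$rank[rt$gene == g]
  }, numeric(1))
  expect_equal(res$folds$rank, unname(expected))
  expect_equal(res$median, stats::median(res$folds$rank))
  expect_equal(res$mean, mean(res$folds$rank))
})

test_that("even fold counts use the midpoint median convention", {
  net <- rand_net(30, 0.15, 4)
  seeds <- sample(net$nodes, 4)
  res <- loocv(net, seeds, "rwr", params = rwr_params(restart = 0.5))
  r <- sort(res$folds$rank)
  expect_equal(res$median, (r[2] + r[3]) / 2)
})

test_that("heterogeneous folds remove the disease-gene edge and restore bitwise", {
  fix <- simulate_hetero_fixture(n_genes = 40, module_sizes = 10,
                                 n_diseases = 5, n_seeds = 5, rng_seed = 21)
  hnet <- fix$hnet
  snapshot <- hnet
  seen <- new.env()
  seen$edge_present <- logical(0)
  probe <- function(net, seeds, ...) {
    left_out <- setdiff(fix$seeds, seeds)
    seen$edge_present <- c(seen$edge_present,
                           net$gda[left_out, fix$disease] != 0)
    rwrh(net, seeds)
  }
  res <- loocv(hnet, fix$seeds, probe, disease = fix$disease)
  expect_length(seen$edge_present, 5)
  expect_false(any(seen$edge_present))
  expect_identical(hnet, snapshot)
  # and every left-out module seed is rediscovered with a finite rank
  expect_true(all(is.finite(res$folds$rank)))
})

test_that("failing folds are reported as NA without aborting the run", {
  net <- rand_net(30, 0.15, 6)
  seeds <- sample(net$nodes, 4)
  flaky <- local({
    calls <- 0
    function(net, seeds, ...) {
      calls <<- calls + 1
      if (calls == 2) stop("boom")
      degree_baseline(net)
    }
  })
  expect_warning(res <- loocv(net, seeds, flaky), "boom")
  expect_equal(res$n_na, 1)
  expect_equal(sum(is.na(res$folds$rank)), 1)
  expect_true(is.finite(res$median))
  expect_true(is.finite(res$median_worst))
})

test_that("random-seed trials are counted, reproducible and hub-dominated", {
  star <- star_net(12)
  res <- random_seed_experiment(star, "rwr", n_trials = 3,
                                seeds_per_trial = 4, rng_seed = 5)
  expect_equal(res$n_trials, 3L)
  expect_equal(res$medians$median_rank[res$medians$gene == "hub"], 1)

  res2 <- random_seed_experiment(star, "rwr", n_trials = 3,
                                 seeds_per_trial = 4, rng_seed = 5)
  expect_identical(res$medians, res2$medians)
  res3 <- random_seed_experiment(star, "rwr", n_trials = 3,
                                 seeds_per_trial = 4, rng_seed = 6)
  expect_false(identical(res$medians$median_rank, res3$medians$median_rank))
})

test_that("tracked genes keep their full rank distribution", {
  net <- rand_net(25, 0.2, 8)
  res <- random_seed_experiment(net, "degree", n_trials = 4,
                                seeds_per_trial = 3, rng_seed = 1,
                                track = net$nodes[1:2])
  expect_equal(nrow(res$track_ranks), 8)
  expect_setequal(unique(res$track_ranks$gene), net$nodes[1:2])
})

test_that("degree-rank association: perfect order gives rho = -1, noise near 0", {
  fake <- function(medians) {
    structure(list(medians = medians, algorithm = "fake"),
              class = "random_seed_result")
  }
  net <- rand_net(50, 0.1, 9)
  deg <- as.numeric(net$degree) + stats::runif(net$n_nodes) * 1e-6  # break ties
  perfect <- fake(tibble::tibble(gene = net$nodes, degree = deg,
                                 median_rank = rank(-deg)))
  expect_equal(degree_rank_association(perfect, net)$spearman, -1)

  set.seed(10)
  big <- tibble::tibble(gene = sprintf("g%04d", 1:1000),
                        degree = stats::rexp(1000) + 1e-9,
                        median_rank = sample(1:1000))
  shuffled <- fake(big)
  fake_net <- list(nodes = big$gene)
  rho <- degree_rank_association(shuffled, fake_net)$spearman
  expect_lt(abs(rho), 0.1)

  const <- fake(tibble::tibble(gene = net$nodes, degree = deg,
                               median_rank = rep(1, net$n_nodes)))
  expect_true(is.na(degree_rank_association(const, net)$spearman))
})

test_that("SNPs map to flanked gene regions, including shared overlaps", {
  regions <- tibble::tibble(gene = c("gA", "gB"), chrom = c("1", "1"),
                            start = c(5000, 5500), end = c(6000, 7000))
  gwas <- tibble::tibble(snp = c("s1", "s2", "s3", "s4"),
                         chrom = "1",
                         pos = c(4001, 3999, 5600, 7500),
                         pvalue = c(0.1, 0.2, 0.3, 0.4))
  mapped <- map_snps_to_genes(gwas, regions, flank = 1000)
  expect_true(all(c("gA", "gB") %in% mapped$gene[mapped$snp == "s3"]))
  expect_true("s1" %in% mapped$snp[mapped$gene == "gA"])
  expect_false("s2" %in% mapped$snp)
  expect_false("s4" %in% mapped$snp[mapped$gene == "gA"])

  gwas_bad <- dplyr::bind_rows(gwas,
                               tibble::tibble(snp = "sX", chrom = NA,
                                              pos = 1, pvalue = 0.5))
  expect_message(map_snps_to_genes(gwas_bad, regions), "1 malformed")
})

test_that("pooled BH adjustment follows the textbook step-up", {
  regions <- tibble::tibble(gene = "gA", chrom = "1", start = 1000, end = 2000)
  gwas <- tibble::tibble(snp = paste0("s", 1:4), chrom = "1",
                         pos = 1100 + 1:4, pvalue = c(0.01, 0.02, 0.03, 0.04))
  ranks <- tibble::tibble(gene = "gA", rank = 1)
  val <- gwas_validate(ranks, gwas, regions, top_n = 1, fdr = 0.05)
  expect_equal(val$snp_table$p_adj, rep(0.04, 4))
  expect_equal(val$n_sig_snps, 4)
  expect_equal(val$n_validated, 1)
})

test_that("validation calls exactly the planted signal genes", {
  genes <- sprintf("g%03d", 1:40)
  regions <- simulate_gene_regions(genes)
  planted <- genes[c(3, 9, 17, 25, 33)]
  gwas <- simulate_gwas(regions, planted, snps_per_gene = 10,
                        effect_p = 1e-8, rng_seed = 4)
  ranks <- tibble::tibble(gene = genes, rank = seq_along(genes))
  val <- gwas_validate(ranks, gwas, regions, top_n = 40, fdr = 0.05)
  validated <- val$gene_table$gene[val$gene_table$validated]
  expect_setequal(validated, planted)

  none <- gwas_validate(ranks, gwas, regions, top_n = 40, fdr = 0)
  expect_equal(none$n_validated, 0)
})

test_that("genes whose SNPs never pass are never validated", {
  genes <- sprintf("g%03d", 1:20)
  regions <- simulate_gene_regions(genes)
  gwas <- simulate_gwas(regions, character(), snps_per_gene = 8, rng_seed = 2)
  ranks <- tibble::tibble(gene = genes, rank = seq_along(genes))
  val <- gwas_validate(ranks, gwas, regions, top_n = 20, fdr = 0.05)
  never <- dplyr::filter(val$gene_table, n_sig == 0)
  expect_false(any(never$validated))
})

test_that("confirmed-gene metrics count hits within the top fraction", {
  ranks <- tibble::tibble(gene = sprintf("g%03d", 1:100), rank = 1:100)
  confirmed <- sprintf("g%03d", 1:7)
  cm <- confirmed_gene_metrics(ranks, confirmed, top_frac = 0.1)
  expect_equal(cm$median_rank, 4)
  expect_equal(cm$n_hits, 7)
  expect_equal(cm$hits$gene, confirmed)

  expect_message(
    cm2 <- confirmed_gene_metrics(ranks, c("g001", "ghost"), top_frac = 0.1),
    "ghost")
  expect_equal(cm2$missing, "ghost")
  expect_equal(cm2$median_rank, 1)
  expect_error(confirmed_gene_metrics(ranks, character()), "confirmed")
})
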