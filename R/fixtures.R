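#' Simulate a scale-free gene network with planted functional modules
#'
#' Builds a desk-scale stand-in for a curated protein-gene interaction
#' network: a preferential-attachment (Barabasi-Albert) backbone gives the
#' heavy-tailed degree distribution real interactomes show, and one or
#' more planted modules -- node subsets whose internal edges are added as
#' independent Bernoulli(p_within) draws -- emulate the dense functional
#' pathways that make guilt-by-association work. Ground-truth membership
#' is returned so recovery can be scored.
#'
#' @param n_genes Number of genes (default 500).
#' @param attach Edges added per node in the preferential-attachment
#'   backbone (default 10, matching the roughly 20-neighbour mean degree and heavy tail of curated human interactomes).
#' @param module_sizes Integer vector of planted module sizes (default 30).
#' @param p_within Within-module edge probability (default 0.5).
#' @param rng_seed Integer seed; identical seeds give identical networks.
#' @return A list with `net` (a `gene_network`), `membership` (tibble
#'   `gene`, `module`; module 0 = background) and `rng_seed`. Gene ids are
#'   zero-padded `g0001`-style strings.
#' @export
simulate_modular_network <- function(n_genes = 500L, attach = 10L,
                                     module_sizes = 30L, p_within = 0.5,
                                     rng_seed = 1L) {
  stopifnot(n_genes > 2, all(module_sizes <= n_genes), p_within >= 0,
            p_within <= 1)
  set.seed(rng_seed)
  ids <- sprintf("g%0*d", nchar(n_genes), seq_len(n_genes))
  g <- igraph::sample_pa(n_genes, m = attach, directed = FALSE)
  el <- igraph::as_edgelist(g, names = FALSE)
  edges <- tibble::tibble(source = ids[el[, 1]], target = ids[el[, 2]])
  membership <- stats::setNames(rep(0L, n_genes), ids)
  free <- ids
  for (mod in seq_along(module_sizes)) {
    members <- sample(free, module_sizes[mod])
    free <- setdiff(free, members)
    membership[members] <- mod
    pairs <- utils::combn(sort(members), 2)
    keep <- stats::runif(ncol(pairs)) < p_within
    if (any(keep)) {
      edges <- dplyr::bind_rows(
        edges,
        tibble::tibble(source = pairs[1, keep], target = pairs[2, keep])
      )
    }
  }
  net <- network_from_edges(edges, quiet = TRUE)
  # preferential attachment leaves no isolates, so all ids are present
  list(net = net,
       membership = tibble::tibble(gene = ids,
                                   module = unname(membership[ids])),
       rng_seed = as.integer(rng_seed))
}

#' Simulate a disease-gene heterogeneous fixture
#'
#' Wraps [simulate_modular_network()] and adds the two extra layers a
#' heterogeneous prioritizer needs: a bipartite gene-disease association
#' layer of given density, a disease-similarity layer, and a designated
#' query disease whose associations are exactly the seed genes (drawn from
#' the first planted module). The query disease is linked into the
#' similarity layer to a few random diseases so that propagation can reach
#' the rest of the disease layer.
#'
#' @inheritParams simulate_modular_network
#' @param n_diseases Background diseases (default 20).
#' @param gda_density Probability of a (gene, disease) association
#'   (default 0.01).
#' @param dsim_density Probability of a disease-disease similarity edge
#'   (default 0.2).
#' @param n_seeds Seed genes drawn from the first planted module
#'   (default 10).
#' @return A list with `hnet` (a `hetero_network`), `disease` (query id),
#'   `seeds`, `membership`, `net` and `rng_seed`.
#' @export
simulate_hetero_fixture <- function(n_genes = 500L, attach = 10L,
                                    module_sizes = 30L, p_within = 0.5,
                                    n_diseases = 20L, gda_density = 0.01,
                                    dsim_density = 0.2, n_seeds = 10L,
                                    rng_seed = 1L) {
  stopifnot(n_seeds <= module_sizes[1])
  fix <- simulate_modular_network(n_genes, attach, module_sizes, p_within,
                                  rng_seed)
  set.seed(rng_seed + 1L)
  ids <- fix$net$nodes
  diseases <- sprintf("d%02d", seq_len(n_diseases))
  query <- "d_query"
  module1 <- fix$membership$gene[fix$membership$module == 1]
  seeds <- sort(sample(module1, n_seeds))
  grid <- expand.grid(gene = ids, disease = diseases,
                      stringsAsFactors = FALSE)
  gda <- grid[stats::runif(nrow(grid)) < gda_density, ]
  gda <- dplyr::bind_rows(tibble::as_tibble(gda),
                          tibble::tibble(gene = seeds, disease = query))
  pairs <- utils::combn(c(diseases, query), 2)
  keep <- stats::runif(ncol(pairs)) < dsim_density
  dsim <- tibble::tibble(disease1 = pairs[1, keep], disease2 = pairs[2, keep])
  hnet <- hetero_network(fix$net, gda, dsim,
                         disease_ids = c(diseases, query))
  list(hnet = hnet, disease = query, seeds = seeds,
       membership = fix$membership, net = fix$net,
       rng_seed = as.integer(rng_seed))
}

#' Simulate gene regions on a toy genome
#'
#' Lays genes head-to-tail on one chromosome with fixed length and gap,
#' giving a deterministic region table in the 1-based inclusive dialect
#' the SNP mapper expects.
#'
#' @param genes Character vector of gene ids.
#' @param chrom Chromosome label.
#' @param gene_length,gap Basepairs per gene and between genes.
#' @return A tibble `gene`, `chrom`, `start`, `end`.
#' @export
simulate_gene_regions <- function(genes, chrom = "1", gene_length = 10000L,
                                  gap = 20000L) {
  n <- length(genes)
  start <- gap + (seq_len(n) - 1L) * (gene_length + gap) + 1L
  tibble::tibble(gene = genes, chrom = chrom, start = start,
                 end = start + gene_length - 1L)
}

#' Simulate a GWAS summary-statistics table
#'
#' Emulates SNP-level association results with known ground truth: every
#' gene region receives `snps_per_gene` SNPs at uniform positions within
#' its flanked region; SNPs in `enriched_genes` draw p-values uniformly
#' below `effect_p` (strong association), all others draw p ~ Uniform(0,1)
#' (null). Optionally adds intergenic null SNPs.
#'
#' @param regions Gene-region table (`gene`, `chrom`, `start`, `end`).
#' @param enriched_genes Genes carrying true signal (subset of
#'   `regions$gene`).
#' @param snps_per_gene SNPs simulated per gene (default 10).
#' @param effect_p Upper bound of p-values in enriched genes
#'   (default 1e-8).
#' @param flank Flank within which positions are drawn (matches the
#'   mapper's flank).
#' @param rng_seed Integer seed.
#' @return A tibble `snp`, `chrom`, `pos`, `pvalue`.
#' @export
simulate_gwas <- function(regions, enriched_genes = character(),
                          snps_per_gene = 10L, effect_p = 1e-8,
                          flank = 1000L, rng_seed = 1L) {
  missing <- setdiff(enriched_genes, regions$gene)
  if (length(missing) > 0) {
    stop(sprintf("enriched gene(s) not in regions: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  set.seed(rng_seed)
  rows <- purrr::pmap(regions, function(gene, chrom, start, end, ...) {
    pos <- sort(sample((start - flank):(end + flank), snps_per_gene))
    p <- if (gene %in% enriched_genes) {
      stats::runif(snps_per_gene, 0, effect_p)
    } else {
      stats::runif(snps_per_gene)
    }
    tibble::tibble(chrom = chrom, pos = pos, pvalue = p)
  })
  out <- dplyr::bind_rows(rows)
  out |>
    dplyr::mutate(snp = sprintf("rs%06d", seq_len(nrow(out))), .before = 1) |>
    dplyr::arrange(.data$chrom, .data$pos)
}
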