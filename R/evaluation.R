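#' Leave-one-out cross-validation of a prioritizer
#'
#' The rediscovery benchmark: each seed gene in turn is left out, the
#' algorithm is run from the remaining seeds, and the rank the left-out
#' gene receives among non-seed candidates is recorded (its LOOCV rank;
#' lower is better). On a heterogeneous network the association edge
#' between the query disease and the left-out gene is also removed for the
#' duration of the fold, so the disease layer cannot leak the answer, and
#' the network is restored bitwise afterwards. Remaining seeds are
#' excluded from the candidate ranking by default. Folds where the
#' algorithm assigns the left-out gene no rank (e.g. DIAMOnD beyond its
#' step budget) are reported as NA, and summary statistics are given both
#' over available ranks and with NA folds counted at worst-case rank.
#'
#' @param net A `gene_network` or `hetero_network`.
#' @param seeds Character vector of >= 2 seed gene ids.
#' @param algorithm Key or function, see [run_prioritizer()].
#' @param disease Query-disease id; needed for the leakage-safe edge
#'   removal on heterogeneous networks.
#' @param exclude_seeds Exclude the remaining seeds from each fold's
#'   candidate ranking (default TRUE).
#' @param params,model,... Passed to [run_prioritizer()]. For `n2v` an
#'   embedding is trained once and reused across folds (it does not depend
#'   on the seed set); for `n2vh` the expanded network changes per fold,
#'   so the embedding is retrained per fold unless `model` is supplied.
#' @return An object of class `loocv_result`: list with `folds` (tibble
#'   `seed`, `rank`), `median`, `mean`, `median_worst`, `n_na`,
#'   `n_candidates`, `algorithm`.
#' @export
loocv <- function(net, seeds, algorithm, disease = NULL,
                  exclude_seeds = TRUE, params = NULL, model = NULL, ...) {
  gnet <- if (is_hetero_network(net)) net$gene_net else net
  seeds <- check_seeds(gnet, seeds)
  if (length(seeds) < 2) stop("LOOCV needs at least 2 seeds", call. = FALSE)
  hetero_fold <- is_hetero_network(net) && !is.null(disease)
  if (is.null(model) && is.character(algorithm) && algorithm == "n2v") {
    model <- maybe_train_model("n2v", net, params = params, ...)
  }
  ranks <- vapply(seeds, function(g) {
    rest <- setdiff(seeds, g)
    fold_net <- if (hetero_fold) set_gda_edge(net, g, disease, 0) else net
    scores <- tryCatch(
      run_prioritizer(algorithm, fold_net, rest, disease = disease,
                      params = params, model = model, ...),
      error = function(e) {
        warning(sprintf("fold for '%s' failed: %s", g, conditionMessage(e)))
        NULL
      }
    )
    if (is.null(scores)) return(NA_real_)
    rt <- rank_scores(scores, exclude = if (exclude_seeds) rest else NULL,
                      na_rm = TRUE)
    r <- rt$rank[match(g, rt$gene)]
    if (length(r) == 0) NA_real_ else r
  }, numeric(1))
  n_candidates <- gnet$n_nodes - if (exclude_seeds) length(seeds) - 1 else 0
  ranks_worst <- ifelse(is.na(ranks), n_candidates, ranks)
  structure(
    list(folds = tibble::tibble(seed = seeds, rank = unname(ranks)),
         median = stats::median(ranks, na.rm = TRUE),
         mean = mean(ranks, na.rm = TRUE),
         median_worst = stats::median(ranks_worst),
         n_na = sum(is.na(ranks)),
         n_candidates = n_candidates,
         algorithm = if (is.character(algorithm)) algorithm else "custom"),
    class = "loocv_result"
  )
}

#' @export
print.loocv_result <- function(x, ...) {
  cat(sprintf("<loocv_result> %s: median rank %s, mean %s over %d fold(s) (%d na)\n",
              x$algorithm, format(x$median), format(round(x$mean, 2)),
              nrow(x$folds), x$n_na))
  invisible(x)
}

#' Random-seed degree-bias experiment
#'
#' Measures what a prioritizer ranks well *regardless* of the seeds:
#' in each trial a fresh seed set is drawn uniformly at random, the
#' algorithm is run, and every node's rank is recorded; the per-node
#' median rank across trials isolates the seed-independent component of
#' the ranking (for propagation methods this is dominated by degree).
#' Embeddings are trained once and reused, since they do not depend on
#' the seed draw.
#'
#' @param net A `gene_network`.
#' @param algorithm Key or function, see [run_prioritizer()].
#' @param n_trials Number of trials (the reference protocol uses 1000).
#' @param seeds_per_trial Seeds drawn per trial (default 10).
#' @param rng_seed Integer seed making the trial sequence reproducible.
#' @param track Optional gene ids whose full rank distribution is kept.
#' @param params,model,... Passed to [run_prioritizer()].
#' @return An object of class `random_seed_result`: list with `medians`
#'   (tibble `gene`, `degree`, `median_rank`), `track_ranks` (tibble
#'   `gene`, `trial`, `rank`), `n_trials`, `seeds_per_trial`, `rng_seed`,
#'   `algorithm`, `n_failed`.
#' @export
random_seed_experiment <- function(net, algorithm, n_trials = 1000L,
                                   seeds_per_trial = 10L, rng_seed = 1L,
                                   track = character(), params = NULL,
                                   model = NULL, ...) {
  stopifnot(is_gene_network(net), net$n_nodes > seeds_per_trial)
  if (is.null(model)) {
    model <- maybe_train_model(if (is.character(algorithm)) algorithm else "",
                               net, params = params, ...)
  }
  set.seed(rng_seed)
  rank_mat <- matrix(NA_real_, net$n_nodes, n_trials,
                     dimnames = list(net$nodes, NULL))
  n_failed <- 0L
  for (trial in seq_len(n_trials)) {
    seeds <- sample(net$nodes, seeds_per_trial)
    scores <- tryCatch(
      run_prioritizer(algorithm, net, seeds, params = params, model = model, ...),
      error = function(e) {
        warning(sprintf("trial %d failed: %s", trial, conditionMessage(e)))
        NULL
      }
    )
    if (is.null(scores)) { n_failed <- n_failed + 1L; next }
    rt <- rank_scores(scores, na_rm = TRUE)
    rank_mat[rt$gene, trial] <- rt$rank
  }
  med <- apply(rank_mat, 1, stats::median, na.rm = TRUE)
  track <- intersect(track, net$nodes)
  track_ranks <- if (length(track) > 0) {
    tibble::tibble(
      gene = rep(track, each = n_trials),
      trial = rep(seq_len(n_trials), length(track)),
      rank = as.numeric(t(rank_mat[track, , drop = FALSE]))
    )
  } else {
    tibble::tibble(gene = character(), trial = integer(), rank = numeric())
  }
  structure(
    list(medians = tibble::tibble(gene = net$nodes,
                                  degree = as.numeric(net$degree),
                                  median_rank = unname(med)),
         track_ranks = track_ranks,
         n_trials = as.integer(n_trials),
         seeds_per_trial = as.integer(seeds_per_trial),
         rng_seed = as.integer(rng_seed),
         algorithm = if (is.character(algorithm)) algorithm else "custom",
         n_failed = n_failed),
    class = "random_seed_result"
  )
}

#' @export
print.random_seed_result <- function(x, ...) {
  cat(sprintf("<random_seed_result> %s: %d trial(s) x %d seed(s), %d node(s)\n",
              x$algorithm, x$n_trials, x$seeds_per_trial, nrow(x$medians)))
  invisible(x)
}

#' Degree dependency of random-seed ranks
#'
#' Summarizes how strongly a prioritizer's seed-independent ranking tracks
#' node degree: the Spearman correlation between degree and median
#' random-seed rank (negative = high-degree nodes rank well no matter the
#' seeds) plus a degree-decile table of median ranks for plotting.
#'
#' @param result A `random_seed_result`.
#' @param net The `gene_network` it was run on.
#' @return A list of class `degree_bias`: `spearman` (rho, or NA when the
#'   ranks are constant), `p_value`, `deciles` (tibble `decile`,
#'   `mean_degree`, `median_rank`), `algorithm`.
#' @export
degree_rank_association <- function(result, net) {
  stopifnot(identical(sort(result$medians$gene), sort(net$nodes)))
  df <- dplyr::filter(result$medians, !is.na(.data$median_rank))
  if (stats::sd(df$median_rank) == 0 || stats::sd(df$degree) == 0) {
    rho <- NA_real_; pv <- NA_real_
  } else {
    ct <- suppressWarnings(
      stats::cor.test(df$degree, df$median_rank, method = "spearman"))
    rho <- unname(ct$estimate); pv <- ct$p.value
  }
  deciles <- df |>
    dplyr::mutate(decile = dplyr::ntile(.data$degree, 10)) |>
    dplyr::group_by(.data$decile) |>
    dplyr::summarise(mean_degree = mean(.data$degree),
                     median_rank = stats::median(.data$median_rank),
                     .groups = "drop")
  structure(list(spearman = rho, p_value = pv, deciles = deciles,
                 algorithm = result$algorithm),
            class = "degree_bias")
}

#' @export
print.degree_bias <- function(x, ...) {
  cat(sprintf("<degree_bias> %s: Spearman rho = %s (p = %s)\n",
              x$algorithm, format(x$spearman), format(x$p_value)))
  invisible(x)
}

#' Read a gene-region table
#'
#' `format = "tsv"` expects 1-based inclusive columns
#' `gene  chrom  start  end`; `format = "bed"` expects BED order
#' `chrom  start  end  gene` with 0-based half-open coordinates, converted
#' to 1-based inclusive on read.
#'
#' @param path Path to the file.
#' @param format `"tsv"` or `"bed"`.
#' @return A tibble `gene`, `chrom`, `start`, `end` (1-based inclusive).
#' @export
read_gene_regions <- function(path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  raw <- readr::read_tsv(path, comment = "#", col_names = FALSE,
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (format == "bed") {
    tibble::tibble(gene = raw[[4]], chrom = raw[[1]],
                   start = as.integer(raw[[2]]) + 1L,
                   end = as.integer(raw[[3]]))
  } else {
    tibble::tibble(gene = raw[[1]], chrom = raw[[2]],
                   start = as.integer(raw[[3]]), end = as.integer(raw[[4]]))
  }
}

#' Map SNPs to genes by genomic position
#'
#' Assigns a SNP to every gene whose region, widened by `flank` bp on both
#' sides, contains its position on the same chromosome (1-based inclusive
#' coordinates; chromosomes compared as strings). A SNP inside two
#' overlapping regions maps to both genes. Rows with missing chromosome,
#' position or p-value are skipped and counted.
#'
#' @param gwas Data frame with columns `snp`, `chrom`, `pos`, `pvalue`.
#' @param regions Data frame with columns `gene`, `chrom`, `start`, `end`
#'   (1-based inclusive), e.g. from [read_gene_regions()].
#' @param flank Basepairs added on each side of the gene region
#'   (default 1000).
#' @return A tibble `gene`, `snp`, `chrom`, `pos`, `pvalue`, one row per
#'   (SNP, gene) assignment.
#' @export
map_snps_to_genes <- function(gwas, regions, flank = 1000L) {
  gwas <- tibble::tibble(snp = as.character(gwas[["snp"]]),
                         chrom = as.character(gwas[["chrom"]]),
                         pos = as.numeric(gwas[["pos"]]),
                         pvalue = as.numeric(gwas[["pvalue"]]))
  bad <- is.na(gwas$chrom) | is.na(gwas$pos) | is.na(gwas$pvalue)
  if (any(bad)) {
    message(sprintf("map_snps_to_genes: skipped %d malformed SNP row(s)", sum(bad)))
    gwas <- gwas[!bad, ]
  }
  reg <- tibble::tibble(gene = as.character(regions[["gene"]]),
                        chrom = as.character(regions[["chrom"]]),
                        lo = as.numeric(regions[["start"]]) - flank,
                        hi = as.numeric(regions[["end"]]) + flank)
  dplyr::inner_join(
    gwas, reg,
    by = dplyr::join_by("chrom", dplyr::between(x$pos, y$lo, y$hi)),
    relationship = "many-to-many"
  ) |>
    dplyr::select("gene", "snp", "chrom", "pos", "pvalue") |>
    dplyr::arrange(.data$gene, .data$pos)
}

#' Validate top-ranked genes against GWAS summary statistics
#'
#' External validation of a prioritization: SNPs are mapped to the top
#' `top_n` ranked genes, their p-values are pooled and Benjamini-Hochberg
#' adjusted across the pool, and each gene is tested for carrying a
#' significant proportion of passing SNPs via a one-sample t-test of its
#' SNP pass/fail indicators against 0. Genes with test p < 0.05 are called
#' validated. Degenerate indicator vectors make the t-test undefined and
#' are resolved deterministically: all-zero indicators (mean 0) are never
#' validated; constant all-one indicators, and single-SNP genes, are
#' validated iff the (sole) indicator is 1. Genes with no mapped SNP are
#' excluded from the gene denominator.
#'
#' @param ranks A rank table from [rank_scores()] (columns `gene`,
#'   `rank`).
#' @param gwas SNP table, see [map_snps_to_genes()].
#' @param regions Gene-region table, see [map_snps_to_genes()].
#' @param top_n Number of top-ranked genes to validate (default 200).
#' @param fdr BH-adjusted significance threshold for SNPs (default 0.05).
#' @param flank SNP-to-gene mapping flank in bp.
#' @return An object of class `gwas_validation`: list with `snp_table`
#'   (per SNP-gene assignment: `pvalue`, `p_adj`, `significant`),
#'   `gene_table` (`gene`, `rank`, `n_snps`, `n_sig`, `t_p`, `validated`),
#'   `n_sig_snps`, `n_snps`, `n_validated`, `n_genes_tested`, `top_n`,
#'   `fdr`, `adjust_method`.
#' @export
gwas_validate <- function(ranks, gwas, regions, top_n = 200L, fdr = 0.05,
                          flank = 1000L) {
  stopifnot(all(c("gene", "rank") %in% names(ranks)))
  ranks <- dplyr::arrange(tibble::as_tibble(ranks), .data$rank)
  if (top_n > nrow(ranks)) {
    stop("top_n exceeds the number of ranked genes", call. = FALSE)
  }
  top <- utils::head(ranks, top_n)
  mapped <- map_snps_to_genes(gwas, regions, flank = flank) |>
    dplyr::filter(.data$gene %in% top$gene)
  # BH across the pooled unique SNPs of the top genes
  pool <- mapped |> dplyr::distinct(.data$snp, .data$pvalue)
  pool$p_adj <- stats::p.adjust(pool$pvalue, method = "BH")
  snp_table <- mapped |>
    dplyr::left_join(dplyr::select(pool, "snp", "p_adj"), by = "snp") |>
    dplyr::mutate(significant = .data$p_adj < fdr)
  gene_table <- snp_table |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(n_snps = dplyr::n(),
                     n_sig = sum(.data$significant),
                     t_p = indicator_t_p(as.numeric(.data$significant)),
                     .groups = "drop") |>
    dplyr::mutate(validated = !is.na(.data$t_p) & .data$t_p < 0.05) |>
    dplyr::left_join(dplyr::select(top, "gene", "rank"), by = "gene") |>
    dplyr::arrange(.data$rank)
  structure(
    list(snp_table = snp_table, gene_table = gene_table,
         n_sig_snps = sum(snp_table$significant),
         n_snps = nrow(snp_table),
         n_validated = sum(gene_table$validated),
         n_genes_tested = nrow(gene_table),
         top_n = as.integer(top_n), fdr = fdr, adjust_method = "BH"),
    class = "gwas_validation"
  )
}

# One-sample t-test p-value of an indicator vector against 0, with the
# documented deterministic fallbacks where the test is degenerate:
# zero variance or a single observation -> p = 0 if the mean is 1
# (validated), p = 1 if the mean is 0 (not validated).
indicator_t_p <- function(ind) {
  if (length(ind) < 2 || stats::sd(ind) == 0) {
    return(if (mean(ind) > 0) 0 else 1)
  }
  stats::t.test(ind, mu = 0)$p.value
}

#' @export
print.gwas_validation <- function(x, ...) {
  cat(sprintf("<gwas_validation> SNPs %d/%d significant; genes %d/%d validated (top %d, BH fdr %g)\n",
              x$n_sig_snps, x$n_snps, x$n_validated, x$n_genes_tested,
              x$top_n, x$fdr))
  invisible(x)
}

#' Rank metrics for externally confirmed genes
#'
#' Given a full rank table and a list of externally confirmed genes (e.g.
#' genome-wide significant loci from an independent GWAS), reports the
#' confirmed genes' median rank and how many fall within the top fraction
#' of all predictions (hits), with the hit list in rank order. Confirmed
#' genes absent from the ranked universe are excluded and reported.
#'
#' @param ranks A rank table (columns `gene`, `rank`).
#' @param confirmed Character vector of confirmed gene ids.
#' @param top_frac Fraction of the ranked list counted as a hit
#'   (default 0.1).
#' @return A list of class `confirmed_metrics`: `median_rank`, `n_hits`,
#'   `n_confirmed`, `hits` (tibble `gene`, `rank`), `missing` (ids not in
#'   the ranking), `top_frac`, `cutoff_rank`.
#' @export
confirmed_gene_metrics <- function(ranks, confirmed, top_frac = 0.1) {
  stopifnot(all(c("gene", "rank") %in% names(ranks)))
  confirmed <- unique(as.character(confirmed))
  if (length(confirmed) == 0) stop("no confirmed genes given", call. = FALSE)
  present <- dplyr::filter(tibble::as_tibble(ranks), .data$gene %in% confirmed)
  missing <- setdiff(confirmed, present$gene)
  if (length(missing) > 0) {
    message(sprintf("confirmed_gene_metrics: %d confirmed gene(s) not in the ranking: %s",
                    length(missing), paste(missing, collapse = ", ")))
  }
  cutoff <- top_frac * nrow(ranks)
  hits <- present |>
    dplyr::filter(.data$rank <= cutoff) |>
    dplyr::arrange(.data$rank)
  structure(
    list(median_rank = stats::median(present$rank),
         n_hits = nrow(hits),
         n_confirmed = length(confirmed),
         hits = dplyr::select(hits, "gene", "rank"),
         missing = missing,
         top_frac = top_frac,
         cutoff_rank = cutoff),
    class = "confirmed_metrics"
  )
}

#' @export
print.confirmed_metrics <- function(x, ...) {
  cat(sprintf("<confirmed_metrics> median rank %s, hits %d/%d within top %g%%: %s\n",
              format(x$median_rank), x$n_hits, x$n_confirmed,
              100 * x$top_frac,
              if (x$n_hits > 0) paste(x$hits$gene, collapse = ", ") else "-"))
  invisible(x)
}
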