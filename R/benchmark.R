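#' Run the full benchmarking suite from a config
#'
#' One call covering the three-part workflow: run a set of prioritizers on
#' a (heterogeneous) network, benchmark them by leave-one-out
#' cross-validation, and optionally validate their top predictions against
#' GWAS summary statistics. Produces a wide LOOCV matrix (one row per seed
#' plus median/mean rows, one column per algorithm, `na` preserved for
#' folds without a rank) and a per-algorithm GWAS summary table.
#'
#' @param config A named list or the path to a YAML file with keys:
#'   \describe{
#'     \item{network}{edge-list TSV path (or pass `net`).}
#'     \item{score_threshold}{optional edge-score cut-off.}
#'     \item{gda, dsim}{association / similarity TSV paths (or pass
#'       `hnet`); required by `rwrh`, `n2vh`, `idlp`.}
#'     \item{seeds}{seed-list path or character vector.}
#'     \item{disease}{query-disease id for heterogeneous algorithms.}
#'     \item{algorithms}{character vector of [prioritizer_keys()].}
#'     \item{restart, idlp, walks}{optional parameter sub-lists forwarded
#'       to [rwr_params()], [idlp_params()], [walk_params()].}
#'     \item{gwas, regions}{GWAS table / gene-region TSV paths enabling
#'       external validation.}
#'     \item{confirmed}{externally confirmed gene ids for
#'       [confirmed_gene_metrics()].}
#'     \item{top_n, fdr, top_frac}{validation settings (defaults 200,
#'       0.05, 0.1).}
#'     \item{out_dir}{optional directory for TSV reports + JSON manifest.}
#'   }
#' @param net,hnet Optional pre-built network objects overriding the
#'   file-based keys.
#' @return An object of class `benchmark_report`: list with
#'   `loocv_matrix` (wide tibble), `loocv` (named list of
#'   [loocv()] results), `gwas_summary` (tibble, possibly empty),
#'   `gwas` (named list of validations), `manifest`.
#' @export
run_benchmark_suite <- function(config, net = NULL, hnet = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  algorithms <- config$algorithms %||% "rwr"
  bad <- setdiff(algorithms, prioritizer_keys())
  if (length(bad) > 0) {
    stop(sprintf("unknown algorithm key(s): %s; valid keys: %s",
                 paste(bad, collapse = ", "),
                 paste(prioritizer_keys(), collapse = ", ")), call. = FALSE)
  }
  needs_hetero <- any(algorithms %in% hetero_keys())
  if (needs_hetero && is.null(hnet) && is.null(config$gda)) {
    stop("heterogeneous algorithm requested but no `gda` layer (or hnet) given",
         call. = FALSE)
  }
  if (is.null(net)) {
    if (is.null(config$network)) stop("config must name a network", call. = FALSE)
    net <- read_edge_list(config$network,
                          score_threshold = config$score_threshold,
                          quiet = TRUE)
  }
  if (needs_hetero && is.null(hnet)) {
    gda <- read_association_list(config$gda)
    dsim <- if (!is.null(config$dsim)) read_association_list(config$dsim) else NULL
    hnet <- hetero_network(net, gda, dsim)
  }
  seeds <- config$seeds
  if (is.character(seeds) && length(seeds) == 1 && file.exists(seeds)) {
    seeds <- read_seed_list(seeds)
  }
  seeds <- check_seeds(net, seeds)
  param_for <- function(alg) {
    switch(alg,
      rwr = , rwrh = do.call(rwr_params, config$restart %||% list()),
      idlp = do.call(idlp_params, config$idlp %||% list()),
      n2v = , n2vh = do.call(walk_params, config$walks %||% list()),
      NULL)
  }

  loocv_results <- lapply(stats::setNames(algorithms, algorithms), function(alg) {
    use_net <- if (alg %in% hetero_keys()) hnet else net
    loocv(use_net, seeds, alg, disease = config$disease,
          params = param_for(alg))
  })
  fold_cols <- lapply(loocv_results, function(r) r$folds$rank)
  loocv_matrix <- dplyr::bind_cols(
    tibble::tibble(seed = loocv_results[[1]]$folds$seed),
    tibble::as_tibble(fold_cols)
  )
  summary_rows <- dplyr::bind_rows(
    c(list(seed = "median"), lapply(loocv_results, function(r) r$median)),
    c(list(seed = "mean"), lapply(loocv_results, function(r) r$mean))
  )
  loocv_matrix <- dplyr::bind_rows(loocv_matrix, summary_rows)

  gwas_results <- list()
  gwas_summary <- tibble::tibble()
  if (!is.null(config$gwas) && !is.null(config$regions)) {
    gwas <- readr::read_tsv(config$gwas, col_types = "ccdd", progress = FALSE)
    regions <- read_gene_regions(config$regions)
    top_n <- config$top_n %||% 200L
    fdr <- config$fdr %||% 0.05
    gwas_results <- lapply(stats::setNames(algorithms, algorithms), function(alg) {
      use_net <- if (alg %in% hetero_keys()) hnet else net
      scores <- run_prioritizer(alg, use_net, seeds,
                                disease = config$disease,
                                params = param_for(alg))
      ranks <- rank_scores(scores, exclude = seeds, na_rm = TRUE)
      val <- gwas_validate(ranks, gwas, regions,
                           top_n = min(top_n, nrow(ranks)), fdr = fdr)
      conf <- if (!is.null(config$confirmed)) {
        confirmed_gene_metrics(ranks, config$confirmed,
                               top_frac = config$top_frac %||% 0.1)
      }
      list(validation = val, confirmed = conf)
    })
    gwas_summary <- dplyr::bind_rows(lapply(names(gwas_results), function(alg) {
      v <- gwas_results[[alg]]$validation
      cm <- gwas_results[[alg]]$confirmed
      tibble::tibble(
        algorithm = alg,
        snp_sig = v$n_sig_snps, snp_total = v$n_snps,
        gene_sig = v$n_validated, gene_total = v$n_genes_tested,
        confirmed_median_rank = if (!is.null(cm)) cm$median_rank else NA_real_,
        hits = if (!is.null(cm)) cm$n_hits else NA_integer_,
        hits_list = if (!is.null(cm)) paste(cm$hits$gene, collapse = ",") else ""
      )
    }))
  }

  manifest <- list(
    command = "run_benchmark_suite",
    algorithms = algorithms,
    n_nodes = net$n_nodes, n_edges = net$n_edges,
    n_seeds = length(seeds),
    disease = config$disease,
    parameters = config[intersect(names(config),
                                  c("restart", "idlp", "walks", "top_n",
                                    "fdr", "top_frac", "score_threshold"))],
    input_digests = input_digests(config),
    version = as.character(utils::packageVersion("netprio")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  report <- structure(
    list(loocv_matrix = loocv_matrix, loocv = loocv_results,
         gwas_summary = gwas_summary, gwas = gwas_results,
         manifest = manifest),
    class = "benchmark_report"
  )
  if (!is.null(config$out_dir)) write_benchmark_report(report, config$out_dir)
  report
}

input_digests <- function(config) {
  paths <- unlist(config[intersect(names(config),
                                   c("network", "gda", "dsim", "gwas",
                                     "regions"))])
  paths <- paths[vapply(paths, function(p) is.character(p) && file.exists(p),
                        logical(1))]
  if (length(paths) == 0) return(list())
  as.list(tools::md5sum(paths))
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat("<benchmark_report>\nLOOCV ranks:\n")
  print(x$loocv_matrix, n = Inf)
  if (nrow(x$gwas_summary) > 0) {
    cat("\nGWAS validation:\n")
    print(x$gwas_summary)
  }
  invisible(x)
}

#' Write a benchmark report bundle to disk
#'
#' Emits `loocv_ranks.tsv` (wide matrix, `na` preserved),
#' `gwas_summary.tsv` when present, and `manifest.json`.
#'
#' @param report A `benchmark_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_benchmark_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(report$loocv_matrix, file.path(dir, "loocv_ranks.tsv"),
                   na = "na")
  if (nrow(report$gwas_summary) > 0) {
    readr::write_tsv(report$gwas_summary, file.path(dir, "gwas_summary.tsv"))
  }
  jsonlite::write_json(report$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Write a gene ranking as TSV
#'
#' Standard rank output dialect: columns `gene  score  rank`, best rank
#' first.
#'
#' @param ranks A rank table from [rank_scores()].
#' @param path Output path.
#' @export
write_rank_table <- function(ranks, path) {
  readr::write_tsv(dplyr::arrange(ranks, .data$rank), path)
  invisible(path)
}
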