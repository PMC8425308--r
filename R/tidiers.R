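#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy methods for netprio result objects
#'
#' `tidy()` returns the per-unit table of a result (folds, selections,
#' per-node medians, per-gene validation calls); `glance()` returns its
#' one-row summary.
#'
#' @param x A result object.
#' @param ... Unused.
#' @return A tibble.
#' @name netprio-tidiers
NULL

#' @rdname netprio-tidiers
#' @export
tidy.loocv_result <- function(x, ...) {
  dplyr::mutate(x$folds, algorithm = x$algorithm)
}

#' @rdname netprio-tidiers
#' @export
glance.loocv_result <- function(x, ...) {
  tibble::tibble(algorithm = x$algorithm, n_folds = nrow(x$folds),
                 n_na = x$n_na, median = x$median, mean = x$mean,
                 median_worst = x$median_worst,
                 n_candidates = x$n_candidates)
}

#' @rdname netprio-tidiers
#' @export
tidy.random_seed_result <- function(x, ...) x$medians

#' @rdname netprio-tidiers
#' @export
glance.random_seed_result <- function(x, ...) {
  tibble::tibble(algorithm = x$algorithm, n_trials = x$n_trials,
                 seeds_per_trial = x$seeds_per_trial, n_failed = x$n_failed,
                 grand_median = stats::median(x$medians$median_rank,
                                              na.rm = TRUE))
}

#' @rdname netprio-tidiers
#' @export
tidy.diamond_result <- function(x, ...) x$selection

#' @rdname netprio-tidiers
#' @export
glance.diamond_result <- function(x, ...) {
  tibble::tibble(n_selected = nrow(x$selection), n_seeds = length(x$seeds),
                 alpha = x$alpha, n_ties = x$n_ties)
}

#' @rdname netprio-tidiers
#' @export
tidy.gwas_validation <- function(x, ...) x$gene_table

#' @rdname netprio-tidiers
#' @export
glance.gwas_validation <- function(x, ...) {
  tibble::tibble(n_sig_snps = x$n_sig_snps, n_snps = x$n_snps,
                 n_validated = x$n_validated,
                 n_genes_tested = x$n_genes_tested,
                 top_n = x$top_n, fdr = x$fdr)
}

#' @rdname netprio-tidiers
#' @export
tidy.confirmed_metrics <- function(x, ...) x$hits

#' @rdname netprio-tidiers
#' @export
glance.confirmed_metrics <- function(x, ...) {
  tibble::tibble(median_rank = x$median_rank, n_hits = x$n_hits,
                 n_confirmed = x$n_confirmed, top_frac = x$top_frac)
}

#' @rdname netprio-tidiers
#' @export
tidy.degree_bias <- function(x, ...) x$deciles

#' @rdname netprio-tidiers
#' @export
glance.degree_bias <- function(x, ...) {
  tibble::tibble(algorithm = x$algorithm, spearman = x$spearman,
                 p_value = x$p_value)
}

#' @rdname netprio-tidiers
#' @export
tidy.modularity_result <- function(x, ...) {
  tibble::tibble(gene = names(x$membership),
                 membership = unname(x$membership))
}

#' @rdname netprio-tidiers
#' @export
glance.modularity_result <- function(x, ...) {
  tibble::tibble(Q = x$Q, n_pathway = sum(x$membership == -1),
                 diagonal = x$diagonal)
}

#' Plot methods for netprio result objects
#'
#' Quick diagnostic ggplots: LOOCV fold ranks per seed, median
#' random-seed rank vs degree (log-log), degree-decile bias profile, and
#' the rank distribution of tracked genes.
#'
#' @param object A result object.
#' @param ... Unused.
#' @return A ggplot.
#' @name netprio-autoplot
NULL

#' @rdname netprio-autoplot
#' @export
autoplot.loocv_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$seed, .data$rank),
                                   y = .data$rank)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = object$median, linetype = 2) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = "left-out seed", y = "LOOCV rank",
                  title = sprintf("%s: median LOOCV rank %s",
                                  object$algorithm, format(object$median)))
}

#' @rdname netprio-autoplot
#' @export
autoplot.random_seed_result <- function(object, ...) {
  ggplot2::ggplot(object$medians,
                  ggplot2::aes(x = .data$degree, y = .data$median_rank)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "degree", y = "median random-seed rank",
                  title = sprintf("%s: seed-independent rank vs degree",
                                  object$algorithm))
}

#' @rdname netprio-autoplot
#' @export
autoplot.degree_bias <- function(object, ...) {
  ggplot2::ggplot(object$deciles,
                  ggplot2::aes(x = .data$decile, y = .data$median_rank)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = 1:10) +
    ggplot2::labs(x = "degree decile (1 = lowest degree)",
                  y = "median random-seed rank",
                  title = sprintf("%s: Spearman rho = %.3f",
                                  object$algorithm, object$spearman))
}

#' @rdname netprio-autoplot
#' @export
autoplot.gwas_validation <- function(object, ...) {
  ggplot2::ggplot(object$gene_table,
                  ggplot2::aes(x = .data$rank, y = .data$n_sig / .data$n_snps,
                               colour = .data$validated)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "prioritization rank", y = "fraction of significant SNPs",
                  colour = "validated")
}
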