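#' Build a gene network from an edge table
#'
#' Constructs a simple undirected network over opaque string node ids from a
#' two- or three-column edge table. Self-loops are dropped and duplicate or
#' reversed edges are collapsed, so the result is always a simple graph. When
#' a `score` column is present, edges below `score_threshold` are removed
#' before the graph is built -- the generic confidence cut-off used to turn
#' scored interaction tables (e.g. STRING-style combined scores) into binary
#' networks.
#'
#' @param edges A data frame whose first two columns are node ids
#'   (`source`, `target`) and whose optional third column is a numeric edge
#'   score.
#' @param score_threshold Optional numeric; edges with `score <
#'   score_threshold` are dropped. Requires a score column.
#' @param quiet Suppress the node/edge count message.
#'
#' @return An object of class `gene_network`: a list with elements `nodes`
#'   (character vector in index order), `adjacency` (sparse symmetric 0/1
#'   [Matrix::dgCMatrix-class] with zero diagonal), `degree` (named integer
#'   vector of row sums), `graph` (the equivalent [igraph::igraph] object),
#'   `n_nodes` and `n_edges`.
#' @seealso [read_edge_list()] to load the TSV dialect directly.
#' @export
#' @examples
#' edges <- tibble::tibble(source = c("a", "b"), target = c("b", "c"),
#'                         score = c(400, 300))
#' net <- network_from_edges(edges, score_threshold = 350)
#' net$n_edges  # 1
network_from_edges <- function(edges, score_threshold = NULL, quiet = FALSE) {
  stopifnot(is.data.frame(edges), ncol(edges) >= 2)
  ed <- tibble::tibble(
    source = as.character(edges[[1]]),
    target = as.character(edges[[2]])
  )
  if (ncol(edges) >= 3) ed$score <- as.numeric(edges[[3]])
  if (!is.null(score_threshold)) {
    if (is.null(ed$score)) {
      stop("`score_threshold` given but the edge table has no score column", call. = FALSE)
    }
    ed <- dplyr::filter(ed, .data$score >= score_threshold)
  }
  # canonical orientation so (a,b) and (b,a) collapse; drop self-loops
  ed <- ed |>
    dplyr::filter(.data$source != .data$target) |>
    dplyr::mutate(
      lo = pmin(.data$source, .data$target),
      hi = pmax(.data$source, .data$target)
    ) |>
    dplyr::distinct(.data$lo, .data$hi)
  nodes <- sort(unique(c(as.character(edges[[1]]), as.character(edges[[2]]))))
  if (length(nodes) == 0 || nrow(ed) == 0) {
    stop("no edges remain after filtering; refusing to build an empty network",
         call. = FALSE)
  }
  idx <- stats::setNames(seq_along(nodes), nodes)
  i <- idx[ed$lo]
  j <- idx[ed$hi]
  n <- length(nodes)
  A <- Matrix::sparseMatrix(
    i = c(i, j), j = c(j, i), x = 1,
    dims = c(n, n), dimnames = list(nodes, nodes)
  )
  A <- methods::as(A, "CsparseMatrix")
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  net <- structure(
    list(
      nodes = nodes,
      adjacency = A,
      degree = stats::setNames(as.integer(Matrix::rowSums(A)), nodes),
      graph = g,
      n_nodes = n,
      n_edges = nrow(ed)
    ),
    class = "gene_network"
  )
  if (!quiet) {
    message(sprintf("network: %d nodes, %d edges", net$n_nodes, net$n_edges))
  }
  net
}

#' Read a tab-separated edge list
#'
#' Reads a TSV with columns `source  target  [score]` (lines starting with
#' `#` ignored) and builds a [network_from_edges()] network, optionally
#' applying a score threshold.
#'
#' @param path Path to the TSV file.
#' @inheritParams network_from_edges
#' @return A `gene_network`.
#' @export
read_edge_list <- function(path, score_threshold = NULL, quiet = FALSE) {
  ed <- tryCatch(
    readr::read_tsv(path, comment = "#", col_names = FALSE,
                    col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE),
    error = function(e) stop(sprintf("failed to parse '%s': %s", path,
                                     conditionMessage(e)), call. = FALSE)
  )
  if (ncol(ed) < 2) {
    stop(sprintf("edge list '%s' must have at least 2 columns", path),
         call. = FALSE)
  }
  bad <- which(is.na(ed[[1]]) | is.na(ed[[2]]))
  if (length(bad) > 0) {
    stop(sprintf("malformed edge list '%s': missing node id at line %d",
                 path, bad[1]), call. = FALSE)
  }
  if (ncol(ed) >= 3) {
    sc <- suppressWarnings(as.numeric(ed[[3]]))
    bad <- which(!is.na(ed[[3]]) & is.na(sc))
    if (length(bad) > 0) {
      stop(sprintf("malformed score in '%s' at line %d", path, bad[1]),
           call. = FALSE)
    }
    ed[[3]] <- sc
  }
  network_from_edges(ed, score_threshold = score_threshold, quiet = quiet)
}

#' Read a seed-gene list
#'
#' One node id per line; blank lines and `#` comments ignored.
#'
#' @param path Path to the file.
#' @return Character vector of seed ids.
#' @export
read_seed_list <- function(path) {
  x <- readr::read_lines(path)
  x <- trimws(x)
  x <- x[nzchar(x) & !startsWith(x, "#")]
  unique(x)
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("<gene_network> %d nodes, %d edges\n", x$n_nodes, x$n_edges))
  invisible(x)
}

is_gene_network <- function(x) inherits(x, "gene_network")

#' Validate a seed set against a network
#'
#' @param net A `gene_network`.
#' @param seeds Character vector of node ids.
#' @return The deduplicated seed vector, invisibly erroring if any id is
#'   absent from the network or the set is empty.
#' @keywords internal
check_seeds <- function(net, seeds) {
  seeds <- unique(as.character(seeds))
  if (length(seeds) == 0) stop("seed set is empty", call. = FALSE)
  missing <- setdiff(seeds, net$nodes)
  if (length(missing) > 0) {
    stop(sprintf("seed id(s) not in network: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  seeds
}

#' Column-normalize a network adjacency matrix
#'
#' Returns the column-stochastic transition matrix W = A D^-1 used by the
#' random-walk propagation methods: each nonzero-degree column is divided by
#' its degree so it sums to 1. Zero-degree columns are left all-zero (the
#' walk treats such dangling nodes as restart-only) and their count is
#' reported.
#'
#' @param net A `gene_network`, or a square (sparse) adjacency matrix.
#' @param quiet Suppress the dangling-column message.
#' @return A sparse column-stochastic matrix with the same dimnames.
#' @export
column_normalize <- function(net, quiet = TRUE) {
  A <- if (is_gene_network(net)) net$adjacency else methods::as(net, "CsparseMatrix")
  k <- Matrix::colSums(A)
  inv <- ifelse(k > 0, 1 / k, 0)
  dangling <- sum(k == 0)
  if (dangling > 0 && !quiet) {
    message(sprintf("column_normalize: %d zero-degree column(s) left all-zero",
                    dangling))
  }
  W <- A %*% Matrix::Diagonal(x = inv)
  dimnames(W) <- dimnames(A)
  W
}

#' Symmetrically normalize an adjacency matrix
#'
#' Computes K^{-1/2} A K^{-1/2}, i.e. entry (i,j) becomes
#' A_ij / sqrt(k_i k_j), where k is the degree (row sum). This is the
#' normalization used by dual label propagation for both the gene network
#' and the disease-similarity layer. Zero-degree rows/columns stay zero.
#'
#' @param adjacency Square symmetric nonnegative matrix (dense or sparse).
#' @return Normalized matrix of the same class family, still symmetric.
#' @export
symmetric_normalize <- function(adjacency) {
  A <- methods::as(adjacency, "CsparseMatrix")
  if (nrow(A) != ncol(A) || !Matrix::isSymmetric(A, tol = 0)) {
    stop("symmetric_normalize() requires a symmetric square matrix", call. = FALSE)
  }
  k <- Matrix::rowSums(A)
  inv_sqrt <- ifelse(k > 0, 1 / sqrt(k), 0)
  D <- Matrix::Diagonal(x = inv_sqrt)
  S <- D %*% A %*% D
  dimnames(S) <- dimnames(A)
  S
}

largest_component_ids <- function(net) {
  comp <- igraph::components(net$graph)
  net$nodes[comp$membership == which.max(comp$csize)]
}

#' Centrality profile of selected nodes
#'
#' Degree, eigenvector, betweenness and closeness centralities plus the
#' local clustering coefficient for a set of nodes, with selection- and
#' graph-wide median/mean summary rows. Degree centrality is normalized by
#' (n - 1); betweenness and closeness are normalized; closeness and
#' betweenness are computed on the largest connected component. Nodes with
#' degree < 2 get clustering coefficient 0.
#'
#' @param net A `gene_network`.
#' @param ids Character vector of node ids to profile.
#' @return A tibble with one row per id plus `selection median`,
#'   `selection mean`, `graph median` and `graph mean` rows, columns
#'   `vertex`, `degree`, `eigenvector`, `betweenness`, `closeness`,
#'   `clustering`.
#' @export
centrality_profile <- function(net, ids) {
  ids <- unique(as.character(ids))
  missing <- setdiff(ids, net$nodes)
  if (length(missing) > 0) {
    stop(sprintf("id(s) not in network: %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  g <- net$graph
  n <- net$n_nodes
  lcc <- largest_component_ids(net)
  g_lcc <- igraph::induced_subgraph(g, lcc)

  deg <- net$degree / (n - 1)
  eig <- igraph::eigen_centrality(g)$vector
  btw <- stats::setNames(rep(NA_real_, n), net$nodes)
  btw[lcc] <- igraph::betweenness(g_lcc, normalized = TRUE)
  clo <- stats::setNames(rep(NA_real_, n), net$nodes)
  clo[lcc] <- igraph::closeness(g_lcc, normalized = TRUE)
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  cc <- stats::setNames(ifelse(is.nan(cc), 0, cc), net$nodes)

  tab <- tibble::tibble(
    vertex = net$nodes,
    degree = unname(deg),
    eigenvector = unname(eig[net$nodes]),
    betweenness = unname(btw[net$nodes]),
    closeness = unname(clo[net$nodes]),
    clustering = unname(cc[net$nodes])
  )
  sel <- dplyr::filter(tab, .data$vertex %in% ids)
  sel <- sel[match(ids, sel$vertex), ]
  summarize_rows <- function(df, label, fn) {
    df |>
      dplyr::summarise(dplyr::across(-"vertex", \(x) fn(x, na.rm = TRUE))) |>
      dplyr::mutate(vertex = label, .before = 1)
  }
  dplyr::bind_rows(
    sel,
    summarize_rows(sel, "selection median", stats::median),
    summarize_rows(sel, "selection mean", mean),
    summarize_rows(tab, "graph median", stats::median),
    summarize_rows(tab, "graph mean", mean)
  )
}

#' Pairwise distances or walk affinities between seed nodes
#'
#' For `metric = "shortest_path"`, the unweighted geodesic length between
#' every pair of seeds (Inf across components). For `metric = "rwr"`, entry
#' (i, j) is the converged random-walk-with-restart probability at j when
#' the walk starts from the single seed {i} -- an affinity, not a metric:
#' the matrix is not symmetric in general (row i is the walk started at i)
#' and is returned un-symmetrized.
#'
#' @param net A `gene_network`.
#' @param seeds Character vector of seed ids.
#' @param metric `"shortest_path"` or `"rwr"`.
#' @param r Restart probability, required for the rwr metric.
#' @return A |S| x |S| matrix with seed ids as dimnames.
#' @export
pairwise_seed_distance <- function(net, seeds,
                                   metric = c("shortest_path", "rwr"),
                                   r = NULL) {
  metric <- match.arg(metric)
  seeds <- check_seeds(net, seeds)
  if (metric == "shortest_path") {
    d <- igraph::distances(net$graph, v = seeds, to = seeds)
    return(d[seeds, seeds, drop = FALSE])
  }
  if (is.null(r)) stop("rwr metric requires `r`", call. = FALSE)
  out <- matrix(NA_real_, length(seeds), length(seeds),
                dimnames = list(seeds, seeds))
  for (s in seeds) {
    p <- rwr(net, s, params = rwr_params(restart = r))
    out[s, ] <- p$score[match(seeds, p$gene)]
  }
  out
}

#' Two-community modularity of a node subset
#'
#' Scores how much denser a pathway (node subset) is than expected under
#' the configuration null, by treating the pathway and the rest of the
#' network as two communities: Q = s^T B s / (4m) with membership s_i = -1
#' inside the pathway and +1 outside, and modularity matrix
#' B_ij = A_ij - k_i k_j / (2m). By default the diagonal of B is set to
#' zero (`diagonal = "zero"`); `diagonal = "standard"` keeps the usual
#' Newman diagonal B_ii = -k_i^2/(2m). The two differ by a constant
#' sum(k^2)/(8 m^2) in Q, so contrasts between pathways are unaffected.
#'
#' @param net A `gene_network`.
#' @param pathway Character vector of node ids (may be empty).
#' @param diagonal `"zero"` or `"standard"`.
#' @return A list of class `modularity_result`: `Q`, `membership` (named
#'   -1/+1 vector), `modularity_matrix` (dense B), `diagonal`.
#' @export
two_community_modularity <- function(net, pathway,
                                     diagonal = c("zero", "standard")) {
  diagonal <- match.arg(diagonal)
  pathway <- unique(as.character(pathway))
  missing <- setdiff(pathway, net$nodes)
  if (length(missing) > 0) {
    stop(sprintf("pathway id(s) not in network: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  m <- net$n_edges
  if (m == 0) stop("modularity undefined on an edgeless network", call. = FALSE)
  k <- as.numeric(net$degree)
  B <- as.matrix(net$adjacency) - outer(k, k) / (2 * m)
  if (diagonal == "zero") diag(B) <- 0
  s <- ifelse(net$nodes %in% pathway, -1, 1)
  Q <- as.numeric(t(s) %*% B %*% s) / (4 * m)
  structure(
    list(Q = Q,
         membership = stats::setNames(s, net$nodes),
         modularity_matrix = B,
         diagonal = diagonal),
    class = "modularity_result"
  )
}

#' @export
print.modularity_result <- function(x, ...) {
  cat(sprintf("<modularity_result> Q = %.6f (%d in pathway, diagonal = %s)\n",
              x$Q, sum(x$membership == -1), x$diagonal))
  invisible(x)
}

#' Rank a score table
#'
#' Turns per-gene scores into tie-aware ranks: scores are sorted descending
#' (higher is better) and tied scores receive the average of the positions
#' they span, so e.g. two genes tied at the bottom of a 15 010-gene list
#' both get rank 7505.5. Optionally removes ids (typically the remaining
#' seed genes during cross-validation) before ranking.
#'
#' @param scores Data frame with columns `gene` and `score`.
#' @param exclude Optional character vector of gene ids dropped before
#'   ranking.
#' @param na_rm Drop genes with missing scores before ranking (they stay
#'   unranked); the default is to error on missing scores.
#' @return A tibble `gene`, `score`, `rank` sorted by rank (best first).
#' @export
#' @examples
#' rank_scores(tibble::tibble(gene = letters[1:4],
#'                            score = c(0.5, 0.3, 0.3, 0.1)))
rank_scores <- function(scores, exclude = NULL, na_rm = FALSE) {
  stopifnot(is.data.frame(scores), all(c("gene", "score") %in% names(scores)))
  out <- tibble::as_tibble(scores[c("gene", "score")])
  if (!is.null(exclude)) out <- dplyr::filter(out, !(.data$gene %in% exclude))
  if (na_rm) out <- dplyr::filter(out, !is.na(.data$score))
  if (anyNA(out$score) || any(!is.finite(out$score))) {
    stop("rank_scores(): scores must be finite and non-missing", call. = FALSE)
  }
  out |>
    dplyr::mutate(rank = rank(-.data$score, ties.method = "average")) |>
    dplyr::arrange(.data$rank)
}

#' Degree-centrality baseline prioritizer
#'
#' Scores every gene by its degree, independent of any seed set. Used as
#' the naive baseline a real prioritizer must beat.
#'
#' @param net A `gene_network`.
#' @param seeds Ignored; accepted so the baseline is call-compatible with
#'   the seed-based prioritizers.
#' @return A tibble `gene`, `score`.
#' @export
degree_baseline <- function(net, seeds = NULL) {
  tibble::tibble(gene = net$nodes, score = as.numeric(net$degree))
}
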