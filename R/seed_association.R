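#' Hypergeometric connectivity significance
#'
#' The probability that a candidate node of degree `k` connects to exactly
#' `k_st` of the `n_seeds` current seed nodes in a network of `n` nodes,
#' under the hypergeometric null that its `k` link endpoints are drawn
#' without replacement from the node set:
#'
#' \deqn{p = \frac{\binom{|S_t|}{k_{st}} \binom{n-|S_t|}{k-k_{st}}}{\binom{n}{k}}}
#'
#' With seed weight `alpha > 1` the original seeds count alpha-fold:
#' |S_t| and k_st are inflated by (alpha - 1)|S| and (alpha - 1)k_s, and n
#' and k by the same amounts in the denominator. `tail = TRUE` returns the
#' upper-tail sum over k_st' >= k_st (the original DIAMOnD statistic)
#' instead of the point mass.
#'
#' @param k Candidate degree.
#' @param k_st Links from the candidate to the current seed set.
#' @param n_seeds Current seed-set size |S_t|.
#' @param n Network size.
#' @param alpha Seed weight >= 1 (default 1).
#' @param k_s Links to the *original* seed set (needed when alpha > 1).
#' @param n_orig_seeds Original seed-set size |S| (needed when alpha > 1).
#' @param tail Return the cumulative upper tail instead of the point mass.
#' @return Probability in \[0, 1\].
#' @export
#' @examples
#' connectivity_p(k = 2, k_st = 1, n_seeds = 3, n = 10)  # 7/15
connectivity_p <- function(k, k_st, n_seeds, n, alpha = 1, k_s = k_st,
                           n_orig_seeds = n_seeds, tail = FALSE) {
  stopifnot(alpha >= 1, k >= 0, k_st >= 0, k_st <= k, k_st <= n_seeds,
            n_seeds <= n)
  w <- alpha - 1
  point <- function(kst) {
    S_eff <- n_seeds + w * n_orig_seeds
    kst_eff <- kst + w * k_s
    num <- lchoose(S_eff, kst_eff) + lchoose(n - n_seeds, k - kst)
    den <- lchoose(n + w * n_orig_seeds, k + w * k_s)
    if (!is.finite(num) || !is.finite(den)) return(0)
    exp(num - den)
  }
  if (k - k_st > n - n_seeds) {
    stop("impossible arguments: k - k_st exceeds the non-seed pool", call. = FALSE)
  }
  if (!tail) return(point(k_st))
  sum(vapply(k_st:min(k, n_seeds), point, numeric(1)))
}

#' DIAMOnD disease-module growth
#'
#' Grows a disease module outward from the seed genes: at every step the
#' hypergeometric connectivity significance ([connectivity_p()]) is
#' computed for each non-seed node adjacent to the current seed set, the
#' node with the lowest p-value is added to the set, and its step number
#' becomes its rank. Ties in p are broken by higher connectivity to the
#' seed set, then lexicographically by node id (logged via attribute).
#' Growth stops at `max_steps` or when no candidate touches the module;
#' genes never selected have no DIAMOnD rank (reported as NA).
#'
#' @param net A `gene_network`.
#' @param seeds Character vector of seed gene ids.
#' @param alpha Seed weight >= 1 (see [connectivity_p()]).
#' @param max_steps Maximum selections (default 5000).
#' @param tail Use the upper-tail statistic instead of the point mass.
#' @return An object of class `diamond_result`: list with `selection`
#'   (tibble `gene`, `step`, `p_value`), `seeds`, `alpha`, `n_ties` (count
#'   of tie-broken steps).
#' @export
diamond <- function(net, seeds, alpha = 1, max_steps = 5000L, tail = FALSE) {
  seeds <- check_seeds(net, seeds)
  A <- net$adjacency
  n <- net$n_nodes
  deg <- net$degree
  node_of <- net$nodes
  seed_mask <- net$nodes %in% seeds
  # links to original seeds, fixed across steps
  ks_orig <- as.numeric(A %*% as.numeric(seed_mask))
  in_set <- seed_mask
  kst <- ks_orig  # links to current seed set, updated incrementally
  sel_gene <- character(0); sel_p <- numeric(0)
  n_ties <- 0L
  for (step in seq_len(max_steps)) {
    cand <- which(!in_set & kst > 0)
    if (length(cand) == 0) break
    pvals <- vapply(cand, function(i) {
      connectivity_p(k = deg[[i]], k_st = kst[[i]], n_seeds = sum(in_set),
                     n = n, alpha = alpha, k_s = ks_orig[[i]],
                     n_orig_seeds = length(seeds), tail = tail)
    }, numeric(1))
    ord <- order(pvals, -kst[cand], node_of[cand])
    best <- cand[ord[1]]
    if (sum(pvals == min(pvals)) > 1) n_ties <- n_ties + 1L
    sel_gene <- c(sel_gene, node_of[best])
    sel_p <- c(sel_p, pvals[ord[1]])
    in_set[best] <- TRUE
    nbrs <- which(A[, best] != 0)
    kst[nbrs] <- kst[nbrs] + 1
  }
  if (length(sel_gene) == 0) {
    warning("DIAMOnD: seed set has no non-seed neighbours; nothing selected")
  }
  structure(
    list(selection = tibble::tibble(gene = sel_gene,
                                    step = seq_along(sel_gene),
                                    p_value = sel_p),
         seeds = seeds, alpha = alpha, n_ties = n_ties),
    class = "diamond_result"
  )
}

#' @export
print.diamond_result <- function(x, ...) {
  cat(sprintf("<diamond_result> %d gene(s) selected from %d seed(s) (alpha = %g)\n",
              nrow(x$selection), length(x$seeds), x$alpha))
  invisible(x)
}

#' Convert a DIAMOnD result to a full score table
#'
#' Selected genes score by negative selection step (so step 1 is best);
#' unselected non-seed genes get `NA` by default, or -- when a complete
#' ranking is required, e.g. for hits-within-top-10% metrics -- are placed
#' after all selected genes with a shared tail score so [rank_scores()]
#' assigns them averaged tail ranks (`force_complete = TRUE`).
#'
#' @param result A `diamond_result`.
#' @param net The `gene_network` it was run on.
#' @param force_complete Assign a shared tail score to unselected genes.
#' @return A tibble `gene`, `score` (NA score for unselected genes unless
#'   forced).
#' @export
diamond_scores <- function(result, net, force_complete = FALSE) {
  score <- stats::setNames(rep(NA_real_, net$n_nodes), net$nodes)
  score[result$selection$gene] <- -result$selection$step
  score[result$seeds] <- 1  # seeds above every selection; excluded downstream
  if (force_complete) {
    score[is.na(score)] <- -(nrow(result$selection) + 1)
  }
  tibble::tibble(gene = net$nodes, score = unname(score))
}

#' Degree-adjusted distance matrix
#'
#' All-pairs unweighted shortest-path lengths divided by the geometric
#' mean of the endpoint degrees: d_adj(i,j) = d_ij / sqrt(k_i k_j).
#' Entries across components are Inf; the diagonal is 0.
#'
#' @param net A `gene_network`.
#' @param ids Optional row subset (columns always span all nodes).
#' @return A dense numeric matrix with node-id dimnames.
#' @export
adjusted_distance <- function(net, ids = NULL) {
  v <- if (is.null(ids)) igraph::V(net$graph) else ids
  d <- igraph::distances(net$graph, v = v)
  k <- as.numeric(net$degree)
  rk <- if (is.null(ids)) k else k[match(ids, net$nodes)]
  d / sqrt(outer(rk, k[match(colnames(d), net$nodes)]))
}

#' GenePanda prioritization
#'
#' Scores a gene by how much closer it sits to the seed genes than to the
#' network at large, in degree-adjusted distance: the mean adjusted
#' distance to all nodes minus the mean adjusted distance to the seeds
#' (higher is better). Distances are computed on the largest connected
#' component; nodes outside it are returned with NA scores and every seed
#' must lie inside it.
#'
#' @param net A `gene_network`.
#' @param seeds Character vector of seed gene ids.
#' @return A tibble `gene`, `score` (NA outside the largest component).
#' @export
genepanda <- function(net, seeds) {
  seeds <- check_seeds(net, seeds)
  lcc <- largest_component_ids(net)
  out_seeds <- setdiff(seeds, lcc)
  if (length(out_seeds) > 0) {
    stop(sprintf("seed(s) outside the largest connected component: %s",
                 paste(out_seeds, collapse = ", ")), call. = FALSE)
  }
  sub <- induced_network(net, lcc)
  d_adj <- adjusted_distance(sub)
  mean_all <- rowSums(d_adj) / ncol(d_adj)
  mean_seed <- rowSums(d_adj[, seeds, drop = FALSE]) / length(seeds)
  score <- stats::setNames(rep(NA_real_, net$n_nodes), net$nodes)
  score[rownames(d_adj)] <- mean_all - mean_seed
  tibble::tibble(gene = net$nodes, score = unname(score))
}

#' Restrict a network to a node subset
#' @keywords internal
induced_network <- function(net, ids) {
  ids <- sort(intersect(net$nodes, ids))
  A <- net$adjacency[ids, ids, drop = FALSE]
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  structure(
    list(nodes = ids, adjacency = A,
         degree = stats::setNames(as.integer(Matrix::rowSums(A)), ids),
         graph = g, n_nodes = length(ids),
         n_edges = as.integer(Matrix::nnzero(A) / 2)),
    class = "gene_network"
  )
}
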