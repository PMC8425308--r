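# Independent brute-force oracles and small graph builders used across the
# suite. These deliberately avoid the package's own code paths (and igraph
# where the oracle is meant to be independent of it).

# quick network from an edge matrix / vectors of endpoints
make_net <- function(from, to) {
  network_from_edges(tibble::tibble(source = from, target = to), quiet = TRUE)
}

path_net <- function() make_net(c("a", "b"), c("b", "c"))
triangle_net <- function() make_net(c("a", "a", "b"), c("b", "c", "c"))
star_net <- function(leaves = 3) {
  make_net(rep("hub", leaves), paste0("leaf", seq_len(leaves)))
}

# Erdos-Renyi style random simple graph with no isolated nodes
rand_net <- function(n, p, seed) {
  set.seed(seed)
  pairs <- utils::combn(sprintf("n%03d", seq_len(n)), 2)
  keep <- stats::runif(ncol(pairs)) < p
  if (!any(keep)) keep[sample(ncol(pairs), 2)] <- TRUE
  make_net(pairs[1, keep], pairs[2, keep])
}

# Direct double-sum over all ordered pairs of the two-community modularity
# (zero-diagonal modularity matrix as the default).
modularity_oracle <- function(net, pathway, zero_diag = TRUE) {
  A <- as.matrix(net$adjacency)
  k <- as.numeric(net$degree)
  m <- net$n_edges
  s <- ifelse(net$nodes %in% pathway, -1, 1)
  total <- 0
  for (i in seq_len(net$n_nodes)) {
    for (j in seq_len(net$n_nodes)) {
      if (zero_diag && i == j) next
      total <- total + s[i] * s[j] * (A[i, j] - k[i] * k[j] / (2 * m))
    }
  }
  total / (4 * m)
}

# Closed-form restart-walk solution p = r (I - (1-r) W)^{-1} p0 by dense
# linear algebra; assumes no zero-degree nodes.
rwr_oracle <- function(W, p0, r) {
  W <- as.matrix(W)
  as.numeric(r * solve(diag(nrow(W)) - (1 - r) * W, p0))
}

# All-pairs BFS shortest-path lengths on an adjacency matrix, igraph-free.
bfs_all_pairs <- function(A) {
  A <- as.matrix(A) != 0
  n <- nrow(A)
  D <- matrix(Inf, n, n, dimnames = dimnames(A))
  for (s in seq_len(n)) {
    dist <- rep(Inf, n)
    dist[s] <- 0
    frontier <- s
    d <- 0
    while (length(frontier) > 0) {
      d <- d + 1
      nxt <- which(apply(A[frontier, , drop = FALSE], 2, any) & !is.finite(dist))
      dist[nxt] <- d
      frontier <- nxt
    }
    D[s, ] <- dist
  }
  D
}

# Direct combinatorial evaluation of the hypergeometric connectivity mass.
connectivity_oracle <- function(k, k_st, n_seeds, n) {
  choose(n_seeds, k_st) * choose(n - n_seeds, k - k_st) / choose(n, k)
}

# Naive DIAMOnD rescan: at every step recompute every candidate's links to
# the current set from scratch and pick the smallest p with the package's
# documented tie-break (higher k_st, then lexicographic id).
diamond_oracle <- function(net, seeds, max_steps = 50) {
  A <- as.matrix(net$adjacency)
  nodes <- net$nodes
  n <- net$n_nodes
  cur <- seeds
  out <- character(0)
  for (step in seq_len(max_steps)) {
    cand <- setdiff(nodes, cur)
    kst <- vapply(cand, function(v) sum(A[v, cur]), numeric(1))
    cand <- cand[kst > 0]
    if (length(cand) == 0) break
    stats_tab <- t(vapply(cand, function(v) {
      k <- sum(A[v, ])
      kst <- sum(A[v, cur])
      c(p = connectivity_oracle(k, kst, length(cur), n), kst = kst)
    }, numeric(2)))
    ord <- order(stats_tab[, "p"], -stats_tab[, "kst"], cand)
    best <- cand[ord[1]]
    out <- c(out, best)
    cur <- c(cur, best)
  }
  out
}
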