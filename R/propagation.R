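#' Random-walk-with-restart parameters
#'
#' @param restart Restart probability r in (0, 1]: the per-step probability
#'   of jumping back to the seed distribution. The headline default is 0.5;
#'   `rwr_grid()` gives the conventional tuning grid 0.1, 0.3, 0.5, 0.7,
#'   0.9.
#' @param tolerance L1 convergence tolerance on successive probability
#'   vectors (default 1e-8).
#' @param max_iter Iteration safeguard.
#' @return A list of class `rwr_params`.
#' @export
rwr_params <- function(restart = 0.5, tolerance = 1e-8, max_iter = 10000L) {
  stopifnot(restart > 0, restart <= 1, tolerance > 0, max_iter >= 1)
  structure(list(restart = restart, tolerance = tolerance,
                 max_iter = as.integer(max_iter)),
            class = "rwr_params")
}

#' Restart-probability tuning grid
#' @return Numeric vector `c(0.1, 0.3, 0.5, 0.7, 0.9)`.
#' @export
rwr_grid <- function() seq(0.1, 0.9, by = 0.2)

# Core power iteration p_t = (1-r) W p_{t-1} + r p0 with dangling
# (zero-degree) columns treated as restart-only: the probability mass
# sitting on them is fed back into p0 each step, conserving total mass.
rwr_iterate <- function(W, p0, params) {
  r <- params$restart
  if (r == 1) return(p0)
  dangling <- Matrix::colSums(W) == 0
  p <- p0
  for (iter in seq_len(params$max_iter)) {
    leak <- if (any(dangling)) sum(p[dangling]) else 0
    p_new <- as.numeric((1 - r) * (W %*% p)) + ((1 - r) * leak + r) * p0
    delta <- sum(abs(p_new - p))
    p <- p_new
    if (delta < params$tolerance) return(p)
  }
  stop(sprintf("RWR did not converge in %d iterations (last L1 residual %.3g)",
               params$max_iter, delta), call. = FALSE)
}

#' Random walk with restart (RWR)
#'
#' Propagates probability mass from the seed genes over the network by
#' iterating p_t = (1 - r) W p_{t-1} + r p_0 until the L1 change drops
#' below tolerance, where W is the column-normalized adjacency and p_0 is
#' uniform over the seeds. The converged probability at a gene is its
#' prioritization score: genes the walker visits often are network-close to
#' the seeds.
#'
#' @param net A `gene_network`.
#' @param seeds Character vector of seed gene ids.
#' @param params An [rwr_params()] object.
#' @return A tibble `gene`, `score` (converged probabilities).
#' @export
#' @examples
#' net <- network_from_edges(tibble::tibble(a = "a", b = "b"), quiet = TRUE)
#' rwr(net, "a", rwr_params(restart = 0.5))  # scores 2/3, 1/3
rwr <- function(net, seeds, params = rwr_params()) {
  seeds <- check_seeds(net, seeds)
  W <- column_normalize(net)
  p0 <- stats::setNames(numeric(net$n_nodes), net$nodes)
  p0[seeds] <- 1 / length(seeds)
  p <- rwr_iterate(W, unname(p0), params)
  tibble::tibble(gene = net$nodes, score = p)
}

#' Random walk with restart on the heterogeneous network (RWRH)
#'
#' Runs the same restart walk on the expanded adjacency of a
#' disease-gene heterogeneous network, so the walker can travel through
#' disease nodes: gene -> disease -> other genes associated with that
#' disease. The expanded matrix is column-normalized as a whole. By default
#' the restart vector puts its mass uniformly on the seed genes only;
#' `disease_weight > 0` additionally places that fraction of restart mass
#' on the query disease node.
#'
#' @param hnet A `hetero_network`.
#' @param seeds Character vector of seed gene ids.
#' @param disease Optional query-disease id; required when
#'   `disease_weight > 0`.
#' @param params An [rwr_params()].
#' @param disease_weight Fraction of restart mass on the query disease node
#'   (default 0).
#' @return A tibble `gene`, `score` with the gene-layer block of the
#'   converged probability vector; the disease-layer block is attached as
#'   attribute `"disease_scores"` for diagnostics.
#' @export
rwrh <- function(hnet, seeds, disease = NULL, params = rwr_params(),
                 disease_weight = 0) {
  stopifnot(is_hetero_network(hnet), disease_weight >= 0, disease_weight < 1)
  seeds <- check_seeds(hnet$gene_net, seeds)
  if (!is.null(disease) && !disease %in% hnet$disease_ids) {
    stop(sprintf("disease id '%s' not in the disease layer", disease),
         call. = FALSE)
  }
  if (disease_weight > 0 && is.null(disease)) {
    stop("disease_weight > 0 requires a `disease` id", call. = FALSE)
  }
  A <- hnet$expanded
  all_ids <- c(hnet$gene_net$nodes, hnet$disease_ids)
  W <- column_normalize(A)
  p0 <- stats::setNames(numeric(length(all_ids)), all_ids)
  p0[seeds] <- (1 - disease_weight) / length(seeds)
  if (disease_weight > 0) p0[disease] <- disease_weight
  p <- rwr_iterate(W, unname(p0), params)
  n <- hnet$gene_net$n_nodes
  out <- tibble::tibble(gene = hnet$gene_net$nodes, score = p[seq_len(n)])
  attr(out, "disease_scores") <- stats::setNames(p[-seq_len(n)], hnet$disease_ids)
  out
}

#' IDLP parameters
#'
#' Hyperparameters of improved dual label propagation: `alpha`/`beta`/
#' `gamma` act on the gene-network side, the primed triple on the
#' disease-similarity side. `gamma` weights how strongly the learnt
#' gene-disease matrix Y feeds back into the propagation graphs
#' (A* = A_norm + gamma Y Y^T). Defaults are alpha = alpha2 = 0.5,
#' beta = beta2 = 1, gamma = gamma2 = 0.1 with 20 iterations.
#'
#' @param alpha,beta,gamma Gene-side coefficients.
#' @param alpha2,beta2,gamma2 Disease-side coefficients.
#' @param n_iter Number of alternating iterations (default 20).
#' @param init_seed RNG seed for the random initialization of Y.
#' @return A list of class `idlp_params`.
#' @export
idlp_params <- function(alpha = 0.5, beta = 1, gamma = 0.1,
                        alpha2 = 0.5, beta2 = 1, gamma2 = 0.1,
                        n_iter = 20L, init_seed = 20210101L) {
  stopifnot(n_iter >= 1)
  structure(list(alpha = alpha, beta = beta, gamma = gamma,
                 alpha2 = alpha2, beta2 = beta2, gamma2 = gamma2,
                 n_iter = as.integer(n_iter), init_seed = as.integer(init_seed)),
            class = "idlp_params")
}

#' Improved dual label propagation (IDLP)
#'
#' Learns a gene-disease relationship matrix Y by alternating label
#' propagation between the gene network and the disease-similarity
#' network, each updated with the current Y before propagating:
#'
#' \enumerate{
#'   \item A* = A_norm + gamma Y Y^T
#'   \item Y  = beta (I - alpha A*)^{-1} A_PD
#'   \item A_DD* = A_DD_norm + gamma' Y^T Y
#'   \item Y  = beta' A_PD (I - alpha' A_DD*)^{-1}
#' }
#'
#' where A_norm and A_DD_norm are the symmetrically normalized layers.
#' Before iterating, an extra column for the query disease is appended to
#' A_PD with 1 at the seed genes (and a zero row/column is added to the
#' similarity layer for conformability if the query is not already a
#' disease node); Y is initialized with uniform(0,1) noise from a recorded
#' seed. After `n_iter` iterations the query-disease column of Y is the
#' prioritization score. `literal = TRUE` applies the resolvent-free
#' variants Y = beta (I - alpha) A*^{-1} A_PD and
#' Y = beta' A_PD (I - alpha' A_DD*) instead of the resolvent reading.
#'
#' A propagation operator must have spectral radius at most 1, otherwise
#' the resolvent (I - alpha A*)^{-1} amplifies instead of smoothing and
#' the alternation oscillates; the updated networks A* and A_DD* are
#' therefore symmetrically re-normalized before each propagation
#' (`renormalize = TRUE`, the default -- the same normalization the raw
#' layers receive). `renormalize = FALSE` propagates on the raw updated
#' sums.
#'
#' @param hnet A `hetero_network`.
#' @param seeds Character vector of seed gene ids.
#' @param params An [idlp_params()].
#' @param query Label used for the appended query-disease column.
#' @param literal Use the resolvent-free update forms (default FALSE).
#' @param renormalize Re-normalize the updated networks each iteration
#'   (default TRUE).
#' @return A tibble `gene`, `score`; attribute `"delta"` holds the
#'   per-iteration Frobenius change of Y.
#' @export
idlp <- function(hnet, seeds, params = idlp_params(), query = ".query",
                 literal = FALSE, renormalize = TRUE) {
  stopifnot(is_hetero_network(hnet))
  seeds <- check_seeds(hnet$gene_net, seeds)
  n <- hnet$gene_net$n_nodes
  A_norm <- as.matrix(symmetric_normalize(hnet$gene_net$adjacency))
  # augment the association matrix with the query column (1 at seed genes)
  A_pd <- cbind(as.matrix(hnet$gda),
                as.numeric(hnet$gene_net$nodes %in% seeds))
  colnames(A_pd)[ncol(A_pd)] <- query
  A_dd <- as.matrix(hnet$dsim)
  A_dd <- rbind(cbind(A_dd, 0), 0)  # zero row/col for the query disease
  A_dd_norm <- as.matrix(symmetric_normalize(A_dd))
  d <- ncol(A_pd)

  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(params$init_seed)
  Y <- matrix(stats::runif(n * d), n, d)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())

  I_n <- diag(n)
  I_d <- diag(d)
  delta <- numeric(params$n_iter)
  renorm <- function(M) {
    if (!renormalize) return(M)
    as.matrix(symmetric_normalize(M))
  }
  for (it in seq_len(params$n_iter)) {
    Y_prev <- Y
    A_star <- renorm(A_norm + params$gamma * tcrossprod(Y))
    Y <- if (literal) {
      params$beta * (1 - params$alpha) * solve(A_star, A_pd)
    } else {
      M <- I_n - params$alpha * A_star
      params$beta * tryCatch(
        solve(M, A_pd),
        error = function(e) stop("(I - alpha A*) is singular; use a smaller alpha",
                                 call. = FALSE)
      )
    }
    A_dd_star <- renorm(A_dd_norm + params$gamma2 * crossprod(Y))
    Y <- if (literal) {
      params$beta2 * A_pd %*% (I_d - params$alpha2 * A_dd_star)
    } else {
      M <- I_d - params$alpha2 * A_dd_star
      params$beta2 * t(tryCatch(
        solve(t(M), t(A_pd)),
        error = function(e) stop("(I - alpha' A_DD*) is singular; use a smaller alpha'",
                                 call. = FALSE)
      ))
    }
    delta[it] <- sqrt(sum((Y - Y_prev)^2))
  }
  out <- tibble::tibble(gene = hnet$gene_net$nodes, score = unname(Y[, d]))
  attr(out, "delta") <- delta
  out
}
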