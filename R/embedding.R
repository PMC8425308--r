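#' Node2vec walk parameters
#'
#' @param n_walks Walks started per node (default 20; conventional tuning
#'   grid 20/40/80).
#' @param walk_length Nodes per walk (default 80; grid 40/80/160).
#' @param p Return parameter; smaller p keeps the walk local (BFS-like).
#' @param q In-out parameter; smaller q pushes the walk outward (DFS-like).
#'   Grid for both: 0.5/1/2.
#' @param rng_seed Integer seed for the walk sampler.
#' @return A list of class `walk_params`.
#' @export
walk_params <- function(n_walks = 20L, walk_length = 80L, p = 1, q = 1,
                        rng_seed = 1L) {
  stopifnot(n_walks >= 1, walk_length >= 1, p > 0, q > 0)
  structure(list(n_walks = as.integer(n_walks),
                 walk_length = as.integer(walk_length),
                 p = p, q = q, rng_seed = as.integer(rng_seed)),
            class = "walk_params")
}

#' Sample node2vec biased random walks
#'
#' Generates `n_walks` second-order random walks of `walk_length` nodes
#' from every node. The transition from the previous node t through the
#' current node v is biased by 1/p towards returning to t, 1 towards
#' common neighbours of t and v, and 1/q towards nodes one step further
#' out, interpolating between breadth-first and depth-first exploration.
#' Walks that hit a dead end stop early; zero-degree start nodes are
#' skipped with a warning.
#'
#' @param net A `gene_network` (or a `hetero_network`, whose expanded
#'   adjacency is walked as one graph).
#' @param params A [walk_params()].
#' @return A list of character vectors (walks as node-id sequences), with
#'   the parameters attached as attribute `"params"`.
#' @export
sample_walks <- function(net, params = walk_params()) {
  A <- if (is_hetero_network(net)) net$expanded else net$adjacency
  ids <- if (is_hetero_network(net)) {
    c(net$gene_net$nodes, net$disease_ids)
  } else net$nodes
  if (Matrix::nnzero(A) == 0) stop("cannot walk a graph with no edges", call. = FALSE)
  deg <- Matrix::colSums(A)
  if (any(deg == 0)) {
    warning(sprintf("%d zero-degree node(s) skipped as walk starts", sum(deg == 0)))
  }
  A <- methods::as(A, "CsparseMatrix")  # column-compressed; symmetric so CSR==CSC
  walks <- cpp_node2vec_walks(A@p, A@i, params$n_walks, params$walk_length,
                              params$p, params$q, params$rng_seed)
  walks <- lapply(walks, function(w) ids[w + 1L])
  attr(walks, "params") <- params
  walks
}

#' Train a skip-gram node embedding
#'
#' Treats each walk as a sentence and each node as a word, and fits a
#' word2vec-style skip-gram model with negative sampling: vectors are
#' optimized so that nodes co-occurring within the context window of the
#' walks get similar representations. Training is single-threaded and
#' deterministic under `rng_seed`.
#'
#' @param walks List of node-id walks from [sample_walks()].
#' @param dim Embedding dimension (default 128; grid 64/128/256).
#' @param window Context window half-width (default 10).
#' @param epochs Training epochs (default 5).
#' @param negative Negative samples per positive pair (default 5).
#' @param alpha Initial learning rate.
#' @param rng_seed Integer seed for initialization and sampling.
#' @param nodes Optional character vector of node ids that must all occur
#'   in the walks; ids absent from every walk raise an error naming them.
#' @return An object of class `node_embedding`: list with `vectors`
#'   (nodes x dim numeric matrix, rownames = node ids) and the training
#'   metadata.
#' @export
train_embedding <- function(walks, dim = 128L, window = 10L, epochs = 5L,
                            negative = 5L, alpha = 0.025, rng_seed = 1L,
                            nodes = NULL) {
  stopifnot(length(walks) > 0, dim >= 1, window >= 1, epochs >= 1)
  vocab <- sort(unique(unlist(walks, use.names = FALSE)))
  if (!is.null(nodes)) {
    absent <- setdiff(nodes, vocab)
    if (length(absent) > 0) {
      stop(sprintf("node(s) absent from every walk: %s",
                   paste(absent, collapse = ", ")), call. = FALSE)
    }
  }
  idx <- stats::setNames(seq_along(vocab) - 1L, vocab)
  walks_int <- lapply(walks, function(w) unname(idx[w]))
  V <- cpp_skipgram(walks_int, length(vocab), as.integer(dim),
                    as.integer(window), as.integer(epochs),
                    as.integer(negative), alpha, as.integer(rng_seed))
  rownames(V) <- vocab
  structure(
    list(vectors = V, dim = as.integer(dim),
         meta = list(window = as.integer(window), epochs = as.integer(epochs),
                     negative = as.integer(negative), alpha = alpha,
                     rng_seed = as.integer(rng_seed))),
    class = "node_embedding"
  )
}

#' @export
print.node_embedding <- function(x, ...) {
  cat(sprintf("<node_embedding> %d nodes x %d dims\n", nrow(x$vectors), x$dim))
  invisible(x)
}

#' Check that required nodes are embedded
#' @keywords internal
check_embedded <- function(model, ids) {
  missing <- setdiff(ids, rownames(model$vectors))
  if (length(missing) > 0) {
    stop(sprintf("node(s) missing from the embedding: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

#' Max-cosine seed similarity score
#'
#' Scores each embedded node by the maximum cosine similarity between its
#' vector and any seed-gene vector; seeds score exactly 1 by
#' self-similarity and scores lie in \[-1, 1\].
#'
#' @param model A `node_embedding`.
#' @param seeds Character vector of seed ids (must all be embedded).
#' @return A tibble `gene`, `score` over all embedded nodes.
#' @export
n2v_score <- function(model, seeds) {
  seeds <- unique(as.character(seeds))
  check_embedded(model, seeds)
  V <- model$vectors
  nrm <- sqrt(rowSums(V^2))
  if (any(nrm == 0)) {
    stop(sprintf("zero-norm embedding vector for: %s",
                 paste(rownames(V)[nrm == 0], collapse = ", ")), call. = FALSE)
  }
  U <- V / nrm
  sim <- U %*% t(U[seeds, , drop = FALSE])
  score <- apply(sim, 1, max)
  score[seeds] <- 1  # exact, immune to float round-off
  tibble::tibble(gene = rownames(V), score = unname(score))
}

#' Node2vec prioritization (N2V / N2VH)
#'
#' Convenience wrapper: sample walks, train the skip-gram embedding, and
#' score every node by max cosine similarity to the seeds. Passing a
#' `hetero_network` walks the expanded disease-gene graph unchanged (the
#' N2VH variant); only gene-layer rows are returned in that case.
#'
#' @param net A `gene_network` or `hetero_network`.
#' @param seeds Character vector of seed gene ids.
#' @param walk A [walk_params()].
#' @param model An optional pre-trained `node_embedding` to reuse (the
#'   embedding is seed-independent, so cross-validation and random-seed
#'   experiments can train once and re-score per seed set).
#' @inheritParams train_embedding
#' @return A tibble `gene`, `score`.
#' @export
n2v <- function(net, seeds, walk = walk_params(), dim = 128L, window = 10L,
                epochs = 5L, negative = 5L, rng_seed = 1L, model = NULL) {
  gene_ids <- if (is_hetero_network(net)) net$gene_net$nodes else net$nodes
  if (is.null(model)) {
    walks <- sample_walks(net, walk)
    model <- train_embedding(walks, dim = dim, window = window,
                             epochs = epochs, negative = negative,
                             rng_seed = rng_seed)
  }
  scores <- n2v_score(model, seeds)
  dplyr::filter(scores, .data$gene %in% gene_ids)
}

#' Write / read an embedding as TSV
#'
#' Plain-text persistence: columns `node`, `v1`..`vd`.
#'
#' @param model A `node_embedding`.
#' @param path Output path.
#' @export
write_embedding <- function(model, path) {
  df <- tibble::as_tibble(model$vectors, .name_repair = ~ paste0("v", seq_along(.x)))
  df <- dplyr::bind_cols(tibble::tibble(node = rownames(model$vectors)), df)
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_embedding
#' @return `read_embedding()` returns a `node_embedding` (without training
#'   metadata).
#' @export
read_embedding <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    node = readr::col_character(), .default = readr::col_double()),
    progress = FALSE)
  V <- as.matrix(df[-1])
  rownames(V) <- df$node
  colnames(V) <- NULL
  structure(list(vectors = V, dim = ncol(V), meta = list()),
            class = "node_embedding")
}
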