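#' Available prioritization algorithms
#'
#' @return Character vector of algorithm keys accepted wherever an
#'   `algorithm` argument appears: `"rwr"`, `"n2v"`, `"diamond"`,
#'   `"genepanda"`, `"degree"` on a plain gene network and `"rwrh"`,
#'   `"n2vh"`, `"idlp"` on a heterogeneous network.
#' @export
prioritizer_keys <- function() {
  c("rwr", "n2v", "diamond", "genepanda", "degree", "rwrh", "n2vh", "idlp")
}

hetero_keys <- function() c("rwrh", "n2vh", "idlp")

#' Run a prioritizer by key
#'
#' Uniform entry point used by the benchmarking harness and the command
#' line: dispatches on an algorithm key and returns a score table (genes
#' never selected by DIAMOnD get NA scores). Unknown keys raise an error
#' listing the valid ones.
#'
#' @param algorithm One of [prioritizer_keys()], or a function
#'   `(net, seeds, ...) -> tibble(gene, score)`.
#' @param net A `gene_network`, or a `hetero_network` (required for the
#'   heterogeneous algorithms; gene-network algorithms run on its gene
#'   layer).
#' @param seeds Character vector of seed gene ids.
#' @param disease Query-disease id (heterogeneous algorithms).
#' @param params Optional parameter object ([rwr_params()],
#'   [idlp_params()], or [walk_params()] depending on the algorithm).
#' @param model Optional pre-trained `node_embedding` reused by
#'   `n2v`/`n2vh` (the embedding is seed-independent).
#' @param ... Passed through to the algorithm.
#' @return A tibble `gene`, `score`.
#' @export
run_prioritizer <- function(algorithm, net, seeds, disease = NULL,
                            params = NULL, model = NULL, ...) {
  if (is.function(algorithm)) return(algorithm(net, seeds, ...))
  algorithm <- match_algorithm(algorithm)
  gnet <- if (is_hetero_network(net)) net$gene_net else net
  if (algorithm %in% hetero_keys() && !is_hetero_network(net)) {
    stop(sprintf("algorithm '%s' needs a hetero_network", algorithm),
         call. = FALSE)
  }
  switch(
    algorithm,
    rwr = rwr(gnet, seeds, params = params %||% rwr_params()),
    rwrh = rwrh(net, seeds, disease = disease,
                params = params %||% rwr_params(), ...),
    idlp = idlp(net, seeds, params = params %||% idlp_params(), ...),
    n2v = n2v(gnet, seeds, walk = params %||% walk_params(),
              model = model, ...),
    n2vh = n2v(net, seeds, walk = params %||% walk_params(),
               model = model, ...),
    diamond = diamond_scores(diamond(gnet, seeds, ...), gnet),
    genepanda = genepanda(gnet, seeds),
    degree = degree_baseline(gnet)
  )
}

match_algorithm <- function(key) {
  if (!key %in% prioritizer_keys()) {
    stop(sprintf("unknown algorithm '%s'; valid keys: %s",
                 key, paste(prioritizer_keys(), collapse = ", ")),
         call. = FALSE)
  }
  key
}

#' Train the node embedding an algorithm key needs, if any
#' @keywords internal
maybe_train_model <- function(algorithm, net, params = NULL, ...) {
  if (!is.character(algorithm) || !algorithm %in% c("n2v", "n2vh")) return(NULL)
  target <- if (algorithm == "n2vh") {
    stopifnot(is_hetero_network(net))
    net
  } else if (is_hetero_network(net)) net$gene_net else net
  walks <- sample_walks(target, params %||% walk_params())
  train_embedding(walks, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
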