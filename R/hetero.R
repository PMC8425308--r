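#' Assemble a disease-gene heterogeneous network
#'
#' Combines a gene network with a bipartite gene-disease association (GDA)
#' layer and a disease-disease similarity layer into one expanded adjacency
#'
#' \deqn{A^{expand} = \begin{bmatrix} A & A_{PD} \\ A_{PD}^T & A_{DD} \end{bmatrix}}
#'
#' on which heterogeneous-network prioritizers (RWRH, N2VH) operate as if
#' it were one graph.
#'
#' @param gene_net A `gene_network`.
#' @param gda Data frame of gene-disease associations with columns
#'   `gene`, `disease` (extra columns ignored); associations whose gene is
#'   absent from the network are dropped with a message.
#' @param dsim Data frame of disease-disease similarity edges with columns
#'   `disease1`, `disease2`. May be `NULL` for no similarity edges.
#' @param disease_ids Optional character vector fixing the disease node set
#'   and order; defaults to all diseases seen in `gda`/`dsim`.
#'
#' @return An object of class `hetero_network`: list with `gene_net`,
#'   `gda` (sparse n x d 0/1 matrix), `dsim` (sparse d x d symmetric),
#'   `disease_ids`, and `expanded` (sparse (n+d) x (n+d) symmetric).
#' @export
hetero_network <- function(gene_net, gda, dsim = NULL, disease_ids = NULL) {
  stopifnot(is_gene_network(gene_net))
  gda <- tibble::tibble(gene = as.character(gda[[1]]),
                        disease = as.character(gda[[2]]))
  dropped <- sum(!gda$gene %in% gene_net$nodes)
  if (dropped > 0) {
    message(sprintf("hetero_network: dropped %d association(s) with genes absent from the network",
                    dropped))
    gda <- dplyr::filter(gda, .data$gene %in% gene_net$nodes)
  }
  if (!is.null(dsim) && nrow(dsim) > 0) {
    dsim <- tibble::tibble(disease1 = as.character(dsim[[1]]),
                           disease2 = as.character(dsim[[2]]))
  } else {
    dsim <- tibble::tibble(disease1 = character(), disease2 = character())
  }
  if (is.null(disease_ids)) {
    disease_ids <- sort(unique(c(gda$disease, dsim$disease1, dsim$disease2)))
  }
  if (length(disease_ids) == 0) stop("no disease nodes", call. = FALSE)
  n <- gene_net$n_nodes
  d <- length(disease_ids)
  gidx <- stats::setNames(seq_len(n), gene_net$nodes)
  didx <- stats::setNames(seq_len(d), disease_ids)

  gda <- dplyr::distinct(gda)
  A_pd <- Matrix::sparseMatrix(
    i = gidx[gda$gene], j = didx[gda$disease], x = 1,
    dims = c(n, d), dimnames = list(gene_net$nodes, disease_ids)
  )
  dsim <- dsim |>
    dplyr::filter(.data$disease1 != .data$disease2) |>
    dplyr::mutate(lo = pmin(.data$disease1, .data$disease2),
                  hi = pmax(.data$disease1, .data$disease2)) |>
    dplyr::distinct(.data$lo, .data$hi)
  if (nrow(dsim) > 0) {
    A_dd <- Matrix::sparseMatrix(
      i = c(didx[dsim$lo], didx[dsim$hi]),
      j = c(didx[dsim$hi], didx[dsim$lo]), x = 1,
      dims = c(d, d), dimnames = list(disease_ids, disease_ids)
    )
  } else {
    A_dd <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                 dims = c(d, d),
                                 dimnames = list(disease_ids, disease_ids))
  }
  structure(
    list(gene_net = gene_net,
         gda = methods::as(A_pd, "CsparseMatrix"),
         dsim = methods::as(A_dd, "CsparseMatrix"),
         disease_ids = disease_ids,
         expanded = expand_adjacency(gene_net$adjacency, A_pd, A_dd)),
    class = "hetero_network"
  )
}

expand_adjacency <- function(A, A_pd, A_dd) {
  methods::as(rbind(cbind(A, A_pd), cbind(Matrix::t(A_pd), A_dd)),
              "CsparseMatrix")
}

is_hetero_network <- function(x) inherits(x, "hetero_network")

#' @export
print.hetero_network <- function(x, ...) {
  cat(sprintf("<hetero_network> %d genes, %d diseases, %d GDA edge(s), %d similarity edge(s)\n",
              x$gene_net$n_nodes, length(x$disease_ids),
              Matrix::nnzero(x$gda), Matrix::nnzero(x$dsim) / 2))
  invisible(x)
}

#' Remove or restore a gene-disease association edge
#'
#' Returns a copy of the heterogeneous network with the (gene, disease)
#' association set to `value` in both the bipartite layer and the expanded
#' adjacency. Used by cross-validation to delete the association to a
#' left-out seed gene so the fold cannot leak it.
#'
#' @param hnet A `hetero_network`.
#' @param gene,disease Node ids.
#' @param value 0 (remove) or 1 (restore).
#' @return A `hetero_network`.
#' @export
set_gda_edge <- function(hnet, gene, disease, value) {
  stopifnot(is_hetero_network(hnet), value %in% c(0, 1))
  if (!gene %in% hnet$gene_net$nodes) stop("unknown gene id", call. = FALSE)
  if (!disease %in% hnet$disease_ids) stop("unknown disease id", call. = FALSE)
  A_pd <- hnet$gda
  A_pd[gene, disease] <- value
  A_pd <- Matrix::drop0(A_pd)
  hnet$gda <- methods::as(A_pd, "CsparseMatrix")
  hnet$expanded <- expand_adjacency(hnet$gene_net$adjacency, hnet$gda, hnet$dsim)
  hnet
}

#' Read gene-disease associations / disease similarities from TSV
#'
#' Both files share the edge-list dialect: two id columns, `#` comments
#' ignored, extra columns dropped.
#'
#' @param path Path to the TSV.
#' @return A tibble with two character columns.
#' @export
read_association_list <- function(path) {
  ed <- readr::read_tsv(path, comment = "#", col_names = FALSE,
                        col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  if (ncol(ed) < 2) stop(sprintf("'%s' must have at least 2 columns", path),
                         call. = FALSE)
  tibble::tibble(from = ed[[1]], to = ed[[2]])
}
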