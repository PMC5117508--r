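#' Build an interaction network from a weighted edge table
#'
#' Filters a STRING-style edge table at a confidence threshold and returns
#' the binary association structure that the ordering engine consumes.
#' Edges are kept when `confidence` is strictly greater than
#' `min_confidence`; self-loops are discarded; duplicate undirected pairs
#' (including reversed duplicates, as in tables that list both directions)
#' are collapsed to a single edge carrying the maximum confidence seen
#' before thresholding. Genes left with no retained edge are dropped, so
#' every gene in the result has degree at least one.
#'
#' @param edges A data frame with columns `gene_a`, `gene_b`, `confidence`
#'   and optionally `channel` (an evidence-channel tag).
#' @param min_confidence Confidence threshold in `[0, 1]`; edges must exceed
#'   it strictly to be retained. Default `0.8`.
#' @param exclude_channels Optional character vector of evidence channels to
#'   discard before thresholding (e.g. `"textmining"`). Ignored when the
#'   table has no `channel` column.
#'
#' @return An `interaction_network` object: a list with elements `genes`
#'   (unique identifiers in lexicographic order), `adjacency` (symmetric
#'   0/1 integer matrix with zero diagonal, dimnames = genes), `n_genes`,
#'   and `edges` (tibble of retained undirected edges).
#'
#' @examples
#' edges <- tibble::tibble(
#'   gene_a = c("g1", "g2", "g3"),
#'   gene_b = c("g2", "g3", "g3"),
#'   confidence = c(0.95, 0.90, 0.99)
#' )
#' net <- load_interactions(edges, min_confidence = 0.8)
#' net$n_genes
#' @export
load_interactions <- function(edges, min_confidence = 0.8,
                              exclude_channels = NULL) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  required <- c("gene_a", "gene_b", "confidence")
  if (!all(required %in% names(edges))) {
    abort(paste0("`edges` must have columns ",
                 paste(required, collapse = ", ")))
  }
  if (nrow(edges) == 0L) abort("`edges` is empty")
  if (!is.numeric(edges$confidence) || anyNA(edges$confidence)) {
    abort("`confidence` must be numeric with no missing values")
  }
  if (any(edges$confidence < 0 | edges$confidence > 1)) {
    abort("`confidence` values must lie in [0, 1]")
  }
  if (!is.numeric(min_confidence) || min_confidence < 0 || min_confidence > 1) {
    abort("`min_confidence` must be a number in [0, 1]")
  }
  ga <- as.character(edges$gene_a)
  gb <- as.character(edges$gene_b)
  if (anyNA(ga) || anyNA(gb) || any(!nzchar(ga)) || any(!nzchar(gb))) {
    abort("gene identifiers must be non-empty strings")
  }

  if (!is.null(exclude_channels) && "channel" %in% names(edges)) {
    keep <- !(as.character(edges$channel) %in% exclude_channels)
    ga <- ga[keep]; gb <- gb[keep]
    edges <- edges[keep, , drop = FALSE]
  }
  conf <- edges$confidence

  keep <- ga != gb  # self-associations discarded
  ga <- ga[keep]; gb <- gb[keep]; conf <- conf[keep]
  if (length(ga) == 0L) abort("no genes survive threshold")

  # undirected dedupe, keeping the maximum confidence per pair
  lo <- pmin(ga, gb)
  hi <- pmax(ga, gb)
  tab <- tibble::tibble(gene_a = lo, gene_b = hi, confidence = conf) |>
    dplyr::group_by(.data$gene_a, .data$gene_b) |>
    dplyr::summarise(confidence = max(.data$confidence), .groups = "drop") |>
    dplyr::filter(.data$confidence > min_confidence)

  if (nrow(tab) == 0L) abort("no genes survive threshold")

  genes <- sort(unique(c(tab$gene_a, tab$gene_b)))
  n <- length(genes)
  adj <- matrix(0L, n, n, dimnames = list(genes, genes))
  ia <- match(tab$gene_a, genes)
  ib <- match(tab$gene_b, genes)
  adj[cbind(ia, ib)] <- 1L
  adj[cbind(ib, ia)] <- 1L

  new_interaction_network(genes, adj, tab)
}

new_interaction_network <- function(genes, adjacency, edges) {
  structure(
    list(genes = genes, adjacency = adjacency, n_genes = length(genes),
         edges = edges),
    class = "interaction_network"
  )
}

#' @export
print.interaction_network <- function(x, ...) {
  cat("<interaction_network> ", x$n_genes, " genes, ",
      nrow(x$edges), " associations\n", sep = "")
  invisible(x)
}

#' Association matrix under a given gene order
#'
#' Entry (i, j) is 1 iff the genes placed at list positions i and j
#' associate in the network; the matrix is symmetric with zero diagonal.
#'
#' @param network An `interaction_network`.
#' @param order A character vector: a permutation of the network's genes,
#'   position -> gene. Also accepts a `gene_ordering` object.
#' @return An `n_genes` x `n_genes` integer 0/1 matrix whose dimnames are
#'   the genes in list order.
#' @export
association_matrix <- function(network, order) {
  stopifnot(inherits(network, "interaction_network"))
  order <- as_gene_order(order)
  check_permutation(order, network$genes)
  network$adjacency[order, order]
}

check_permutation <- function(order, genes) {
  if (anyDuplicated(order)) {
    abort("invalid permutation: duplicated gene in `order`")
  }
  if (length(order) != length(genes) || !setequal(order, genes)) {
    abort("invalid permutation: `order` must contain each network gene exactly once")
  }
  invisible(order)
}

as_gene_order <- function(x) {
  if (inherits(x, "gene_ordering")) return(x$order)
  if (is.character(x)) return(x)
  abort("expected a character gene order or a `gene_ordering` object")
}
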