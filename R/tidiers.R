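# broom-style tidiers for the package's result objects.

#' Tidy an interaction network into its edge table
#'
#' @param x An `interaction_network`.
#' @param ... Unused.
#' @return A tibble of retained undirected edges (`gene_a`, `gene_b`,
#'   `confidence`).
#' @export
tidy.interaction_network <- function(x, ...) {
  tibble::as_tibble(x$edges)
}

#' One-row summary of an interaction network
#'
#' @param x An `interaction_network`.
#' @param ... Unused.
#' @return A one-row tibble: `n_genes`, `n_edges`, `density`,
#'   `mean_degree`.
#' @export
glance.interaction_network <- function(x, ...) {
  n <- x$n_genes
  e <- nrow(x$edges)
  tibble::tibble(
    n_genes = n, n_edges = e,
    density = e / (n * (n - 1) / 2),
    mean_degree = 2 * e / n
  )
}

#' Tidy a gene ordering into a position/gene table
#'
#' @param x A `gene_ordering`.
#' @param ... Unused.
#' @return A tibble with columns `position`, `relative_position`, `gene`.
#' @export
tidy.gene_ordering <- function(x, ...) {
  n <- length(x$order)
  tibble::tibble(position = seq_len(n),
                 relative_position = seq_len(n) / n,
                 gene = x$order)
}

#' One-row summary of a gene ordering
#'
#' @param x A `gene_ordering`.
#' @param ... Unused.
#' @return A one-row tibble: `n_genes`, `cost`, `alpha`, `seed`.
#' @export
glance.gene_ordering <- function(x, ...) {
  tibble::tibble(n_genes = length(x$order), cost = x$cost,
                 alpha = x$alpha, seed = x$seed)
}

#' One-row summary of a class comparison
#'
#' @param x A `class_comparison`.
#' @param ... Unused.
#' @return A one-row tibble with the compared classes, the number of list
#'   positions, the counts significant at P < 0.05 and P < 0.01, and the
#'   extreme relative-transcriptogram values.
#' @export
glance.class_comparison <- function(x, ...) {
  tibble::tibble(
    class_p = attr(x, "class_p"), class_r = attr(x, "class_r"),
    n_positions = nrow(x),
    n_p_lt_05 = sum(x$p_value < 0.05),
    n_p_lt_01 = sum(x$p_value < 0.01),
    max_delta = max(x$delta), min_delta = min(x$delta)
  )
}

#' One-row summary of a volcano analysis
#'
#' @param x A `volcano_result`.
#' @param ... Unused.
#' @return A one-row tibble with the thresholds and the flagged-gene
#'   counts (total, up, down).
#' @export
glance.volcano_result <- function(x, ...) {
  tibble::tibble(
    class_a = attr(x, "class_a"), class_b = attr(x, "class_b"),
    fc_threshold = attr(x, "fc_threshold"),
    p_threshold = attr(x, "p_threshold"),
    n_genes = nrow(x),
    n_significant = sum(x$significant),
    n_up = sum(x$significant & x$log2_fc > 0),
    n_down = sum(x$significant & x$log2_fc < 0)
  )
}
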