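# Readers/writers for the plain-text interchange formats: STRING-style
# edge lists, ordered-list TSVs, expression + label tables, GMT gene sets.

#' Read a weighted edge list and build the interaction network
#'
#' Parses a tab-separated table with header
#' `gene_a<TAB>gene_b<TAB>confidence[<TAB>channel]` (comment lines start
#' with `#`) and passes it to [load_interactions()]. Malformed rows —
#' wrong column count or a non-numeric confidence — raise a parse error
#' naming the offending line.
#'
#' @param file Path to the edge-list TSV.
#' @inheritParams load_interactions
#' @return An `interaction_network`.
#' @export
read_interactions <- function(file, min_confidence = 0.8,
                              exclude_channels = NULL) {
  lines <- readLines(file)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) < 2L) abort("edge-list file has no data rows")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  header <- parts[[1L]]
  ncol_expected <- length(header)
  if (!(ncol_expected %in% c(3L, 4L))) {
    abort("edge-list header must have 3 or 4 tab-separated columns")
  }
  body <- parts[-1L]
  nc <- lengths(body)
  if (any(nc != ncol_expected)) {
    bad <- which(nc != ncol_expected)[1L]
    abort(sprintf("parse error at line %d: expected %d columns, found %d",
                  lineno[-1L][bad], ncol_expected, nc[bad]))
  }
  conf_chr <- vapply(body, `[[`, character(1), 3L)
  conf <- suppressWarnings(as.numeric(conf_chr))
  if (anyNA(conf)) {
    bad <- which(is.na(conf))[1L]
    abort(sprintf("parse error at line %d: non-numeric confidence '%s'",
                  lineno[-1L][bad], conf_chr[bad]))
  }
  edges <- tibble::tibble(
    gene_a = vapply(body, `[[`, character(1), 1L),
    gene_b = vapply(body, `[[`, character(1), 2L),
    confidence = conf
  )
  if (ncol_expected == 4L) {
    edges$channel <- vapply(body, `[[`, character(1), 4L)
  }
  load_interactions(edges, min_confidence = min_confidence,
                    exclude_channels = exclude_channels)
}

#' Write a network's retained edges as an edge-list TSV
#'
#' @param network An `interaction_network`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_interactions <- function(network, file) {
  stopifnot(inherits(network, "interaction_network"))
  readr::write_tsv(network$edges, file)
  invisible(file)
}

#' Read / write an ordered gene list
#'
#' The ordered-list format is a TSV `position<TAB>gene` with 1-based
#' positions; these two functions round-trip it.
#'
#' @param file Path to the TSV.
#' @param network Optional `interaction_network`; when supplied, the
#'   loaded order is validated against it and a full `gene_ordering`
#'   (with cost) is returned, otherwise a bare character order.
#' @param alpha Distance exponent used when recomputing the cost.
#' @return `read_ordering()`: a character gene order, or a
#'   `gene_ordering` when `network` is given. `write_ordering()`: the
#'   path, invisibly.
#' @export
read_ordering <- function(file, network = NULL, alpha = 1) {
  tab <- readr::read_tsv(file, col_types = readr::cols(
    position = readr::col_integer(), gene = readr::col_character()
  ))
  tab <- dplyr::arrange(tab, .data$position)
  if (!identical(tab$position, seq_len(nrow(tab)))) {
    abort("ordered-list positions must be 1..N without gaps")
  }
  if (is.null(network)) return(tab$gene)
  ordering_state(network, tab$gene, alpha = alpha)
}

#' @rdname read_ordering
#' @param ordering A `gene_ordering` or character gene order.
#' @export
write_ordering <- function(ordering, file) {
  order <- as_gene_order(ordering)
  readr::write_tsv(tibble::tibble(position = seq_along(order), gene = order),
                   file)
  invisible(file)
}

#' Read an expression table and its sample labels
#'
#' `read_expression()` reads a TSV whose first column is the gene
#' identifier and whose remaining columns are samples;
#' `read_labels()` reads the companion `sample<TAB>class` file.
#'
#' @param file Path to the TSV.
#' @return A tibble.
#' @export
read_expression <- function(file) {
  readr::read_tsv(file, col_types = readr::cols(
    .default = readr::col_double(), gene = readr::col_character()
  ))
}

#' @rdname read_expression
#' @export
read_labels <- function(file) {
  readr::read_tsv(file, col_types = readr::cols(
    sample = readr::col_character(), class = readr::col_character()
  ))
}

#' Read / write GMT gene-set files
#'
#' GMT is the tab-separated gene-set format: one set per line as
#' `name<TAB>description<TAB>member1<TAB>member2...`. Reading is
#' delegated to [fgsea::gmtPathways()].
#'
#' @param file Path to the GMT file.
#' @return `read_gmt()`: a named list of character vectors.
#' @export
read_gmt <- function(file) {
  fgsea::gmtPathways(file)
}

#' @rdname read_gmt
#' @param gene_sets Named list of character vectors.
#' @param descriptions Optional character vector of set descriptions
#'   (recycled `NA` -> set name).
#' @export
write_gmt <- function(gene_sets, file, descriptions = NULL) {
  if (is.null(names(gene_sets)) || any(!nzchar(names(gene_sets)))) {
    abort("`gene_sets` must be a named list")
  }
  desc <- descriptions %||% names(gene_sets)
  lines <- vapply(seq_along(gene_sets), function(k) {
    paste(c(names(gene_sets)[k], desc[k], gene_sets[[k]]), collapse = "\t")
  }, character(1))
  writeLines(lines, file)
  invisible(file)
}
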