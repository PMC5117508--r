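#' Binary term-membership indicator along an ordered list
#'
#' `h[i] = 1` when the gene at list position `i` belongs to the term
#' (pathway, GO-like set), 0 otherwise. Term genes absent from the list
#' are ignored; an empty intersection gives an all-zero vector with a
#' warning.
#'
#' @param ordered_genes Character gene order (or a `gene_ordering`).
#' @param term_genes Character vector of term member genes.
#' @return Integer 0/1 vector of length `N`, named by gene.
#' @export
term_indicator <- function(ordered_genes, term_genes) {
  ordered_genes <- as_gene_order(ordered_genes)
  h <- as.integer(ordered_genes %in% term_genes)
  if (sum(h) == 0L) {
    warn("no term gene occurs in the ordered list; indicator is all zero")
  }
  names(h) <- ordered_genes
  h
}

#' Sliding-window running average along the ordered list
#'
#' Smooths a per-position vector with a centred window of size `2r + 1`:
#' `k[i] = mean(x[(i - r):(i + r)])`. Only full windows are reported — no
#' edge padding — so the profile covers positions `r+1 .. N-r`
#' (`N - 2r` values). The default radius is 30 positions.
#'
#' @param x Numeric vector of length `N` along the ordered list.
#' @param r Window radius (window size `2r + 1`). Default 30.
#' @return A `transcriptogram_profile` tibble with columns `position`
#'   (1-based list position of the window centre), `relative_position`
#'   (`position / N`) and `value`; attributes `radius` and `n_genes`.
#' @export
smooth_profile <- function(x, r = 30L) {
  if (!is.numeric(x)) abort("`x` must be numeric")
  n <- length(x)
  r <- as.integer(r)
  if (r < 0L) abort("`r` must be >= 0")
  if (n <= 2L * r + 1L) {
    abort(sprintf("window too large: need N > 2r + 1 (N = %d, r = %d)", n, r))
  }
  w <- 2L * r + 1L
  cs <- c(0, cumsum(x))
  sums <- cs[(w + 1L):(n + 1L)] - cs[seq_len(n - w + 1L)]
  positions <- (r + 1L):(n - r)
  new_profile(positions, sums / w, n, r)
}

new_profile <- function(positions, values, n_genes, radius,
                        extra = NULL) {
  out <- tibble::tibble(
    position = as.integer(positions),
    relative_position = positions / n_genes,
    value = as.numeric(values)
  )
  if (!is.null(extra)) out <- dplyr::bind_cols(extra, out)
  tibble::new_tibble(out, radius = as.integer(radius),
                     n_genes = as.integer(n_genes),
                     class = "transcriptogram_profile")
}

#' Term-enrichment density profile
#'
#' Windowed average of the [term_indicator()]: the value at position `i`
#' is the fraction of genes in the window `i - r .. i + r` that belong to
#' the term. A value of 1 means every gene in the window participates.
#'
#' @inheritParams term_indicator
#' @inheritParams smooth_profile
#' @return A `transcriptogram_profile` tibble with values in `[0, 1]`.
#' @export
enrichment_profile <- function(ordered_genes, term_genes, r = 30L) {
  smooth_profile(term_indicator(ordered_genes, term_genes), r = r)
}

#' Transcriptograms: expression profiles along the ordered list
#'
#' Maps an expression table onto the ordered gene list and smooths each
#' sample with the centred running average of [smooth_profile()]. Genes in
#' the expression table that are absent from the ordered list are dropped
#' (with a message); genes in the list with no expression value are
#' averaged over — each window mean is taken over the genes present in
#' that window — with a hard error if any window has less than 50%
#' coverage.
#'
#' @param expression A data frame whose first column (`gene`) holds gene
#'   identifiers and whose remaining numeric columns are samples.
#' @param ordering A `gene_ordering` or character gene order.
#' @param r Window radius. Default 30.
#' @param samples Optional character vector restricting which sample
#'   columns to profile.
#' @return A long `transcriptogram_profile` tibble with columns `sample`,
#'   `position`, `relative_position`, `value`.
#' @export
transcriptogram <- function(expression, ordering, r = 30L, samples = NULL) {
  expression <- as.data.frame(expression, stringsAsFactors = FALSE)
  gene_col <- if ("gene" %in% names(expression)) "gene" else names(expression)[1L]
  genes_expr <- as.character(expression[[gene_col]])
  if (anyDuplicated(genes_expr)) abort("duplicated gene identifiers in `expression`")
  value_cols <- setdiff(names(expression), gene_col)
  if (!is.null(samples)) {
    missing <- setdiff(samples, value_cols)
    if (length(missing)) {
      abort(paste0("samples not present in `expression`: ",
                   paste(missing, collapse = ", ")))
    }
    value_cols <- samples
  }
  if (!all(vapply(expression[value_cols], is.numeric, logical(1)))) {
    abort("sample columns must be numeric")
  }

  ord <- as_gene_order(ordering)
  n <- length(ord)
  r <- as.integer(r)
  if (n <= 2L * r + 1L) {
    abort(sprintf("window too large: need N > 2r + 1 (N = %d, r = %d)", n, r))
  }

  n_dropped <- sum(!(genes_expr %in% ord))
  if (n_dropped > 0L) {
    inform(sprintf("dropping %d expression gene(s) absent from the ordered list",
                   n_dropped))
  }
  idx <- match(ord, genes_expr)  # NA where the list gene has no expression row
  present <- !is.na(idx)

  w <- 2L * r + 1L
  positions <- (r + 1L):(n - r)
  cs_present <- c(0, cumsum(as.integer(present)))
  n_in_window <- cs_present[(w + 1L):(n + 1L)] - cs_present[seq_len(n - w + 1L)]
  if (any(n_in_window < 0.5 * w)) {
    abort(sprintf(
      "window coverage below 50%% at list position %d: too many list genes lack expression values",
      positions[which(n_in_window < 0.5 * w)[1L]]))
  }

  profiles <- purrr::map(value_cols, function(s) {
    v <- expression[[s]][idx]
    v[!present] <- 0
    cs <- c(0, cumsum(v))
    sums <- cs[(w + 1L):(n + 1L)] - cs[seq_len(n - w + 1L)]
    sums / n_in_window
  })

  out <- purrr::map2_dfr(value_cols, profiles, function(s, v) {
    tibble::tibble(sample = s, position = positions,
                   relative_position = positions / n, value = v)
  })
  tibble::new_tibble(out, radius = r, n_genes = n,
                     class = "transcriptogram_profile")
}

profile_radius <- function(profile) attr(profile, "radius")
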