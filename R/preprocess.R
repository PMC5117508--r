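# Probe tables are tibbles with columns
#   probe, is_negative_control, gene, <sample1>, ..., <sampleK>
# Intensity columns are every numeric column after the three metadata ones.

probe_value_cols <- function(probes) {
  meta <- c("probe", "is_negative_control", "gene")
  if (!all(meta %in% names(probes))) {
    abort("probe table needs columns probe, is_negative_control, gene")
  }
  setdiff(names(probes), meta)
}

#' Normalize raw array intensities
#'
#' Per array: subtract a constant to bring the minimum intensity to 1,
#' then take log2. Across arrays the transformed intensities are then
#' mapped so that their cumulative distributions coincide, realised as
#' quantile normalization (each array's sorted values are replaced by the
#' rank-wise mean across arrays), which preserves within-array rank order
#' exactly. With a single array the cross-array mapping is skipped with a
#' warning.
#'
#' @param probes A probe table (see [generate_raw_probes()] for the
#'   layout): columns `probe`, `is_negative_control`, `gene`, then one
#'   numeric intensity column per array.
#' @return The probe table with intensity columns replaced by normalized
#'   log2 values.
#' @export
normalize_arrays <- function(probes) {
  probes <- tibble::as_tibble(probes)
  cols <- probe_value_cols(probes)
  if (length(cols) == 0L) abort("no intensity columns")
  m <- as.matrix(probes[cols])
  if (!is.numeric(m) || any(!is.finite(m))) {
    abort("intensities must be finite numbers")
  }
  shifted <- sweep(m, 2L, apply(m, 2L, min) - 1)  # per-array min -> 1
  lg <- log2(shifted)
  if (ncol(lg) >= 2L) {
    lg <- limma::normalizeQuantiles(lg)
  } else {
    warn("single array: cross-array distribution mapping skipped")
  }
  probes[cols] <- as.data.frame(lg)
  probes
}

#' Limit-of-detection filter
#'
#' Removes probes whose 90th percentile across samples lies below the
#' limit of detection, estimated from the negative-control probes as
#' `mean + 1.96 * sd` of their (normalized) intensities. By default the
#' controls are pooled across arrays; `per_array = TRUE` computes one LoD
#' per array and compares each probe's 90th percentile of per-array
#' exceedances instead. Negative-control rows themselves are kept (they
#' are dropped later by [collapse_probes()]).
#'
#' @param probes A normalized probe table.
#' @param z Multiplier on the negative-control standard deviation.
#'   Default 1.96.
#' @param prob Percentile of a probe's values that must reach the LoD.
#'   Default 0.9.
#' @param per_array Compute the LoD per array instead of pooled.
#' @return The probe table without the undetected probes; attribute
#'   `lod` records the threshold used.
#' @export
detection_filter <- function(probes, z = 1.96, prob = 0.9,
                             per_array = FALSE) {
  probes <- tibble::as_tibble(probes)
  cols <- probe_value_cols(probes)
  neg <- as.logical(probes$is_negative_control)
  if (sum(neg) == 0L) {
    warn("no negative-control probes: detection filter skipped")
    return(probes)
  }
  negvals <- as.matrix(probes[neg, cols])
  if (length(negvals) < 2L) abort("need at least 2 negative-control values")
  m <- as.matrix(probes[cols])
  if (per_array) {
    lod <- colMeans(negvals) + z * apply(negvals, 2L, stats::sd)
    excess <- sweep(m, 2L, lod)
    q90 <- apply(excess, 1L, stats::quantile, probs = prob, names = FALSE)
    keep <- neg | q90 >= 0
    lod_out <- lod
  } else {
    lod <- mean(negvals) + z * stats::sd(as.vector(negvals))
    q90 <- apply(m, 1L, stats::quantile, probs = prob, names = FALSE)
    keep <- neg | q90 >= lod
    lod_out <- lod
  }
  out <- probes[keep, , drop = FALSE]
  attr(out, "lod") <- lod_out
  out
}

#' Low-range filter
#'
#' Removes probes whose intensity range across all samples — the
#' difference between the 95th and the 5th percentile of the probe's
#' values — is below `log2(1.5)` (about 0.585, i.e. less than 1.5-fold
#' variation). Percentiles use linear interpolation (quantile type 7);
#' probe retention near the cutoff depends on this convention.
#'
#' @param probes A normalized probe table.
#' @param min_range Range cutoff on the log2 scale. Default `log2(1.5)`.
#' @return The probe table without the low-range probes.
#' @export
range_filter <- function(probes, min_range = log2(1.5)) {
  probes <- tibble::as_tibble(probes)
  cols <- probe_value_cols(probes)
  if (length(cols) < 2L) abort("range filter needs at least 2 samples")
  m <- as.matrix(probes[cols])
  qs <- apply(m, 1L, stats::quantile, probs = c(0.05, 0.95), names = FALSE)
  rng <- qs[2L, ] - qs[1L, ]
  neg <- as.logical(probes$is_negative_control)
  probes[neg | rng >= min_range, , drop = FALSE]
}

#' Collapse replicate probes to gene level
#'
#' Averages the values of all probes mapping to the same gene, per
#' sample. Negative-control probes and probes without a gene mapping are
#' dropped (the latter with a message).
#'
#' @param probes A probe table.
#' @return A gene-by-sample tibble (first column `gene`), rows sorted by
#'   gene.
#' @export
collapse_probes <- function(probes) {
  probes <- tibble::as_tibble(probes)
  cols <- probe_value_cols(probes)
  neg <- as.logical(probes$is_negative_control)
  unmapped <- !neg & (is.na(probes$gene) | !nzchar(as.character(probes$gene)))
  if (any(unmapped)) {
    inform(sprintf("dropping %d probe(s) without a gene mapping", sum(unmapped)))
  }
  kept <- probes[!neg & !unmapped, c("gene", cols)]
  kept |>
    dplyr::group_by(gene = as.character(.data$gene)) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(cols), mean), .groups = "drop") |>
    dplyr::arrange(.data$gene)
}

#' Full microarray preprocessing chain
#'
#' Runs, in fixed order: [normalize_arrays()] (min-shift, log2, quantile
#' mapping), [detection_filter()], [range_filter()], [collapse_probes()].
#' The result is the gene-level expression table consumed by
#' [transcriptogram()].
#'
#' @param raw A raw probe table with positive linear-scale intensities.
#' @param ... Passed on to [detection_filter()].
#' @return A gene-by-sample tibble of normalized log2 expression.
#' @export
preprocess_expression <- function(raw, ...) {
  raw |>
    normalize_arrays() |>
    detection_filter(...) |>
    range_filter() |>
    collapse_probes()
}
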