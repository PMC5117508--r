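# ggplot2 autoplot methods for the main result types.

#' Plot transcriptogram or enrichment profiles
#'
#' One line per sample (when the profile tibble carries a `sample`
#' column) of the windowed value against the relative list position.
#'
#' @param object A `transcriptogram_profile` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.transcriptogram_profile <- function(object, ...) {
  p <- ggplot2::ggplot(tibble::as_tibble(object),
                       ggplot2::aes(x = .data$relative_position,
                                    y = .data$value))
  if ("sample" %in% names(object)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(colour = .data$sample))
  } else {
    p <- p + ggplot2::geom_line()
  }
  p + ggplot2::labs(x = "relative position in ordered list",
                    y = "windowed value") +
    ggplot2::theme_minimal()
}

#' Plot a relative transcriptogram with its significance track
#'
#' Two stacked panels sharing the x axis: the relative transcriptogram
#' `delta` (perturbed / reference class means) with a reference line at
#' 1, and `-log10(P)` of the position-wise Welch tests with a dashed line
#' at P = 0.01.
#'
#' @param object A `class_comparison` tibble.
#' @param p_line P-value reference line. Default 0.01.
#' @param ... Unused.
#' @return A ggplot object (facetted panels).
#' @export
autoplot.class_comparison <- function(object, p_line = 0.01, ...) {
  d <- tibble::as_tibble(object)
  long <- dplyr::bind_rows(
    tibble::tibble(relative_position = d$relative_position,
                   panel = "relative transcriptogram",
                   value = d$delta),
    tibble::tibble(relative_position = d$relative_position,
                   panel = "-log10 P",
                   value = -log10(pmax(d$p_value, .Machine$double.xmin)))
  )
  long$panel <- factor(long$panel,
                       levels = c("relative transcriptogram", "-log10 P"))
  refs <- tibble::tibble(
    panel = factor(c("relative transcriptogram", "-log10 P"),
                   levels = levels(long$panel)),
    yintercept = c(1, -log10(p_line))
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$relative_position,
                                     y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(data = refs,
                        ggplot2::aes(yintercept = .data$yintercept),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$panel), scales = "free_y") +
    ggplot2::labs(x = "relative position in ordered list", y = NULL) +
    ggplot2::theme_minimal()
}

#' Volcano plot
#'
#' `log2` fold change against `-log10(P)`, flagged genes highlighted,
#' with dashed lines at the fold-change and P thresholds.
#'
#' @param object A `volcano_result` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.volcano_result <- function(object, ...) {
  fc_thr <- attr(object, "fc_threshold")
  p_thr <- attr(object, "p_threshold")
  d <- tibble::as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$log2_fc,
                                  y = -log10(pmax(.data$p_value,
                                                  .Machine$double.xmin)),
                                  colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_vline(xintercept = c(-log2(fc_thr), log2(fc_thr)),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::geom_hline(yintercept = -log10(p_thr),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 P",
                  colour = "flagged") +
    ggplot2::theme_minimal()
}

#' Plot association frequency against list distance
#'
#' Diagnostic companion to [association_decay()]: frequency of associated
#' pairs by list distance, on a log y scale when all frequencies are
#' positive.
#'
#' @param decay A tibble from [association_decay()].
#' @return A ggplot object.
#' @export
plot_association_decay <- function(decay) {
  p <- ggplot2::ggplot(decay, ggplot2::aes(x = .data$distance,
                                           y = .data$frequency)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "list distance", y = "association frequency") +
    ggplot2::theme_minimal()
  if (all(decay$frequency > 0)) p <- p + ggplot2::scale_y_log10()
  p
}
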