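#' @noRd
normalize_labels <- function(labels) {
  if (is.data.frame(labels)) {
    if (!all(c("sample", "class") %in% names(labels))) {
      abort("`labels` data frame needs columns `sample` and `class`")
    }
    out <- stats::setNames(as.character(labels$class), as.character(labels$sample))
  } else if (!is.null(names(labels))) {
    out <- stats::setNames(as.character(labels), names(labels))
  } else {
    abort("`labels` must be a sample/class data frame or a named character vector")
  }
  if (anyDuplicated(names(out))) abort("duplicated sample in `labels`")
  out
}

# positions x samples value matrix from a long profile tibble
profile_matrix <- function(profiles) {
  if (!all(c("sample", "position", "value") %in% names(profiles))) {
    abort("`profiles` must be a long transcriptogram tibble (sample, position, value)")
  }
  wide <- tidyr::pivot_wider(
    tibble::as_tibble(profiles)[c("sample", "position", "value")],
    names_from = "sample", values_from = "value"
  )
  wide <- dplyr::arrange(wide, .data$position)
  m <- as.matrix(wide[setdiff(names(wide), "position")])
  rownames(m) <- wide$position
  if (anyNA(m)) abort("profiles do not share a common set of positions")
  m
}

# Row-wise two-sample Welch test: unequal-variance t with
# Welch-Satterthwaite degrees of freedom, two-tailed P. Zero-variance
# rows resolve to P = 1 when the means agree and P = 0 (with a warning)
# when they differ.
welch_rows <- function(X, Y) {
  n1 <- ncol(X); n2 <- ncol(Y)
  if (n1 < 2L || n2 < 2L) abort("each class needs at least 2 samples")
  m1 <- unname(rowMeans(X)); m2 <- unname(rowMeans(Y))
  v1 <- unname(rowSums((X - m1)^2)) / (n1 - 1)
  v2 <- unname(rowSums((Y - m2)^2)) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  stat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(stat), df)
  degenerate <- se2 == 0
  if (any(degenerate)) {
    equal <- degenerate & (m1 == m2)
    p[equal] <- 1; stat[equal] <- 0; df[equal] <- NA_real_
    if (any(degenerate & !equal)) {
      warn("zero within-class variance with differing means; reporting P = 0")
      p[degenerate & !equal] <- 0
      stat[degenerate & !equal] <- sign(m1 - m2)[degenerate & !equal] * Inf
      df[degenerate & !equal] <- NA_real_
    }
  }
  list(mean_x = m1, mean_y = m2,
       se_x = sqrt(v1 / n1), se_y = sqrt(v2 / n2),
       statistic = stat, df = df, p_value = p)
}

resolve_classes <- function(lab, class_p, class_r) {
  classes <- unique(unname(lab))
  if (is.null(class_p) || is.null(class_r)) {
    if (length(classes) != 2L) {
      abort("specify `class_p` and `class_r` when labels hold more than two classes")
    }
    class_p <- class_p %||% classes[1L]
    class_r <- class_r %||% setdiff(classes, class_p)[1L]
  }
  for (cl in c(class_p, class_r)) {
    if (sum(lab == cl) < 2L) {
      abort(sprintf("class '%s' needs at least 2 samples", cl))
    }
  }
  list(p = class_p, r = class_r)
}

split_matrix <- function(profiles, labels, class_p, class_r) {
  lab <- normalize_labels(labels)
  cls <- resolve_classes(lab, class_p, class_r)
  m <- profile_matrix(profiles)
  missing <- setdiff(colnames(m), names(lab))
  if (length(missing)) {
    abort(paste0("labels missing for sample(s): ", paste(missing, collapse = ", ")))
  }
  list(X = m[, names(lab)[lab == cls$p & names(lab) %in% colnames(m)], drop = FALSE],
       Y = m[, names(lab)[lab == cls$r & names(lab) %in% colnames(m)], drop = FALSE],
       positions = as.integer(rownames(m)),
       class_p = cls$p, class_r = cls$r)
}

#' Position-wise Welch tests between two sample classes
#'
#' At every list position, tests the difference of class mean
#' transcriptogram values with a two-sample unequal-variance t statistic
#' (Welch-Satterthwaite degrees of freedom) and a two-tailed P value.
#' Adjacent positions share most of their window, so neighbouring P
#' values are strongly dependent; significance across the list is
#' controlled with [permutation_fdr()], not a per-position Bonferroni
#' correction.
#'
#' @param profiles Long transcriptogram tibble from [transcriptogram()]
#'   covering samples of both classes.
#' @param labels Sample class labels: a `sample`/`class` data frame or a
#'   named character vector.
#' @param class_p,class_r The perturbed and reference class names. May be
#'   omitted when `labels` holds exactly two classes.
#' @return A tibble with columns `position`, `statistic`, `df`, `p_value`.
#' @export
positionwise_welch <- function(profiles, labels, class_p = NULL,
                               class_r = NULL) {
  s <- split_matrix(profiles, labels, class_p, class_r)
  w <- welch_rows(s$X, s$Y)
  tibble::tibble(position = s$positions, statistic = w$statistic,
                 df = w$df, p_value = w$p_value)
}

#' Relative transcriptogram between two classes
#'
#' Averages the per-sample transcriptograms within each class, divides
#' the perturbed class mean by the reference class mean position-wise
#' (`delta[i] = mean_P[i] / mean_R[i]`), and attaches standard-error
#' profiles and the position-wise Welch P values. Regions with `delta`
#' well above or below 1 mark coordinated expression differences.
#'
#' @inheritParams positionwise_welch
#' @return A `class_comparison` tibble with columns `position`,
#'   `relative_position`, `mean_p`, `se_p`, `mean_r`, `se_r`, `delta`,
#'   `p_value`; attributes `class_p`, `class_r`, `n_p`, `n_r`.
#' @export
relative_transcriptogram <- function(profiles, labels, class_p = NULL,
                                     class_r = NULL) {
  s <- split_matrix(profiles, labels, class_p, class_r)
  w <- welch_rows(s$X, s$Y)
  if (any(w$mean_y == 0)) {
    abort(sprintf("reference class mean is zero at list position %d; Delta undefined",
                  s$positions[which(w$mean_y == 0)[1L]]))
  }
  n_genes <- attr(profiles, "n_genes") %||% max(s$positions)
  out <- tibble::tibble(
    position = s$positions,
    relative_position = s$positions / n_genes,
    mean_p = w$mean_x, se_p = w$se_x,
    mean_r = w$mean_y, se_r = w$se_y,
    delta = w$mean_x / w$mean_y,
    p_value = w$p_value
  )
  tibble::new_tibble(out, class_p = s$class_p, class_r = s$class_r,
                     n_p = ncol(s$X), n_r = ncol(s$Y),
                     radius = attr(profiles, "radius"),
                     n_genes = attr(profiles, "n_genes"),
                     class = "class_comparison")
}

#' Permutation-based FDR for position-wise Welch tests
#'
#' Estimates, for each P-value cutoff, the false discovery rate of the
#' position-wise comparison by permuting the sample labels. Each
#' permutation reassigns the class labels uniformly at random while
#' preserving class sizes (sampled with replacement over all label
#' arrangements, the identity included); the FDR at cutoff `p*` is the
#' mean permutation count of positions with `P <= p*` divided by the
#' observed count. `NA` is reported where the observed count is zero.
#'
#' With triplicate designs only 20 distinct 3-vs-3 arrangements exist, so
#' large `n_perm` values resample the same arrangements; the default of
#' 500 draws is retained for comparability across designs.
#'
#' @inheritParams positionwise_welch
#' @param thresholds P-value cutoffs at which to estimate the FDR.
#' @param n_perm Number of label permutations. Default 500.
#' @param seed Integer seed for the permutation draws.
#' @return An `fdr_table` tibble with columns `threshold`, `n_observed`,
#'   `expected_false`, `fdr`.
#' @export
permutation_fdr <- function(profiles, labels, class_p = NULL, class_r = NULL,
                            thresholds = c(0.1, 0.05, 0.01, 0.005, 0.001,
                                           0.0005, 0.0001, 0.00005),
                            n_perm = 500L, seed = 1L) {
  if (n_perm < 1L) abort("`n_perm` must be >= 1")
  lab <- normalize_labels(labels)
  cls <- resolve_classes(lab, class_p, class_r)
  m <- profile_matrix(profiles)
  lab <- lab[colnames(m)]
  if (anyNA(lab)) abort("labels missing for some profiled samples")
  use <- lab %in% c(cls$p, cls$r)
  m <- m[, use, drop = FALSE]
  lab <- lab[use]

  obs_p <- welch_rows(m[, lab == cls$p, drop = FALSE],
                      m[, lab == cls$r, drop = FALSE])$p_value
  n_obs <- vapply(thresholds, function(t) sum(obs_p <= t), numeric(1))

  perm_counts <- local_seeded(as.integer(seed), {
    vapply(seq_len(n_perm), function(b) {
      pl <- sample(lab)
      p <- welch_rows(m[, pl == cls$p, drop = FALSE],
                      m[, pl == cls$r, drop = FALSE])$p_value
      vapply(thresholds, function(t) sum(p <= t), numeric(1))
    }, numeric(length(thresholds)))
  })
  expected_false <- rowMeans(matrix(perm_counts, nrow = length(thresholds)))

  out <- tibble::tibble(
    threshold = thresholds,
    n_observed = as.integer(n_obs),
    expected_false = expected_false,
    fdr = ifelse(n_obs == 0, NA_real_, expected_false / n_obs)
  )
  tibble::new_tibble(out, class_p = cls$p, class_r = cls$r,
                     n_permutations = as.integer(n_perm),
                     class = "fdr_table")
}

#' Single-gene volcano analysis
#'
#' Per-gene fold change and Welch P value between two classes. On the
#' default `log2` scale the fold change is `2^(mean_a - mean_b)` (the
#' linear-scale ratio of class averages); on the `linear` scale it is the
#' direct ratio of class means, which must be positive. A gene is flagged
#' significant when the fold change exceeds the threshold in either
#' direction (`FC > thr` or `FC < 1/thr`) and `P < p_threshold`; the
#' defaults are FC > 2 and P < 0.01.
#'
#' @param expression Gene-by-sample data frame (first column `gene`).
#' @param labels Sample class labels, as in [positionwise_welch()].
#' @param class_a,class_b Classes to compare (`FC = class_a / class_b`).
#' @param fc_threshold Fold-change threshold (> 1). Default 2.
#' @param p_threshold P-value threshold. Default 0.01.
#' @param expression_scale `"log2"` (default) if the expression values are
#'   log2 intensities, `"linear"` otherwise.
#' @return A `volcano_result` tibble with columns `gene`, `mean_a`,
#'   `mean_b`, `fold_change`, `log2_fc`, `p_value`, `significant`.
#' @export
volcano <- function(expression, labels, class_a = NULL, class_b = NULL,
                    fc_threshold = 2, p_threshold = 0.01,
                    expression_scale = c("log2", "linear")) {
  expression_scale <- match.arg(expression_scale)
  if (fc_threshold <= 1) abort("`fc_threshold` must exceed 1")
  expression <- as.data.frame(expression, stringsAsFactors = FALSE)
  gene_col <- if ("gene" %in% names(expression)) "gene" else names(expression)[1L]
  genes <- as.character(expression[[gene_col]])
  lab <- normalize_labels(labels)
  cls <- resolve_classes(lab, class_a, class_b)
  sample_cols <- intersect(names(lab), setdiff(names(expression), gene_col))
  m <- as.matrix(expression[sample_cols])
  lab <- lab[sample_cols]

  w <- welch_rows(m[, lab == cls$p, drop = FALSE],
                  m[, lab == cls$r, drop = FALSE])
  if (expression_scale == "log2") {
    log2_fc <- w$mean_x - w$mean_y
    fc <- 2^log2_fc
  } else {
    if (any(w$mean_x <= 0) || any(w$mean_y <= 0)) {
      abort("non-positive class mean on the ratio scale; supply positive linear-scale intensities (or use expression_scale = \"log2\")")
    }
    fc <- w$mean_x / w$mean_y
    log2_fc <- log2(fc)
  }
  out <- tibble::tibble(
    gene = genes,
    mean_a = w$mean_x, mean_b = w$mean_y,
    fold_change = fc, log2_fc = log2_fc,
    p_value = w$p_value,
    significant = (fc > fc_threshold | fc < 1 / fc_threshold) &
      w$p_value < p_threshold
  )
  tibble::new_tibble(out, class_a = cls$p, class_b = cls$r,
                     fc_threshold = fc_threshold, p_threshold = p_threshold,
                     expression_scale = expression_scale,
                     class = "volcano_result")
}

#' Gene-set mean-expression comparison between classes
#'
#' For each gene set, averages expression over the member genes within
#' each sample, then compares classes with two-tailed Welch tests on the
#' per-sample set means. Significance tiers follow the usual single/double
#' asterisk convention (P < 0.05, P < 0.01).
#'
#' @param expression Gene-by-sample data frame (first column `gene`).
#' @param labels Sample class labels.
#' @param gene_sets A named list of character vectors (as read by
#'   [read_gmt()]), or a single character vector treated as one set.
#' @param classes Optional character vector restricting/ordering the
#'   classes; all pairwise comparisons among them are reported.
#' @return A `gene_set_result` tibble, one row per set and class pair:
#'   `set`, `n_genes`, `class_a`, `class_b`, `mean_a`, `se_a`, `mean_b`,
#'   `se_b`, `p_value`, `significance` (`""`, `"*"`, `"**"`).
#' @export
gene_set_comparison <- function(expression, labels, gene_sets,
                                classes = NULL) {
  if (!is.list(gene_sets)) gene_sets <- list(gene_set = gene_sets)
  if (is.null(names(gene_sets)) || any(!nzchar(names(gene_sets)))) {
    abort("`gene_sets` must be a named list")
  }
  expression <- as.data.frame(expression, stringsAsFactors = FALSE)
  gene_col <- if ("gene" %in% names(expression)) "gene" else names(expression)[1L]
  genes <- as.character(expression[[gene_col]])
  lab <- normalize_labels(labels)
  sample_cols <- intersect(names(lab), setdiff(names(expression), gene_col))
  m <- as.matrix(expression[sample_cols])
  lab <- lab[sample_cols]
  classes <- classes %||% unique(unname(lab))
  if (length(classes) < 2L) abort("need at least two classes to compare")

  rows <- purrr::imap_dfr(gene_sets, function(members, set_name) {
    in_set <- genes %in% members
    if (!any(in_set)) {
      abort(sprintf("gene set '%s' has no gene in the expression table", set_name))
    }
    set_means <- colMeans(m[in_set, , drop = FALSE])  # one value per sample
    pairs <- utils::combn(classes, 2L)
    purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
      a <- pairs[1L, k]; b <- pairs[2L, k]
      xa <- set_means[lab == a]; xb <- set_means[lab == b]
      if (length(xa) < 2L || length(xb) < 2L) {
        abort(sprintf("class '%s' or '%s' has fewer than 2 samples",
                      a, b))
      }
      ht <- stats::t.test(xa, xb, var.equal = FALSE)
      tibble::tibble(
        set = set_name, n_genes = sum(in_set),
        class_a = a, class_b = b,
        mean_a = mean(xa), se_a = stats::sd(xa) / sqrt(length(xa)),
        mean_b = mean(xb), se_b = stats::sd(xb) / sqrt(length(xb)),
        p_value = unname(ht$p.value),
        significance = if (ht$p.value < 0.01) "**"
          else if (ht$p.value < 0.05) "*" else ""
      )
    })
  })
  tibble::new_tibble(rows, class = "gene_set_result")
}
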