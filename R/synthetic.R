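# Synthetic benchmark generators: planted-partition interaction networks,
# module-based gene-set annotations, replicate expression with planted
# class effects, and raw probe tables for the preprocessing chain. Every
# generator is fully determined by (arguments, seed) and returns its
# ground truth for closed-loop tests.

#' Generate a modular interaction network with edge confidences
#'
#' Draws a planted-partition graph: within-module gene pairs are linked
#' with probability `p_in`, between-module pairs with `p_out`. Each edge
#' receives a confidence score drawn uniformly from the within- or
#' between-module range, so thresholding at `min_confidence` retains most
#' within-module and few between-module edges. Genes left isolated after
#' thresholding are re-wired to a random partner in their module with an
#' above-threshold confidence, guaranteeing degree >= 1.
#'
#' @param n_modules Number of planted modules. Default 4.
#' @param module_size Genes per module. Default 60.
#' @param p_in,p_out Within/between-module edge probabilities
#'   (`p_in > p_out`).
#' @param conf_within,conf_between Uniform confidence ranges for within-
#'   and between-module edges. Defaults `c(0.85, 0.999)` and
#'   `c(0.40, 0.95)` produce realistic leakage across a 0.8 threshold.
#' @param min_confidence Threshold used for the degree guarantee and the
#'   ground-truth edge count. Default 0.8.
#' @param seed Integer seed.
#' @return A list with `edges` (tibble `gene_a`, `gene_b`, `confidence`)
#'   and `truth` (list: `membership` named integer vector,
#'   `n_above_threshold`, `modules` list of gene vectors, the parameters
#'   and seed).
#' @export
generate_network <- function(n_modules = 4L, module_size = 60L,
                             p_in = 0.9, p_out = 0.02,
                             conf_within = c(0.85, 0.999),
                             conf_between = c(0.40, 0.95),
                             min_confidence = 0.8, seed = 1L) {
  if (module_size < 2L || n_modules < 1L) abort("module sizes must be >= 2")
  if (!(p_in > p_out)) abort("`p_in` must exceed `p_out`")
  n <- n_modules * module_size
  width <- max(3L, nchar(as.character(n)))
  genes <- sprintf(paste0("g%0", width, "d"), seq_len(n))
  membership <- stats::setNames(rep(seq_len(n_modules), each = module_size), genes)

  local_seeded(as.integer(seed), {
    pair_i <- rep(seq_len(n - 1L), times = (n - 1L):1L)
    pair_j <- unlist(lapply(seq_len(n - 1L), function(i) (i + 1L):n))
    same <- membership[pair_i] == membership[pair_j]
    p_edge <- ifelse(same, p_in, p_out)
    drawn <- stats::runif(length(p_edge)) < p_edge
    ei <- pair_i[drawn]; ej <- pair_j[drawn]; within <- same[drawn]
    conf <- numeric(length(ei))
    conf[within] <- stats::runif(sum(within), conf_within[1L], conf_within[2L])
    conf[!within] <- stats::runif(sum(!within), conf_between[1L], conf_between[2L])

    # degree >= 1 above threshold: re-wire isolated genes inside their module
    deg <- tabulate(c(ei[conf > min_confidence], ej[conf > min_confidence]), n)
    iso <- which(deg == 0L)
    for (g in iso) {
      partners <- setdiff(which(membership == membership[g]), g)
      p <- partners[sample.int(length(partners), 1L)]
      ei <- c(ei, min(g, p)); ej <- c(ej, max(g, p)); within <- c(within, TRUE)
      conf <- c(conf, stats::runif(1L, max(conf_within[1L], min_confidence + 1e-6),
                                   conf_within[2L]))
    }

    edges <- tibble::tibble(
      gene_a = genes[ei], gene_b = genes[ej], confidence = conf
    ) |>
      dplyr::group_by(.data$gene_a, .data$gene_b) |>
      dplyr::summarise(confidence = max(.data$confidence), .groups = "drop")

    truth <- list(
      membership = membership,
      modules = split(genes, membership),
      n_above_threshold = sum(edges$confidence > min_confidence),
      within_module = unname(membership[edges$gene_a] == membership[edges$gene_b]),
      params = list(n_modules = n_modules, module_size = module_size,
                    p_in = p_in, p_out = p_out,
                    conf_within = conf_within, conf_between = conf_between,
                    min_confidence = min_confidence),
      seed = as.integer(seed)
    )
    list(edges = edges, truth = truth)
  })
}

#' Generate gene-set annotations from the planted modules
#'
#' One gene set per planted module, standing in for KEGG-pathway/GO-term
#' membership. With `super_terms = TRUE`, additional sets spanning each
#' pair of consecutive modules are appended.
#'
#' @param truth The `truth` element returned by [generate_network()].
#' @param super_terms Also emit two-module "super terms". Default FALSE.
#' @return A named list of character vectors (the format of
#'   [read_gmt()]).
#' @export
generate_annotations <- function(truth, super_terms = FALSE) {
  mods <- truth$modules
  sets <- stats::setNames(mods, sprintf("module_%02d", seq_along(mods)))
  if (super_terms && length(mods) >= 2L) {
    for (k in seq_len(length(mods) - 1L)) {
      sets[[sprintf("super_%02d_%02d", k, k + 1L)]] <-
        c(mods[[k]], mods[[k + 1L]])
    }
  }
  lapply(sets, unname)
}

#' Generate replicate expression with planted module effects
#'
#' Emulates a triplicate two-or-more-class design on the log2 scale:
#' `value = baseline + log2-effect(class, module) + N(0, noise_sd)`.
#' Effects are multiplicative on the linear scale and specified as log2
#' shifts of whole planted modules in specific classes.
#'
#' @param truth The `truth` element of [generate_network()].
#' @param classes Character class names. Default `c("R", "P")`
#'   (reference, perturbed).
#' @param n_replicates Samples per class (>= 2). Default 3, the
#'   triplicate design.
#' @param baseline Baseline log2 intensity. Default 8.
#' @param effects `NULL` (no planted effect) or a data frame with columns
#'   `class`, `module`, `log2_effect`.
#' @param noise_sd Standard deviation of i.i.d. Gaussian noise on the
#'   log2 scale. Default 0.25.
#' @param seed Integer seed.
#' @return A list with `expression` (tibble `gene` + one column per
#'   sample, named `<class>_<rep>`), `labels` (tibble `sample`, `class`)
#'   and `effects` (the planted effect table, zero-filled).
#' @export
generate_expression <- function(truth, classes = c("R", "P"),
                                n_replicates = 3L, baseline = 8,
                                effects = NULL, noise_sd = 0.25,
                                seed = 1L) {
  if (n_replicates < 2L) abort("`n_replicates` must be >= 2")
  genes <- names(truth$membership)
  modules <- unname(truth$membership)
  samples <- as.vector(t(outer(classes, seq_len(n_replicates),
                               function(c, k) paste0(c, "_", k))))
  sample_class <- rep(classes, each = n_replicates)

  eff <- matrix(0, nrow = max(modules), ncol = length(classes),
                dimnames = list(NULL, classes))
  if (!is.null(effects)) {
    effects <- as.data.frame(effects)
    if (!all(c("class", "module", "log2_effect") %in% names(effects))) {
      abort("`effects` needs columns class, module, log2_effect")
    }
    for (k in seq_len(nrow(effects))) {
      eff[effects$module[k], as.character(effects$class[k])] <-
        effects$log2_effect[k]
    }
  }

  vals <- local_seeded(as.integer(seed), {
    mu <- baseline + eff[modules, sample_class, drop = FALSE]
    mu + matrix(stats::rnorm(length(genes) * length(samples), 0, noise_sd),
                nrow = length(genes))
  })
  colnames(vals) <- samples

  list(
    expression = dplyr::bind_cols(tibble::tibble(gene = genes),
                                  tibble::as_tibble(as.data.frame(vals))),
    labels = tibble::tibble(sample = samples, class = sample_class),
    effects = eff
  )
}

#' Generate a raw probe-intensity table from a gene-level expression set
#'
#' Expands each gene into `probes_per_gene` replicate probes with a
#' per-probe log2 offset, adds negative-control probes drawn near
#' background, optionally plants a fraction of gene probes well below the
#' implied limit of detection, and returns linear-scale intensities
#' (`2^log2value`) ready for [preprocess_expression()].
#'
#' @param expression Gene-by-sample tibble (log2 scale), e.g. from
#'   [generate_expression()].
#' @param probes_per_gene Replicate probes per gene (>= 1). Default 3.
#' @param n_negative_controls Number of negative-control probes.
#'   Default 50.
#' @param below_lod_fraction Fraction of gene probes re-drawn below the
#'   limit of detection. Default 0.
#' @param background_mean,background_sd Log2 mean and sd of the
#'   negative-control intensities. Defaults 4 and 0.3.
#' @param probe_jitter_sd Sd of the per-probe log2 offset. Default 0.1.
#' @param seed Integer seed.
#' @return A list with `probes` (tibble `probe`, `is_negative_control`,
#'   `gene`, samples; linear intensities) and `truth` (list:
#'   `below_lod_probes`, `probe_to_gene`).
#' @export
generate_raw_probes <- function(expression, probes_per_gene = 3L,
                                n_negative_controls = 50L,
                                below_lod_fraction = 0,
                                background_mean = 4, background_sd = 0.3,
                                probe_jitter_sd = 0.1, seed = 1L) {
  if (probes_per_gene < 1L) abort("`probes_per_gene` must be >= 1")
  expression <- as.data.frame(expression, stringsAsFactors = FALSE)
  gene_col <- if ("gene" %in% names(expression)) "gene" else names(expression)[1L]
  genes <- as.character(expression[[gene_col]])
  cols <- setdiff(names(expression), gene_col)
  vals <- as.matrix(expression[cols])

  local_seeded(as.integer(seed), {
    gidx <- rep(seq_along(genes), each = probes_per_gene)
    probe_ids <- paste0(genes[gidx], "_p", rep(seq_len(probes_per_gene),
                                               times = length(genes)))
    offset <- stats::rnorm(length(probe_ids), 0, probe_jitter_sd)
    lg <- vals[gidx, , drop = FALSE] + offset

    n_low <- floor(below_lod_fraction * length(probe_ids))
    below <- character(0)
    if (n_low > 0L) {
      pick <- sample(seq_along(probe_ids), n_low)
      below <- probe_ids[pick]
      # well under LoD = background_mean + 1.96 * background_sd
      lg[pick, ] <- matrix(stats::rnorm(n_low * ncol(lg),
                                        background_mean - 1.5, 0.1),
                           nrow = n_low)
    }

    neg_ids <- sprintf("NEG_%03d", seq_len(n_negative_controls))
    neg <- matrix(stats::rnorm(n_negative_controls * ncol(lg),
                               background_mean, background_sd),
                  nrow = n_negative_controls)

    intensities <- rbind(2^lg, 2^neg)
    colnames(intensities) <- cols
    probes <- dplyr::bind_cols(
      tibble::tibble(
        probe = c(probe_ids, neg_ids),
        is_negative_control = c(rep(FALSE, length(probe_ids)),
                                rep(TRUE, n_negative_controls)),
        gene = c(genes[gidx], rep(NA_character_, n_negative_controls))
      ),
      tibble::as_tibble(as.data.frame(intensities))
    )
    list(
      probes = probes,
      truth = list(
        below_lod_probes = sort(below),
        probe_to_gene = tibble::tibble(probe = probe_ids, gene = genes[gidx])
      )
    )
  })
}
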