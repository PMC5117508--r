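# Shared fixtures and independent oracles. The oracles deliberately use
# plain double loops / stats::t.test so they share no code with the
# implementation they check.

# direct double-loop evaluation of the neighbourhood cost on an
# association matrix already in list order
naive_cost <- function(A, alpha = 1) {
  N <- nrow(A)
  total <- 0
  for (i in seq_len(N - 1)) {
    for (j in (i + 1):N) {
      s <- 0
      if (i + 1 <= N) s <- s + abs(A[i, j] - A[i + 1, j])
      if (i - 1 >= 1) s <- s + abs(A[i, j] - A[i - 1, j])
      if (j + 1 <= N) s <- s + abs(A[i, j] - A[i, j + 1])
      if (j - 1 >= 1) s <- s + abs(A[i, j] - A[i, j - 1])
      total <- total + abs(i - j)^alpha * s
    }
  }
  total
}

# windowed mean by explicit per-position summation
naive_smooth <- function(x, r) {
  n <- length(x)
  positions <- (r + 1):(n - r)
  vapply(positions, function(i) mean(x[(i - r):(i + r)]), numeric(1))
}

path_edges <- function(n, prefix = "g") {
  tibble::tibble(gene_a = paste0(prefix, seq_len(n - 1)),
                 gene_b = paste0(prefix, 2:n),
                 confidence = 0.9)
}

complete_edges <- function(n, prefix = "g") {
  pairs <- t(utils::combn(n, 2))
  tibble::tibble(gene_a = paste0(prefix, pairs[, 1]),
                 gene_b = paste0(prefix, pairs[, 2]),
                 confidence = 0.9)
}

# Erdos-Renyi G(n, p) edge table; re-drawn until no isolated gene so the
# loader keeps all n genes
gnp_edges <- function(n, p, seed, prefix = "x") {
  genes <- sprintf("%s%02d", prefix, seq_len(n))
  set.seed(seed)
  repeat {
    pairs <- t(utils::combn(n, 2))
    drawn <- stats::runif(nrow(pairs)) < p
    if (all(seq_len(n) %in% c(pairs[drawn, 1], pairs[drawn, 2]))) {
      return(tibble::tibble(gene_a = genes[pairs[drawn, 1]],
                            gene_b = genes[pairs[drawn, 2]],
                            confidence = 0.9))
    }
  }
}

# connected components by breadth-first search over an edge table
components_bfs <- function(genes, edge_a, edge_b) {
  comp <- stats::setNames(rep(NA_integer_, length(genes)), genes)
  nb <- split(c(edge_b, edge_a), c(edge_a, edge_b))
  k <- 0L
  for (g in genes) {
    if (!is.na(comp[g])) next
    k <- k + 1L
    queue <- g
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      if (!is.na(comp[v])) next
      comp[v] <- k
      queue <- c(queue, setdiff(nb[[v]], names(comp)[!is.na(comp)]))
    }
  }
  comp
}

# long profile tibble from a positions x samples matrix, for feeding the
# differential stage directly
profiles_from_matrix <- function(m, positions = seq_len(nrow(m))) {
  out <- purrr::map_dfr(colnames(m), function(s) {
    tibble::tibble(sample = s, position = positions,
                   relative_position = positions / max(positions),
                   value = m[, s])
  })
  out
}

# compact anneal schedule used by tests on small/medium networks
test_schedule <- function(n_restarts = 1L) {
  anneal_schedule(n_levels = 60L, steps_per_level = 15L,
                  n_restarts = n_restarts)
}

# all permutations of a small vector (recursive; for oracle enumeration)
combinat_perms <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (k in seq_along(x)) {
    out <- c(out, lapply(combinat_perms(x[-k]), function(p) c(x[k], p)))
  }
  out
}
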