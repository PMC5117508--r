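test_that("cost function matches the naive double-loop oracle", {
  # single edge, N = 2: the one pair is compared against its two in-range
  # neighbours (both diagonal zeros)
  net2 <- load_interactions(tibble::tibble(gene_a = "a", gene_b = "b",
                                           confidence = 0.9))
  A <- association_matrix(net2, c("a", "b"))
  expect_equal(cost_function(net2, c("a", "b")), naive_cost(A))

  # random graphs, random orders, several alphas
  for (seed in 1:5) {
    net <- load_interactions(gnp_edges(9, 0.35, seed = seed))
    set.seed(seed + 100)
    ord <- sample(net$genes)
    for (alpha in c(0, 0.5, 1, 2)) {
      expect_equal(cost_function(net, ord, alpha),
                   naive_cost(association_matrix(net, ord), alpha))
    }
  }
})

test_that("complete-graph cost is identical for every permutation", {
  net <- load_interactions(complete_edges(4))
  perms <- combinat_perms(net$genes)
  costs <- vapply(perms, function(o) cost_function(net, o), numeric(1))
  expect_equal(max(costs) - min(costs), 0)
})

test_that("cost is invariant under order reversal", {
  for (seed in 1:5) {
    net <- load_interactions(gnp_edges(10, 0.3, seed = seed + 20))
    set.seed(seed)
    ord <- sample(net$genes)
    expect_equal(cost_function(net, ord), cost_function(net, rev(ord)))
  }
})

test_that("incremental swap cost matches full recomputation", {
  net <- load_interactions(gnp_edges(12, 0.3, seed = 42))
  set.seed(9)
  st <- ordering_state(net, sample(net$genes))
  for (k in 1:100) {
    ab <- sample(net$n_genes, 2)
    d <- delta_cost_swap(st, ab[1], ab[2])
    swapped <- st$order
    swapped[ab] <- swapped[rev(ab)]
    full <- cost_function(net, swapped) - st$cost
    expect_equal(d, full, tolerance = 1e-9)
  }
})

test_that("swapping back cancels exactly and K4 swaps are free", {
  net <- load_interactions(gnp_edges(10, 0.4, seed = 5))
  set.seed(3)
  st <- ordering_state(net, sample(net$genes))
  d1 <- delta_cost_swap(st, 2, 7)
  swapped <- st$order
  swapped[c(2, 7)] <- swapped[c(7, 2)]
  st2 <- ordering_state(net, swapped)
  d2 <- delta_cost_swap(st2, 2, 7)
  expect_equal(d1 + d2, 0)

  k4 <- load_interactions(complete_edges(4))
  stk <- ordering_state(k4, k4$genes)
  expect_equal(delta_cost_swap(stk, 1, 3), 0)
  expect_error(delta_cost_swap(stk, 2, 2), "differ")
  expect_error(delta_cost_swap(stk, 0, 2), "1..N")
})

test_that("exhaustive search returns the enumeration minimum with lexicographic ties", {
  net <- load_interactions(path_edges(3))
  ex <- exhaustive_order(net)
  perms <- combinat_perms(sort(net$genes))
  costs <- vapply(perms, function(o) naive_cost(association_matrix(net, o)),
                  numeric(1))
  expect_equal(ex$cost, min(costs))
  expect_identical(ex$order, perms[[which.min(costs)]])

  # all orders tie on a single edge; lexicographically smallest returned
  pair <- load_interactions(tibble::tibble(gene_a = "b", gene_b = "a",
                                           confidence = 0.9))
  expect_equal(exhaustive_order(pair)$order, c("a", "b"))

  big <- load_interactions(gnp_edges(11, 0.5, seed = 1))
  expect_error(exhaustive_order(big), "more than 10")
})

test_that("exhaustive search agrees with an R-level enumeration", {
  net <- load_interactions(gnp_edges(5, 0.5, seed = 8))
  perms <- combinat_perms(net$genes)
  costs <- vapply(perms, function(o) cost_function(net, o), numeric(1))
  expect_equal(exhaustive_order(net)$cost, min(costs))
})

test_that("annealing is deterministic and finds the P6 exhaustive minimum", {
  net <- load_interactions(path_edges(6))
  sch <- anneal_schedule(t_initial = 5, t_decrement = 0.05,
                         steps_per_level = 100, n_restarts = 5)
  a1 <- anneal(net, sch, seed = 42)
  a2 <- anneal(net, sch, seed = 42)
  expect_identical(a1$order, a2$order)
  expect_identical(a1$cost, a2$cost)
  expect_equal(a1$cost, exhaustive_order(net)$cost)
})

test_that("annealing matches exhaustive search on a two-triangle bridge graph", {
  tri <- tibble::tibble(
    gene_a = c("a1", "a1", "a2", "b1", "b1", "b2", "a3"),
    gene_b = c("a2", "a3", "a3", "b2", "b3", "b3", "b1"),
    confidence = 0.9
  )
  net <- load_interactions(tri)
  expect_equal(net$n_genes, 6L)
  an <- anneal(net, test_schedule(n_restarts = 10L), seed = 1)
  expect_equal(an$cost, exhaustive_order(net)$cost)
})

test_that("the running-minimum cost trace never increases", {
  net <- load_interactions(gnp_edges(15, 0.25, seed = 13))
  an <- anneal(net, test_schedule(), seed = 2)
  tr <- an$trace$best_cost
  expect_true(all(diff(tr) <= 0))
  # the returned state is at least as good as any traced level
  expect_lte(an$cost, min(tr))
})

test_that("annealing clusters planted modules into contiguous blocks", {
  g <- generate_network(n_modules = 4L, module_size = 15L,
                        p_in = 0.9, p_out = 0.02, seed = 1L)
  net <- load_interactions(g$edges, 0.8)
  an <- anneal(net, test_schedule(), seed = 5)
  mem <- g$truth$membership[an$order]
  spread <- mean(tapply(seq_along(mem), mem, stats::sd))
  set.seed(99)
  null_spread <- replicate(1000, {
    o <- sample(names(g$truth$membership))
    mean(tapply(seq_along(o), g$truth$membership[o], stats::sd))
  })
  expect_lt(spread, mean(null_spread))
})

test_that("association frequency decays with list distance after ordering", {
  # random labelling of G(n, p): frequency approximately p at all distances
  g <- gnp_edges(40, 0.3, seed = 21)
  net <- load_interactions(g)
  dec <- association_decay(ordering_state(net, net$genes),
                           max_distance = 39L)
  expect_true(all(dec$frequency >= 0 & dec$frequency <= 1))
  expect_equal(dec$n_pairs[1], net$n_genes - 1L)
  expect_equal(mean(dec$frequency[1:10]), 0.3, tolerance = 0.25)

  # annealed modular network: near-diagonal association much richer than
  # mid-range
  gm <- generate_network(n_modules = 4L, module_size = 20L, seed = 2L)
  netm <- load_interactions(gm$edges, 0.8)
  an <- anneal(netm, test_schedule(), seed = 3)
  dec2 <- association_decay(an, max_distance = 60L)
  expect_gt(mean(dec2$frequency[dec2$distance <= 5]),
            mean(dec2$frequency[dec2$distance >= 30]))
})

test_that("ordered lists round-trip through TSV", {
  net <- load_interactions(gnp_edges(10, 0.4, seed = 31))
  an <- anneal(net, test_schedule(), seed = 1)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_ordering(an, f)
  back <- read_ordering(f, network = net)
  expect_identical(back$order, an$order)
  expect_equal(back$cost, an$cost)
})
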