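test_that("knn sets rank by ascending consistency with index tie-breaks", {
  omega <- matrix(0, 4, 4)
  omega[1, 2:4] <- c(-0.9, -0.2, 0.5)
  omega[2:4, 1] <- omega[1, 2:4]
  expect_equal(knn_sets(omega, 2)[[1]], c(2L, 3L))
  # k = N - 1 returns every other SNP
  expect_equal(sort(knn_sets(omega, 3)[[1]]), 2:4)
  # tie at the k-th rank: lower index wins
  omega2 <- matrix(0, 4, 4)
  omega2[1, 2:4] <- c(-0.5, -0.5, -0.5)
  expect_equal(knn_sets(omega2, 2)[[1]], c(2L, 3L))
  expect_warning(knn_sets(omega, 5), "clamped")
})

test_that("mining finds shared-neighbour itemsets with support weights", {
  # mutual triangle: all three augmented transactions equal {1,2,3}
  knn <- list(c(2L, 3L), c(1L, 3L), c(1L, 2L))
  hg <- mine_hyperedges(knn, sc = 2)
  expect_equal(length(hg$edges), 1L)
  expect_equal(hg$edges[[1]], 1:3)
  expect_equal(hg$weights, 3)
  # chained neighbour sets share nothing pairwise: no frequent itemsets
  knn2 <- list(2L, 3L, 4L, 5L, 6L, 1L)
  expect_equal(length(mine_hyperedges(knn2, sc = 2)$edges), 0L)
  # sc = 1: every augmented transaction is contained in some maximal itemset
  set.seed(2)
  knn3 <- lapply(1:6, function(i) sample(setdiff(1:6, i), 2))
  hg3 <- mine_hyperedges(knn3, sc = 1)
  for (i in 1:6) {
    trans <- sort(unique(c(i, knn3[[i]])))
    expect_true(any(vapply(hg3$edges, function(e) all(trans %in% e), TRUE)))
  }
})

test_that("mined hyperedges are maximal and support-consistent", {
  set.seed(13)
  knn <- lapply(1:12, function(i) sample(setdiff(1:12, i), 4))
  trans <- lapply(1:12, function(i) sort(unique(c(i, knn[[i]]))))
  hg <- mine_hyperedges(knn, sc = 2)
  for (k in seq_along(hg$edges)) {
    e <- hg$edges[[k]]
    supp <- sum(vapply(trans, function(t) all(e %in% t), TRUE))
    expect_gte(supp, 2)
    expect_equal(hg$weights[k], supp)
    expect_gte(length(e), 2)
  }
  # no edge contained in another
  if (length(hg$edges) > 1) {
    for (a in seq_along(hg$edges)) for (b in seq_along(hg$edges)) {
      if (a != b) expect_false(all(hg$edges[[a]] %in% hg$edges[[b]]))
    }
  }
})

test_that("partitioning solves the worked example and degenerate cases", {
  hg <- structure(list(n_vertices = 6L,
                       edges = list(1:3, 3:4, 4:6),
                       weights = c(3, 1, 3)),
                  class = "snp_hypergraph")
  bp <- partition_hypergraph(hg, seed = 1)
  expect_equal(bp$cut_weight, 1)
  expect_equal(cut_weight(hg, bp$side), 1)
  expect_setequal(which(bp$side == bp$side[1]), 1:3)
  # disconnected hyperedges split at zero cost
  hg0 <- structure(list(n_vertices = 6L, edges = list(1:3, 4:6),
                        weights = c(2, 5)), class = "snp_hypergraph")
  expect_equal(partition_hypergraph(hg0, seed = 2)$cut_weight, 0)
  # a single spanning hyperedge is cut by every bipartition
  hg1 <- structure(list(n_vertices = 4L, edges = list(1:4), weights = 7),
                   class = "snp_hypergraph")
  expect_equal(partition_hypergraph(hg1, seed = 3)$cut_weight, 7)
})

test_that("FM cut matches the exhaustive minimum on small hypergraphs", {
  hits <- 0
  n_cases <- 40
  for (seed in seq_len(n_cases)) {
    set.seed(seed)
    n <- sample(6:12, 1)
    hg <- random_hypergraph(n, sample(3:6, 1))
    min_side <- max(1L, floor(0.2 * n))
    bp <- partition_hypergraph(hg, balance_floor = 0.2, seed = seed + 100)
    opt <- brute_min_cut(hg, min_side)
    expect_gte(bp$cut_weight, opt - 1e-9)  # heuristic can never beat the optimum
    expect_equal(bp$cut_weight, cut_weight(hg, bp$side))
    if (abs(bp$cut_weight - opt) < 1e-9) hits <- hits + 1
  }
  expect_gte(hits / n_cases, 0.95)
})

test_that("partitioning is deterministic under a fixed seed and balanced", {
  set.seed(77)
  hg <- random_hypergraph(10, 5)
  a <- partition_hypergraph(hg, seed = 5)
  b <- partition_hypergraph(hg, seed = 5)
  expect_identical(a$side, b$side)
  n1 <- sum(a$side == 1)
  expect_gte(min(n1, 10 - n1), max(1, floor(0.2 * 10)))
  expect_true(length(a$cutset) <= 5)
})

test_that("hypergraph components are the zero-cut building blocks", {
  hg <- structure(list(n_vertices = 7L, edges = list(1:2, c(2L, 3L), 5:6),
                       weights = c(1, 1, 1)), class = "snp_hypergraph")
  comps <- hypergraph_components(hg)
  expect_equal(comps, list(1:3, 5:6))
  for (cm in comps) {
    side <- rep(1L, 7); side[cm] <- 2L
    expect_equal(cut_weight(hg, side), 0)
  }
})
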