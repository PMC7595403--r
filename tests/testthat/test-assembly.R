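test_that("diploid CutSet flips complement both rows and keep the pair structure", {
  h <- hap_from_strings("0101", "1010")
  expect_equal(diploid_update(h, integer(0)), h)
  flipped <- diploid_update(h, c(1L, 3L))
  expect_equal(unclass(flipped)[1, ], c(1L, 1L, 1L, 1L))
  expect_equal(unclass(flipped)[2, ], c(0L, 0L, 0L, 0L))
  # flipping every column is a row relabeling: same unordered pair, same MEC
  all_flip <- diploid_update(h, 1:4)
  expect_equal(unclass(all_flip)[1, ], unclass(h)[2, ])
  set.seed(1)
  x <- random_fragment_matrix(8, 4)
  expect_equal(mec(x, all_flip), mec(x, h))
})

test_that("flipping a CutSet or its complement gives the same unordered pair", {
  set.seed(2)
  h1 <- sample(c(0L, 1L), 10, replace = TRUE)
  h <- haplotype_set(rbind(h1, 1L - h1))
  cs <- sample(10, 4)
  a <- diploid_update(h, cs)
  b <- diploid_update(h, setdiff(1:10, cs))
  expect_equal(unclass(a)[1, ], unclass(b)[2, ])
  expect_equal(unclass(a)[2, ], unclass(b)[1, ])
})

test_that("polyploid CutSet update scores all row permutations and never worsens MEC", {
  # triploid toy where swapping rows 1 and 2 inside the cutset fits the fragments
  truth <- hap_from_strings("001100", "110010", "010101")
  wrong <- unclass(truth)
  wrong[c(1, 2), 4:6] <- wrong[c(2, 1), 4:6]  # mis-permuted right half
  wrongh <- haplotype_set(wrong)
  set.seed(3)
  inst <- simulate_fragments(truth, sim_config(3, 6, 12, 0,
                                               fragment_length = c(4, 6),
                                               mate_gap_prob = 0))
  x <- inst$fragments
  m0 <- mec(x, wrongh)
  upd <- polyploid_update(x, wrongh, 4:6)
  expect_lt(mec(x, upd), m0)
  # brute force over all 6 permutations of the cutset block agrees
  best <- Inf
  for (p in all_perms(3)) {
    cand <- unclass(wrongh)
    cand[, 4:6] <- cand[p, 4:6]
    best <- min(best, mec(x, haplotype_set(cand)))
  }
  expect_equal(mec(x, upd), best)
  # identity permutation optimal -> unchanged
  expect_equal(unclass(polyploid_update(x, truth, 4:6)), unclass(truth))
  expect_error(polyploid_update(x, haplotype_set(matrix(0L, 7, 6)), 1:2),
               "cap")
})

test_that("pair perturbation is seeded, bounded and never raises MEC", {
  set.seed(4)
  x <- random_fragment_matrix(12, 8)
  h1 <- sample(c(0L, 1L), 8, replace = TRUE)
  h <- haplotype_set(rbind(h1, 1L - h1))
  m0 <- mec(x, h)
  expect_identical(perturb_pairs(x, h, 1:8, nc = 0, seed = 1)$haplotypes, h)
  a <- perturb_pairs(x, h, 1:8, nc = 0.5, seed = 9)
  b <- perturb_pairs(x, h, 1:8, nc = 0.5, seed = 9)
  expect_identical(unclass(a$haplotypes), unclass(b$haplotypes))
  expect_lte(a$mec, m0)
  expect_equal(a$mec, mec(x, a$haplotypes))
})

test_that("fragment blocks partition the columns by co-coverage", {
  x <- frag_from_strings("11---", "-00--", "---11")
  bl <- fragment_blocks(x)
  expect_equal(bl, list(1:3, 4:5))
})

test_that("assembly recovers error-free instances exactly", {
  inst <- simulate_instance(sim_config(2, 100, 10, 0), seed = 51)
  res <- assemble(inst$fragments, ploidy = 2, seed = 52)
  expect_equal(res$mec, 0)
  ev <- evaluate_assembly(res, inst$truth)
  expect_equal(ev$rr, 1.0)
  expect_true(all(diff(res$trace) <= 0))
  expect_equal(res$mec, tail(res$trace, 1))
})

test_that("the accepted-MEC trace is non-increasing and bounded by the start", {
  inst <- simulate_instance(sim_config(2, 80, 5, 0.2), seed = 61)
  res <- assemble(inst$fragments, ploidy = 2, seed = 62)
  expect_true(all(diff(res$trace) <= 0))
  expect_equal(res$mec, mec(remove_homozygous_columns(inst$fragments)$fragments,
                            res$haplotypes))
})

test_that("assembly is reproducible under a fixed seed", {
  inst <- simulate_instance(sim_config(2, 60, 6, 0.1), seed = 71)
  a <- assemble(inst$fragments, ploidy = 2, seed = 72)
  b <- assemble(inst$fragments, ploidy = 2, seed = 72)
  expect_identical(unclass(a$haplotypes), unclass(b$haplotypes))
  expect_identical(a$trace, b$trace)
  expect_identical(a$mec, b$mec)
})

test_that("degenerate inputs are rejected", {
  expect_error(assemble(fragment_matrix(matrix(integer(), 0, 0)), 2), "empty")
  expect_error(assemble(fragment_matrix(matrix(NA_integer_, 3, 4)), 2),
               "empty|all-gap")
})
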