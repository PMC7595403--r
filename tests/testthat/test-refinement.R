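test_that("diploid locus confidence multiplies match/mismatch probabilities", {
  # three fragments all matching at the column: raw emission 0.9^3
  h <- hap_from_strings("00", "11")
  x <- frag_from_strings("00", "00", "00")
  conf <- locus_confidence_diploid(x, h, assign_fragments(x, h),
                                   default_q = 0.1)
  expect_equal(conf$raw[1], 0.9^3)
  expect_gt(conf$posterior[1], 0.99)
  # two matches and one mismatch against the assigned row: 0.9^2 * 0.1
  x2 <- frag_from_strings("00", "00", "01")
  conf2 <- locus_confidence_diploid(x2, h, assign_fragments(x2, h),
                                    default_q = 0.1)
  expect_equal(conf2$raw[2], 0.9^2 * 0.1)
  # uncovered column: empty product 1, posterior 1/2
  x3 <- frag_from_strings("0-", "0-")
  conf3 <- locus_confidence_diploid(x3, h, assign_fragments(x3, h),
                                    default_q = 0.1)
  expect_equal(conf3$raw[2], 1)
  expect_equal(conf3$posterior[2], 0.5)
})

test_that("polyploid loci are flagged by genotype multiset mismatch", {
  h <- haplotype_set(rbind(c(0L, 1L, 0L), c(1L, 1L, 1L), c(1L, 1L, 0L)))
  expect_equal(flag_low_confidence_polyploid(h, c(2L, 2L, 1L)), 2L)
  expect_equal(flag_low_confidence_polyploid(h, c(2L, 3L, 1L)), integer(0))
})

test_that("the chaos-game map follows the midpoint rule and inverts exactly", {
  cs <- cgr_map(rep(1L, 4))
  expect_equal(cs, c(0.75, 0.875, 0.9375, 0.96875))
  expect_equal(cgr_map(c(1L, 0L)), c(0.75, 0.375))
  for (seed in 1:10) {
    set.seed(seed)
    v <- sample(c(0L, 1L), 50, replace = TRUE)
    cs <- cgr_map(v)
    # algebraic inversion and threshold round trip
    prev <- c(0.5, cs[-50])
    expect_equal(2 * cs - prev, as.numeric(v))
    expect_identical(cgr_threshold(cs), v)
  }
})

test_that("local projection fills gaps from delay-embedded neighbours", {
  # exactly periodic series: the neighbours' successors agree
  cs <- rep(c(0.25, 0.75), 6)
  cs[7] <- NA  # original value 0.25
  filled <- local_projection_fill(cs, em = 1, k_lp = 3)
  expect_equal(filled[7], 0.25)
  # constant series
  k <- rep(0.6, 10); k[5] <- NA
  expect_equal(local_projection_fill(k, em = 2, k_lp = 3)[5], 0.6)
  # no missing values: identity
  full <- cgr_map(sample(c(0L, 1L), 20, replace = TRUE))
  expect_identical(local_projection_fill(full, 2, 5), full)
  # too few defined values: unchanged with a warning
  short <- c(0.2, NA, 0.8)
  expect_warning(out <- local_projection_fill(short, 2, 5), "too few")
  expect_identical(out, short)
})

test_that("refinement touches only flagged loci and respects the 0.5 threshold", {
  set.seed(5)
  inst <- simulate_instance(sim_config(2, 60, 12, 0), seed = 5)
  pp <- remove_homozygous_columns(inst$fragments)
  h <- haplotype_set(unclass(inst$truth)[, pp$column_map$kept, drop = FALSE])
  asg <- assign_fragments(pp$fragments, h)
  cfg <- refinement_config(min_length = 10)
  # error-free, consistent haplotypes: nothing is flagged, nothing changes
  out <- refine_haplotypes(h, pp$fragments, asg, config = cfg)
  expect_identical(unclass(out), unclass(h))
  # below min_length the refinement is a pass-through
  cfg2 <- refinement_config(min_length = 10000)
  expect_identical(unclass(refine_haplotypes(h, pp$fragments, asg,
                                             config = cfg2)),
                   unclass(h))
})

test_that("refinement corrects corrupted loci on long haplotypes", {
  set.seed(6)
  inst <- simulate_instance(sim_config(2, 700, 10, 0.1), seed = 6)
  pp <- remove_homozygous_columns(inst$fragments)
  tf <- haplotype_set(unclass(inst$truth)[, pp$column_map$kept, drop = FALSE])
  np <- ncol(tf)
  bad <- sample(np, round(0.08 * np))
  h <- diploid_update(tf, bad)
  asg <- assign_fragments(pp$fragments, h)
  bl <- fragment_blocks(pp$fragments)
  r0 <- reconstruction_rate(tf, h, bl)
  hr <- refine_haplotypes(h, pp$fragments, asg, config = refinement_config())
  expect_gt(reconstruction_rate(tf, hr, bl), r0)
  # unflagged loci are untouched
  conf <- locus_confidence_diploid(pp$fragments, h, asg)
  unflagged <- which(conf$posterior >= 0.9)
  expect_equal(unclass(hr)[1, unflagged], unclass(h)[1, unflagged])
})

test_that("polyploid refinement without a genotype is skipped with a warning", {
  h <- haplotype_set(matrix(sample(c(0L, 1L), 30, replace = TRUE), 3, 10))
  x <- random_fragment_matrix(5, 10)
  expect_warning(
    out <- refine_haplotypes(h, x, assign_fragments(x, h),
                             config = refinement_config(min_length = 2)),
    "genotype")
  expect_identical(unclass(out), unclass(h))
})
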