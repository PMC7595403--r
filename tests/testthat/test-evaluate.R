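test_that("diploid reconstruction rate follows the pairing formula", {
  set.seed(1)
  t1 <- sample(c(0L, 1L), 100, replace = TRUE)
  truth <- haplotype_set(rbind(t1, 1L - t1))
  expect_equal(rr_diploid(truth, truth), 1.0)
  swapped <- haplotype_set(unclass(truth)[2:1, ])
  expect_equal(rr_diploid(truth, swapped), 1.0)
  # one site wrong in both rows under the best pairing: 1 - 2/200
  recon <- diploid_update(truth, 17L)
  expect_equal(rr_diploid(truth, recon), 0.99)
  expect_error(rr_diploid(truth, haplotype_set(matrix(0L, 2, 50))),
               "lengths differ")
})

test_that("polyploid reconstruction rate uses the optimal row mapping", {
  set.seed(2)
  truth <- haplotype_set(matrix(sample(c(0L, 1L), 12, replace = TRUE), 3, 4))
  expect_equal(rr_polyploid(truth, truth), 1.0)
  perm <- haplotype_set(unclass(truth)[c(3, 1, 2), ])
  expect_equal(rr_polyploid(truth, perm), 1.0)
  # mapping cost verified against exhaustive enumeration
  recon <- unclass(perm)
  recon[1, 2] <- 1L - recon[1, 2]
  recon[2, 4] <- 1L - recon[2, 4]
  recon <- haplotype_set(recon)
  expect_equal(rr_polyploid(truth, recon), brute_rr_polyploid(truth, recon))
  expect_error(rr_polyploid(truth, haplotype_set(matrix(0L, 2, 4))),
               "ploidy")
})

test_that("the matching solution equals the P! brute force on random inputs", {
  for (seed in 1:20) {
    set.seed(seed)
    p <- sample(2:5, 1)
    n <- sample(4:10, 1)
    truth <- haplotype_set(matrix(sample(c(0L, 1L), p * n, replace = TRUE), p, n))
    recon <- haplotype_set(matrix(sample(c(0L, 1L), p * n, replace = TRUE), p, n))
    expect_equal(rr_polyploid(truth, recon), brute_rr_polyploid(truth, recon))
    # invariance under row permutations of the reconstruction
    pm <- sample(p)
    expect_equal(rr_polyploid(truth, haplotype_set(unclass(recon)[pm, ])),
                 rr_polyploid(truth, recon))
  }
})

test_that("a complement pair of an all-heterozygous truth scores 1", {
  set.seed(3)
  t1 <- sample(c(0L, 1L), 40, replace = TRUE)
  truth <- haplotype_set(rbind(t1, 1L - t1))
  flipped <- haplotype_set(rbind(1L - t1, t1))
  expect_equal(rr_diploid(truth, flipped), 1.0)
})

test_that("blockwise rates weight per-block pairings by block length", {
  set.seed(4)
  t1 <- sample(c(0L, 1L), 10, replace = TRUE)
  truth <- haplotype_set(rbind(t1, 1L - t1))
  # reconstruction phased oppositely in the second block only
  blocks <- list(1:6, 7:10)
  recon <- unclass(truth)
  recon[, 7:10] <- recon[2:1, 7:10]
  recon <- haplotype_set(recon)
  expect_equal(reconstruction_rate(truth, recon, blocks), 1.0)
  expect_lt(reconstruction_rate(truth, recon), 1.0)
  # single block: blockwise equals global
  expect_equal(reconstruction_rate(truth, recon, list(1:10)),
               reconstruction_rate(truth, recon))
})

test_that("benchmark orchestration is seeded and exact on error-free cells", {
  tab <- run_benchmark(ploidy = 2, lengths = 60, coverages = 6, errors = 0,
                       replicates = 2, seed = 99)
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$rr, c(1, 1))
  expect_equal(tab$mec, c(0, 0))
  tab2 <- run_benchmark(ploidy = 2, lengths = 60, coverages = 6, errors = 0,
                        replicates = 2, seed = 99)
  expect_identical(tab[c("rr", "mec")], tab2[c("rr", "mec")])
  out <- withr::local_tempfile(fileext = ".csv")
  tab3 <- run_benchmark(ploidy = 2, lengths = 40, coverages = 5, errors = 0.1,
                        replicates = 1, seed = 7, out = out)
  expect_true(file.exists(out))
  sm <- summarize_benchmark(tab3)
  expect_equal(sm$n, 1L)
  expect_equal(sm$mean_rr, tab3$rr)
})
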