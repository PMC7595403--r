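test_that("dense dialect parses alleles and gaps", {
  path <- withr::local_tempfile()
  writeLines(c("01-0", "-110"), path)
  x <- read_fragments(path, "dense")
  expect_equal(dim(x), c(2L, 4L))
  expect_equal(sum(!is.na(x$alleles)), 6L)
  expect_equal(x$alleles[1, ], c(0L, 1L, NA, 0L))
  expect_equal(x$alleles[2, ], c(NA, 1L, 1L, 0L))
})

test_that("empty dense file reads as an empty matrix and round-trips", {
  path <- withr::local_tempfile()
  writeLines(character(0), path)
  x <- read_fragments(path, "dense")
  expect_equal(dim(x), c(0L, 0L))
  out <- withr::local_tempfile()
  write_fragments(x, out, "dense")
  expect_equal(dim(read_fragments(out, "dense")), c(0L, 0L))
})

test_that("hapcut dialect decodes blocks, 1-based starts and Phred qualities", {
  path <- withr::local_tempfile()
  writeLines("2 f1 1 01 4 1 QQQ", path)
  x <- read_fragments(path, "hapcut")
  expect_equal(dim(x), c(1L, 4L))
  expect_equal(x$alleles[1, ], c(0L, 1L, NA, 1L))
  expect_equal(x$fragment_ids, "f1")
  q <- 10^(-(utf8ToInt("Q") - 33) / 10)
  expect_equal(x$error_probs[1, c(1, 2, 4)], rep(q, 3))
  expect_true(is.na(x$error_probs[1, 3]))
})

test_that("round trips are identity for both dialects", {
  for (seed in 1:5) {
    set.seed(seed)
    x <- random_fragment_matrix(6, 10)
    for (dialect in c("dense", "hapcut")) {
      out <- withr::local_tempfile()
      write_fragments(x, out, dialect)
      y <- read_fragments(out, dialect, n_snps = n_snps(x))
      expect_true(x == y)
      expect_equal(sum(!is.na(y$alleles)), sum(!is.na(x$alleles)))
    }
  }
  # hapcut round trip also preserves on-grid error probabilities
  set.seed(9)
  x <- random_fragment_matrix(4, 8)
  q <- matrix(NA_real_, 4, 8)
  q[!is.na(x$alleles)] <- 10^(-sample(5:30, sum(!is.na(x$alleles)),
                                      replace = TRUE) / 10)
  x <- fragment_matrix(x$alleles, error_probs = q)
  out <- withr::local_tempfile()
  write_fragments(x, out, "hapcut")
  y <- read_fragments(out, "hapcut", n_snps = 8)
  expect_equal(y$error_probs, x$error_probs, tolerance = 1e-12)
})

test_that("dense writer puts a '-' for a leading gap", {
  x <- frag_from_strings("-101")
  out <- withr::local_tempfile()
  write_fragments(x, out, "dense")
  expect_equal(substr(readLines(out)[1], 1, 1), "-")
})

test_that("malformed fragment input is rejected with the line number", {
  path <- withr::local_tempfile()
  writeLines(c("0101", "01x1"), path)
  expect_error(read_fragments(path, "dense"), "line 2")
  writeLines(c("0101", "011"), path)
  expect_error(read_fragments(path, "dense"), "line 2")
  writeLines("1 f1 1 02 QQ", path)
  expect_error(read_fragments(path, "hapcut"), "line 1")
  writeLines("1 f1 1 01 QQQ", path)
  expect_error(read_fragments(path, "hapcut"), "quality")
})

test_that("haplotype files round-trip and reject malformed rows", {
  path <- withr::local_tempfile()
  writeLines(c("01", "10"), path)
  h <- read_haplotypes(path)
  expect_equal(dim(h), c(2L, 2L))
  set.seed(3)
  h3 <- haplotype_set(matrix(sample(c(0L, 1L), 15, replace = TRUE), 3, 5))
  out <- withr::local_tempfile()
  write_haplotypes(h3, out)
  expect_equal(unclass(read_haplotypes(out)), unclass(h3))
  writeLines(c("01", "100"), path)
  expect_error(read_haplotypes(path), "ragged")
  writeLines(c("01", "0x"), path)
  expect_error(read_haplotypes(path), "0/1")
})

test_that("fragment_matrix validates its invariants", {
  expect_error(fragment_matrix(matrix(2L, 1, 1)), "0, 1 or NA")
  a <- matrix(c(0L, NA), 1, 2)
  expect_error(fragment_matrix(a, error_probs = matrix(c(0.1, 0.2), 1, 2)),
               "non-gap")
  expect_error(fragment_matrix(a, error_probs = matrix(c(1.5, NA), 1, 2)))
  expect_silent(fragment_matrix(a, error_probs = matrix(c(0.1, NA), 1, 2)))
})
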