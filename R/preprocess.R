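#' Remove homozygote columns from a diploid fragment matrix
#'
#' For each SNP column the frequency of the most common allele among the
#' non-gap entries is computed; columns whose frequency is strictly greater
#' than \code{threshold} (default 0.8) are treated as homozygote sites and
#' removed, since they carry no phasing information in the diploid case.
#' All-gap columns (where the frequency is undefined) are removed as well.
#' The surviving columns are re-indexed and the mapping back to the original
#' coordinates is returned.
#'
#' @param x a \code{\link{fragment_matrix}}.
#' @param threshold frequency cut-off in (0.5, 1]; the comparison is strict.
#' @return a list with elements \code{fragments} (the filtered matrix) and
#'   \code{column_map} (see \code{\link{column_map}}).
#' @export
remove_homozygous_columns <- function(x, threshold = 0.8) {
  stopifnot(inherits(x, "fragment_matrix"), threshold > 0.5, threshold <= 1)
  a <- x$alleles
  ones <- colSums(a == 1L, na.rm = TRUE)
  zeros <- colSums(a == 0L, na.rm = TRUE)
  tot <- ones + zeros
  freq <- pmax(ones, zeros) / tot  # NaN for all-gap columns
  keep <- which(tot > 0L & freq <= threshold)
  list(fragments = subset_snps(x, keep),
       column_map = column_map(keep, ncol(a)))
}

#' Column map between filtered and original SNP coordinates
#'
#' @param kept strictly increasing original column indices that survived
#'   filtering (1-based).
#' @param original_n number of columns before filtering.
#' @return a list of class \code{column_map}.
#' @export
column_map <- function(kept, original_n) {
  kept <- as.integer(kept)
  if (is.unsorted(kept, strictly = TRUE)) {
    stop("`kept` must be strictly increasing")
  }
  if (length(kept) && (kept[1] < 1 || kept[length(kept)] > original_n)) {
    stop("`kept` indices out of range")
  }
  structure(list(kept = kept, original_n = as.integer(original_n)),
            class = "column_map")
}

#' Expand haplotypes from filtered back to original coordinates
#'
#' Columns removed by the homozygote filter are filled with \code{fill}
#' (default: the per-column majority allele observed in \code{fragments},
#' i.e. the called homozygous allele, in both rows).
#'
#' @param h a \code{\link{haplotype_set}} in filtered (kept-column)
#'   coordinates.
#' @param map the \code{\link{column_map}} produced by the filter.
#' @param fragments optional original-coordinate \code{fragment_matrix} used
#'   to call the majority allele at removed columns.
#' @param fill allele used at removed columns when \code{fragments} is
#'   absent.
#' @return a \code{haplotype_set} with \code{map$original_n} columns.
#' @export
expand_haplotypes <- function(h, map, fragments = NULL, fill = 0L) {
  stopifnot(inherits(h, "haplotype_set"), inherits(map, "column_map"))
  if (ncol(h) != length(map$kept)) {
    stop("haplotype length does not match the number of kept columns")
  }
  out <- matrix(as.integer(fill), nrow(h), map$original_n)
  dropped <- setdiff(seq_len(map$original_n), map$kept)
  if (!is.null(fragments) && length(dropped)) {
    a <- fragments$alleles[, dropped, drop = FALSE]
    maj <- as.integer(colSums(a == 1L, na.rm = TRUE) >=
                        colSums(a == 0L, na.rm = TRUE))
    out[, dropped] <- matrix(maj, nrow(h), length(dropped), byrow = TRUE)
  }
  out[, map$kept] <- unclass(h)
  haplotype_set(out)
}

#' Random initial haplotype set
#'
#' Diploid: one uniform random row plus its complement (the filtered matrix
#' is all-heterozygous, so the complementary representation is exact).
#' Polyploid: P independent uniform rows.
#'
#' @param ploidy P >= 2.
#' @param n_snps haplotype length (number of kept SNP columns).
#' @param seed optional integer seed.
#' @return a \code{\link{haplotype_set}}.
#' @export
initialize_haplotypes <- function(ploidy, n_snps, seed = NULL) {
  stopifnot(ploidy >= 2, n_snps >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (ploidy == 2) {
    h1 <- sample(c(0L, 1L), n_snps, replace = TRUE)
    haplotype_set(rbind(h1, 1L - h1))
  } else {
    haplotype_set(matrix(sample(c(0L, 1L), ploidy * n_snps, replace = TRUE),
                         ploidy, n_snps))
  }
}
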