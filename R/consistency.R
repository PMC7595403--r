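#' Gap-aware Hamming distance
#'
#' Counts the positions where both sequences are non-gap and unequal; a gap
#' (\code{NA}) at either position contributes zero.
#'
#' @param f,g equal-length vectors over \code{0}, \code{1}, \code{NA}.
#' @return integer mismatch count.
#' @export
hamming_distance <- function(f, g) {
  if (length(f) != length(g)) {
    stop("hamming_distance: sequences of unequal length")
  }
  sum(!is.na(f) & !is.na(g) & f != g)
}

#' Assign fragments to their nearest haplotypes
#'
#' Each fragment is assigned to the haplotype row minimising the gap-aware
#' Hamming distance; ties are broken by the lowest row index, so assignment
#' is deterministic.
#'
#' @param x a \code{\link{fragment_matrix}}.
#' @param h a \code{\link{haplotype_set}} with \code{ncol(h) == n_snps(x)}.
#' @return integer vector of haplotype row indices, one per fragment.
#' @export
assign_fragments <- function(x, h) {
  stopifnot(inherits(x, "fragment_matrix"), inherits(h, "haplotype_set"))
  if (ncol(h) != n_snps(x)) {
    stop("haplotype length does not match the fragment matrix")
  }
  cpp_assign_mec(x$alleles, as_haplotype_matrix(h))$assignment
}

#' Minimum error correction score
#'
#' MEC(X, H): each fragment is assigned to its nearest haplotype row and the
#' gap-aware Hamming distances are summed. Zero on error-free data whose
#' haplotypes are recovered exactly.
#'
#' @inheritParams assign_fragments
#' @return numeric count of alleles that would have to be corrected.
#' @export
mec <- function(x, h) {
  stopifnot(inherits(x, "fragment_matrix"), inherits(h, "haplotype_set"))
  if (n_fragments(x) == 0) return(0)
  if (ncol(h) != n_snps(x)) {
    stop("haplotype length does not match the fragment matrix")
  }
  cpp_assign_mec(x$alleles, as_haplotype_matrix(h))$mec
}

#' Pair-SNP consistency matrix
#'
#' For SNPs \code{i}, \code{j} covered jointly by \code{T_ij} fragments, the
#' consistency is the mean over those fragments of a two-valued term: -1 when
#' the fragment's allele pair at (i, j) equals the pair carried by the
#' fragment's assigned haplotype, +1 otherwise. Values lie in [-1, +1]; -1
#' means the current haplotypes explain every covering fragment at the pair,
#' +1 that they explain none. Pairs covered by no fragment (and the
#' diagonal) are 0. Fragments with a gap at either position are excluded
#' from the pair's cover set.
#'
#' @inheritParams assign_fragments
#' @param assignment optional precomputed fragment assignment (from
#'   \code{\link{assign_fragments}}); computed if missing.
#' @return list with \code{omega} (N x N symmetric numeric matrix) and
#'   \code{tcount} (pair cover counts).
#' @export
pair_consistency <- function(x, h, assignment = NULL) {
  stopifnot(inherits(x, "fragment_matrix"), inherits(h, "haplotype_set"))
  if (is.null(assignment)) assignment <- assign_fragments(x, h)
  stopifnot(length(assignment) == n_fragments(x),
            all(assignment >= 1), all(assignment <= nrow(h)))
  cpp_pair_consistency(x$alleles, as_haplotype_matrix(h),
                       as.integer(assignment))
}
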