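#' Construct a SNP fragment matrix
#'
#' The central container of the package: an \code{M x N} matrix of alleles
#' observed by sequencing fragments (reads) at biallelic SNP sites. Each row
#' is one fragment, each column one SNP; entries are \code{0}, \code{1} or
#' \code{NA} (the gap symbol \code{'-'} on disk), meaning the fragment does
#' not cover that site. Optionally carries per-entry sequencing-error
#' probabilities (e.g. decoded from Phred qualities) with exactly the same
#' coverage pattern as the alleles.
#'
#' @param alleles integer (or coercible) matrix over \code{0}, \code{1},
#'   \code{NA}.
#' @param error_probs optional numeric matrix of the same dimension, values in
#'   (0, 1), non-\code{NA} exactly where \code{alleles} is non-\code{NA}.
#' @param fragment_ids optional character vector of row labels.
#' @return An object of class \code{fragment_matrix}.
#' @export
fragment_matrix <- function(alleles, error_probs = NULL, fragment_ids = NULL) {
  if (is.null(dim(alleles))) {
    stop("`alleles` must be a matrix")
  }
  alleles <- matrix(as.integer(alleles), nrow = nrow(alleles))
  bad <- !is.na(alleles) & !(alleles %in% c(0L, 1L))
  if (any(bad)) {
    stop("fragment alleles must be 0, 1 or NA (gap)")
  }
  if (!is.null(error_probs)) {
    error_probs <- matrix(as.numeric(error_probs), nrow = nrow(alleles))
    if (!identical(dim(error_probs), dim(alleles))) {
      stop("`error_probs` must have the same dimension as `alleles`")
    }
    if (!identical(is.na(error_probs), is.na(alleles))) {
      stop("`error_probs` must be defined exactly at the non-gap entries")
    }
    pr <- error_probs[!is.na(error_probs)]
    if (length(pr) && (any(pr <= 0) || any(pr >= 1))) {
      stop("error probabilities must lie strictly in (0, 1)")
    }
  }
  if (!is.null(fragment_ids)) {
    fragment_ids <- as.character(fragment_ids)
    if (length(fragment_ids) != nrow(alleles)) {
      stop("`fragment_ids` must have one label per fragment")
    }
  }
  structure(
    list(alleles = alleles, error_probs = error_probs,
         fragment_ids = fragment_ids),
    class = "fragment_matrix"
  )
}

#' @export
dim.fragment_matrix <- function(x) dim(x$alleles)

#' Number of fragments / SNP sites
#' @param x a \code{fragment_matrix}.
#' @return integer count.
#' @export
n_fragments <- function(x) nrow(x$alleles)

#' @rdname n_fragments
#' @export
n_snps <- function(x) ncol(x$alleles)

#' @export
print.fragment_matrix <- function(x, ...) {
  cov <- sum(!is.na(x$alleles))
  cat(sprintf(
    "fragment_matrix: %d fragments x %d SNPs, %d observed alleles (%.1f%% gaps)%s\n",
    nrow(x$alleles), ncol(x$alleles), cov,
    if (length(x$alleles)) 100 * (1 - cov / length(x$alleles)) else 0,
    if (is.null(x$error_probs)) "" else ", with qualities"
  ))
  invisible(x)
}

#' @export
`==.fragment_matrix` <- function(e1, e2) {
  identical(unname(e1$alleles), unname(e2$alleles))
}

#' Restrict a fragment matrix to a subset of SNP columns
#'
#' @param x a \code{fragment_matrix}.
#' @param cols integer vector of column indices to keep (1-based, increasing).
#' @return a \code{fragment_matrix} over the selected columns.
#' @export
subset_snps <- function(x, cols) {
  fragment_matrix(
    x$alleles[, cols, drop = FALSE],
    error_probs = if (!is.null(x$error_probs)) x$error_probs[, cols, drop = FALSE],
    fragment_ids = x$fragment_ids
  )
}

#' Construct a haplotype set
#'
#' A haplotype set is a \code{P x N} binary matrix: one row per chromosome
#' copy (P = ploidy), one column per SNP site. In the diploid all-heterozygous
#' state (after homozygote-column removal) the second row is the bitwise
#' complement of the first.
#'
#' @param alleles binary matrix (no \code{NA}).
#' @return An integer matrix of class \code{haplotype_set}.
#' @export
haplotype_set <- function(alleles) {
  if (is.null(dim(alleles))) alleles <- matrix(alleles, nrow = 1)
  m <- matrix(as.integer(alleles), nrow = nrow(alleles))
  if (any(is.na(m)) || !all(m %in% c(0L, 1L))) {
    stop("haplotype alleles must be 0 or 1")
  }
  if (nrow(m) < 1) stop("a haplotype set needs at least one row")
  structure(m, class = c("haplotype_set", "matrix", "array"))
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat(sprintf("haplotype_set: ploidy %d, %d SNPs\n", nrow(x), ncol(x)))
  p <- min(nrow(x), 8L)
  for (i in seq_len(p)) {
    s <- paste(x[i, seq_len(min(ncol(x), 60L))], collapse = "")
    cat(sprintf("  h%d: %s%s\n", i, s, if (ncol(x) > 60) "..." else ""))
  }
  invisible(x)
}

complement <- function(h) 1L - h

as_haplotype_matrix <- function(H) {
  if (inherits(H, "haplotype_set")) unclass(H) else H
}
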