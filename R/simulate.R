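#' Simulation configuration for benchmark-style fragment matrices
#'
#' Encodes the generating conditions of the classic single-individual
#' haplotyping benchmarks: P ground-truth haplotypes of length \code{l},
#' contiguous-block fragments at mean per-SNP coverage \code{c}, symmetric
#' allele-flip errors at rate \code{e}, and gap-dominated rows (short spans,
#' optional interior mate gaps).
#'
#' @param ploidy number of haplotypes P (>= 2).
#' @param length number of SNP sites l (>= 2).
#' @param coverage target mean number of observed alleles per SNP column.
#' @param error_rate per-allele flip probability in [0, 0.5).
#' @param fragment_length integer range (min, max) of fragment spans in SNPs;
#'   default scales the diploid benchmark's short reads, uniform on
#'   [3, 7] at l = 100 (mean span l/20), linearly with \code{length}.
#' @param mate_gap_prob probability that a fragment is split into two blocks
#'   by an interior gap.
#' @param mate_gap_range integer range of the interior gap width in SNPs.
#' @return a list of class \code{sim_config}.
#' @export
sim_config <- function(ploidy = 2, length = 100, coverage = 5,
                       error_rate = 0.1,
                       fragment_length = NULL,
                       mate_gap_prob = 0.5,
                       mate_gap_range = c(1L, 3L)) {
  stopifnot(ploidy >= 2, length >= 2, coverage > 0,
            error_rate >= 0, error_rate < 0.5)
  if (is.null(fragment_length)) {
    fragment_length <- pmax(2L, as.integer(round(c(3, 7) * length / 100)))
  }
  fragment_length <- as.integer(fragment_length)
  stopifnot(length(fragment_length) == 2,
            fragment_length[1] >= 2,
            fragment_length[2] >= fragment_length[1])
  if (fragment_length[2] > length) {
    stop("infeasible configuration: maximum fragment span exceeds the haplotype length")
  }
  structure(list(ploidy = as.integer(ploidy), length = as.integer(length),
                 coverage = coverage, error_rate = error_rate,
                 fragment_length = fragment_length,
                 mate_gap_prob = mate_gap_prob,
                 mate_gap_range = as.integer(mate_gap_range)),
            class = "sim_config")
}

#' Simulate a ground-truth haplotype set
#'
#' Diploid: one uniform random row plus its complement, i.e. the
#' all-heterozygous state that remains after homozygote columns are removed.
#' Polyploid: P independent uniform rows, with any monomorphic column (all P
#' alleles equal) resampled so every site is polymorphic.
#'
#' @param ploidy P >= 2.
#' @param length number of SNPs (>= 2).
#' @param seed optional integer seed.
#' @return a \code{\link{haplotype_set}}.
#' @export
simulate_haplotypes <- function(ploidy, length, seed = NULL) {
  stopifnot(ploidy >= 2, length >= 2)
  if (!is.null(seed)) set.seed(seed)
  if (ploidy == 2) {
    h1 <- sample(c(0L, 1L), length, replace = TRUE)
    return(haplotype_set(rbind(h1, 1L - h1)))
  }
  m <- matrix(sample(c(0L, 1L), ploidy * length, replace = TRUE), ploidy, length)
  repeat {
    mono <- which(colSums(m) %in% c(0L, ploidy))
    if (!length(mono)) break
    m[, mono] <- sample(c(0L, 1L), ploidy * length(mono), replace = TRUE)
  }
  haplotype_set(m)
}

# sample() interprets a length-1 first argument as 1:n; guard against it
sample_range <- function(a, b) if (a >= b) a else sample(seq(a, b), 1)

# Draw the covered column set of one fragment: a contiguous span, possibly
# split by an interior mate gap; when uncovered sites remain the span is
# placed to cover one of them.
draw_fragment_cols <- function(cfg, uncovered) {
  span <- sample_range(cfg$fragment_length[1], cfg$fragment_length[2])
  # mate-pair emulation: two read blocks separated by an uncovered insert,
  # so the gap extends the fragment's reach beyond the read span
  gap <- 0L
  if (stats::runif(1) < cfg$mate_gap_prob && span >= 2L) {
    gap <- sample_range(cfg$mate_gap_range[1], cfg$mate_gap_range[2])
  }
  extent <- span + gap
  if (extent > cfg$length) {
    gap <- 0L
    extent <- span
  }
  if (length(uncovered)) {
    target <- if (length(uncovered) == 1) uncovered else sample(uncovered, 1)
    lo <- max(1L, target - extent + 1L)
    hi <- min(target, cfg$length - extent + 1L)
    start <- sample_range(lo, hi)
  } else {
    start <- sample_range(1L, cfg$length - extent + 1L)
  }
  cols <- start:(start + extent - 1L)
  if (gap > 0L) {
    pos <- sample_range(1L, span - 1L)  # split after this many read bases
    cols <- cols[-(pos + seq_len(gap))]
  }
  cols
}

#' Simulate a noisy, gapped fragment matrix from a haplotype set
#'
#' Fragments are contiguous blocks (optionally split by an interior mate gap)
#' whose source haplotype is chosen uniformly among the P rows; each observed
#' allele is then flipped independently with probability \code{error_rate}.
#' Fragments are drawn until the total number of observed alleles reaches
#' \code{coverage * length} and every SNP column is covered at least once
#' (placement is steered onto still-uncovered columns, so the floor holds by
#' construction while mean coverage stays at the target).
#'
#' @param truth a \code{\link{haplotype_set}}.
#' @param config a \code{\link{sim_config}} with matching ploidy/length.
#' @param seed optional integer seed.
#' @return a list of class \code{sim_instance} with elements \code{truth},
#'   \code{fragments} (a \code{\link{fragment_matrix}}), \code{provenance}
#'   (source haplotype row per fragment) and \code{genotype} (per-site count
#'   of the `1` allele in \code{truth}).
#' @export
simulate_fragments <- function(truth, config, seed = NULL) {
  stopifnot(inherits(truth, "haplotype_set"), inherits(config, "sim_config"))
  if (nrow(truth) != config$ploidy || ncol(truth) != config$length) {
    stop("`truth` dimensions do not match the configuration")
  }
  if (!is.null(seed)) set.seed(seed)
  l <- config$length
  target <- config$coverage * l
  covered <- integer(l)
  cols_list <- list()
  prov <- integer(0)
  total <- 0
  while (total < target || any(covered == 0L)) {
    uncovered <- which(covered == 0L)
    cols <- draw_fragment_cols(config, uncovered)
    cols_list[[length(cols_list) + 1L]] <- cols
    prov <- c(prov, sample.int(config$ploidy, 1))
    covered[cols] <- covered[cols] + 1L
    total <- total + length(cols)
  }
  m <- matrix(NA_integer_, length(cols_list), l)
  for (i in seq_along(cols_list)) {
    cols <- cols_list[[i]]
    a <- unclass(truth)[prov[i], cols]
    if (config$error_rate > 0) {
      flip <- stats::runif(length(a)) < config$error_rate
      a <- ifelse(flip, 1L - a, a)
    }
    m[i, cols] <- a
  }
  structure(list(truth = truth,
                 fragments = fragment_matrix(m),
                 provenance = prov,
                 genotype = as.integer(colSums(unclass(truth)))),
            class = "sim_instance")
}

#' Simulate a complete benchmark instance
#'
#' Convenience wrapper: draws the ground truth with
#' \code{\link{simulate_haplotypes}} and the fragments with
#' \code{\link{simulate_fragments}} under one seed.
#'
#' @inheritParams simulate_fragments
#' @export
simulate_instance <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  truth <- simulate_haplotypes(config$ploidy, config$length)
  simulate_fragments(truth, config)
}

#' Write a simulated instance to disk
#'
#' Produces the (fragment file, truth haplotype file, genotype file) triplet
#' used by the command-line interface.
#'
#' @param inst a \code{sim_instance}.
#' @param prefix output path prefix; files \code{<prefix>.frags},
#'   \code{<prefix>.truth} and \code{<prefix>.genotype} are written.
#' @param dialect fragment dialect passed to \code{\link{write_fragments}}.
#' @return the three paths, invisibly.
#' @export
write_instance <- function(inst, prefix, dialect = "dense") {
  stopifnot(inherits(inst, "sim_instance"))
  paths <- paste0(prefix, c(".frags", ".truth", ".genotype"))
  write_fragments(inst$fragments, paths[1], dialect = dialect)
  write_haplotypes(inst$truth, paths[2])
  writeLines(as.character(inst$genotype), paths[3])
  invisible(paths)
}
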