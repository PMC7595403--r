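full_hd <- function(a, b) sum(a != b)

#' Diploid reconstruction rate
#'
#' \code{RR = 1 - (1 / (2 N)) * min(HD(h1, r1) + HD(h2, r2),
#' HD(h1, r2) + HD(h2, r1))}: the mismatch between truth and reconstruction
#' under the better of the two row pairings, normalised by the total number
#' of alleles. Both sets must be diploid with equal length; the Hamming
#' distances are gap-free and full length.
#'
#' @param truth,recon diploid \code{\link{haplotype_set}}s of equal length.
#' @return rate in [0, 1]; 1 means perfect reconstruction up to row order.
#' @export
rr_diploid <- function(truth, recon) {
  stopifnot(inherits(truth, "haplotype_set"), inherits(recon, "haplotype_set"))
  if (nrow(truth) != 2 || nrow(recon) != 2) stop("rr_diploid needs ploidy 2")
  if (ncol(truth) != ncol(recon)) stop("haplotype lengths differ")
  n <- ncol(truth)
  d <- min(full_hd(truth[1, ], recon[1, ]) + full_hd(truth[2, ], recon[2, ]),
           full_hd(truth[1, ], recon[2, ]) + full_hd(truth[2, ], recon[1, ]))
  1 - d / (2 * n)
}

#' Optimal one-to-one mapping between reconstructed and true haplotypes
#'
#' Solves the P x P assignment problem on the pairwise Hamming-distance cost
#' matrix by maximum-weight bipartite matching.
#'
#' @param truth,recon \code{\link{haplotype_set}}s with equal ploidy and
#'   length.
#' @return list with \code{mapping} (truth row matched to each recon row)
#'   and \code{cost} (total mismatches under the mapping).
#' @export
optimal_row_mapping <- function(truth, recon) {
  p <- nrow(truth)
  n <- ncol(truth)
  cost <- outer(seq_len(p), seq_len(p),
                Vectorize(function(i, j) full_hd(recon[i, ], truth[j, ])))
  w <- n - cost + 1  # strictly positive, so the optimum matching is perfect
  el <- cbind(rep(seq_len(p), each = p), p + rep(seq_len(p), times = p))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  igraph::V(g)$type <- rep(c(FALSE, TRUE), each = p)
  m <- igraph::max_bipartite_match(g, weights = as.vector(t(w)))
  mapping <- m$matching[seq_len(p)] - p
  list(mapping = as.integer(mapping),
       cost = sum(cost[cbind(seq_len(p), mapping)]))
}

#' Polyploid reconstruction rate
#'
#' \code{RR = 1 - (1 / (N P)) * min_M sum d(M(recon)_ij, truth_ij)} over all
#' one-to-one mappings M between reconstructed and true haplotype rows; the
#' optimal mapping is found by weighted bipartite matching
#' (\code{\link{optimal_row_mapping}}).
#'
#' @inheritParams optimal_row_mapping
#' @return rate in [0, 1].
#' @export
rr_polyploid <- function(truth, recon) {
  stopifnot(inherits(truth, "haplotype_set"), inherits(recon, "haplotype_set"))
  if (nrow(truth) != nrow(recon)) stop("ploidy mismatch")
  if (ncol(truth) != ncol(recon)) stop("haplotype lengths differ")
  om <- optimal_row_mapping(truth, recon)
  1 - om$cost / (ncol(truth) * nrow(truth))
}

#' Reconstruction rate, optionally per connected block
#'
#' With \code{blocks = NULL} this is the global metric (diploid or polyploid
#' by ploidy). When the column-index blocks of the fragment matrix are
#' supplied, the rate is computed within each block and averaged weighted by
#' block length: relative phase between disconnected blocks is not
#' identifiable from the fragments, so the blockwise rate is the quantity a
#' perfect assembler can actually attain (and equals the global rate when
#' the instance is a single block).
#'
#' @inheritParams optimal_row_mapping
#' @param blocks optional list of column-index vectors (see
#'   \code{\link{fragment_blocks}}).
#' @return rate in [0, 1].
#' @export
reconstruction_rate <- function(truth, recon, blocks = NULL) {
  rr_fun <- if (nrow(truth) == 2) rr_diploid else rr_polyploid
  if (is.null(blocks)) return(rr_fun(truth, recon))
  stopifnot(sum(lengths(blocks)) == ncol(truth))
  rates <- vapply(blocks, function(cols) {
    rr_fun(haplotype_set(unclass(truth)[, cols, drop = FALSE]),
           haplotype_set(unclass(recon)[, cols, drop = FALSE]))
  }, 0)
  sum(rates * lengths(blocks)) / ncol(truth)
}

#' Evaluate an assembly against the ground truth
#'
#' Restricts the truth (original coordinates) to the columns that survived
#' preprocessing and reports the blockwise and global reconstruction rates
#' together with the final MEC.
#'
#' @param result an \code{hrch_assembly} from \code{\link{assemble}}.
#' @param truth the true \code{\link{haplotype_set}} in original
#'   coordinates.
#' @return list with \code{rr} (blockwise), \code{rr_global}, \code{mec},
#'   \code{n_sites}, \code{n_blocks}, \code{ploidy}.
#' @export
evaluate_assembly <- function(result, truth) {
  stopifnot(inherits(result, "hrch_assembly"), inherits(truth, "haplotype_set"))
  kept <- result$column_map$kept
  tf <- haplotype_set(unclass(truth)[, kept, drop = FALSE])
  list(rr = reconstruction_rate(tf, result$haplotypes, result$blocks),
       rr_global = reconstruction_rate(tf, result$haplotypes),
       mec = result$mec,
       n_sites = length(kept),
       n_blocks = length(result$blocks),
       ploidy = result$ploidy)
}

#' Run a simulation benchmark grid
#'
#' Simulates, assembles and evaluates \code{replicates} instances for every
#' combination of ploidy, length, coverage and error rate, fully seeded.
#'
#' @param ploidy ploidy (single value).
#' @param lengths,coverages,errors parameter vectors defining the grid.
#' @param replicates instances per cell.
#' @param seed integer seed for the whole grid.
#' @param config an \code{\link{assembly_config}}.
#' @param refine forwarded to \code{\link{assemble}}.
#' @param out optional CSV path for the per-replicate table.
#' @return data.frame with one row per replicate: \code{ploidy, l, c, e,
#'   replicate, rr, mec, runtime_s}.
#' @export
run_benchmark <- function(ploidy = 2, lengths = 100, coverages = 5,
                          errors = 0.1, replicates = 1, seed = 1,
                          config = assembly_config(), refine = TRUE,
                          out = NULL) {
  stopifnot(replicates >= 1)
  grid <- expand.grid(l = lengths, c = coverages, e = errors,
                      replicate = seq_len(replicates))
  set.seed(seed)
  run_seeds <- sample.int(.Machine$integer.max - 1L, nrow(grid))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    cfg <- sim_config(ploidy = ploidy, length = g$l, coverage = g$c,
                      error_rate = g$e)
    inst <- simulate_instance(cfg, seed = run_seeds[i])
    t0 <- proc.time()[["elapsed"]]
    res <- assemble(inst$fragments, ploidy = ploidy, config = config,
                    genotype = if (ploidy > 2) inst$genotype,
                    refine = refine)
    dt <- proc.time()[["elapsed"]] - t0
    ev <- evaluate_assembly(res, inst$truth)
    data.frame(ploidy = ploidy, l = g$l, c = g$c, e = g$e,
               replicate = g$replicate, rr = ev$rr, mec = ev$mec,
               runtime_s = dt)
  })
  tab <- do.call(rbind, rows)
  if (!is.null(out)) utils::write.csv(tab, out, row.names = FALSE)
  tab
}

#' Aggregate a benchmark table into per-cell means and standard errors
#'
#' @param tab per-replicate table from \code{\link{run_benchmark}}.
#' @return data.frame with one row per (ploidy, l, c, e) cell.
#' @export
summarize_benchmark <- function(tab) {
  cells <- split(tab, interaction(tab$ploidy, tab$l, tab$c, tab$e, drop = TRUE))
  out <- lapply(cells, function(d) {
    data.frame(ploidy = d$ploidy[1], l = d$l[1], c = d$c[1], e = d$e[1],
               n = nrow(d),
               mean_rr = mean(d$rr), se_rr = stats::sd(d$rr) / sqrt(nrow(d)),
               mean_mec = mean(d$mec),
               mean_runtime_s = mean(d$runtime_s))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$l, res$c, res$e), ]
}
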