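#' Assembly configuration
#'
#' Defaults follow the published operating point of the algorithm:
#' \code{iterations = 100}, \code{k = 5} consistency neighbours,
#' minimum support \code{sc = 2} and perturbation fraction \code{nc = 0.20}
#' of the CutSet. \code{patience} stops the loop early after that many
#' iterations without strict MEC improvement.
#'
#' @param iterations maximum number of improvement iterations.
#' @param k neighbour count for \code{\link{knn_sets}}.
#' @param sc minimum support count for \code{\link{mine_hyperedges}}.
#' @param nc fraction of CutSet SNPs perturbed per iteration, in [0, 1].
#' @param patience iterations without strict improvement before stopping.
#' @param balance_floor bipartition balance floor.
#' @param restarts FM partitioner restarts.
#' @param edge_weighting hyperedge weighting scheme (see
#'   \code{\link{mine_hyperedges}}).
#' @param homozygous_threshold frequency cut-off for diploid homozygote
#'   column removal.
#' @return a list of class \code{assembly_config}.
#' @export
assembly_config <- function(iterations = 100, k = 5, sc = 2, nc = 0.20,
                            patience = 15, balance_floor = 0.2, restarts = 8,
                            edge_weighting = c("support", "sknn"),
                            homozygous_threshold = 0.8) {
  stopifnot(iterations >= 1, k >= 1, sc >= 1, nc >= 0, nc <= 1,
            patience >= 1, restarts >= 1)
  structure(list(iterations = as.integer(iterations), k = as.integer(k),
                 sc = as.integer(sc), nc = nc,
                 patience = as.integer(patience),
                 balance_floor = balance_floor,
                 restarts = as.integer(restarts),
                 edge_weighting = match.arg(edge_weighting),
                 homozygous_threshold = homozygous_threshold),
            class = "assembly_config")
}

#' Flip the CutSet columns of a diploid haplotype pair
#'
#' Both rows are complemented at the CutSet columns, preserving the
#' all-heterozygous invariant h2 = complement(h1). Flipping the complementary
#' CutSet yields the same unordered pair (flipping every column merely swaps
#' the row labels), so only one side needs to be evaluated.
#'
#' @param h a diploid \code{\link{haplotype_set}}.
#' @param cutset integer vector of column indices (possibly empty).
#' @return the updated \code{haplotype_set}.
#' @export
diploid_update <- function(h, cutset) {
  stopifnot(inherits(h, "haplotype_set"), nrow(h) == 2)
  if (!length(cutset)) return(h)
  m <- unclass(h)
  m[, cutset] <- 1L - m[, cutset]
  haplotype_set(m)
}

# all permutations of 1..n, identity first, lexicographic
permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- permutations(n - 1L)
  out <- vector("list", n * length(sub))
  idx <- 0L
  for (first in seq_len(n)) {
    rest <- setdiff(seq_len(n), first)
    for (p in sub) {
      idx <- idx + 1L
      out[[idx]] <- c(first, rest[p])
    }
  }
  out
}

#' Re-permute the CutSet block of a polyploid haplotype set
#'
#' The P x |CutSet| block of \code{h} restricted to the CutSet columns is
#' spliced back under every row permutation (P! candidates, identity
#' included) and scored by MEC; the best-scoring candidate is returned, so
#' the MEC never increases.
#'
#' @param x the \code{\link{fragment_matrix}} being assembled.
#' @param h a \code{\link{haplotype_set}} with P >= 3 rows.
#' @param cutset integer vector of column indices.
#' @param max_ploidy largest P for which exhaustive permutation search is
#'   attempted.
#' @return the best \code{haplotype_set} found.
#' @export
polyploid_update <- function(x, h, cutset, max_ploidy = 6) {
  stopifnot(inherits(h, "haplotype_set"), nrow(h) >= 3)
  if (nrow(h) > max_ploidy) {
    stop(sprintf(
      "ploidy %d exceeds the exhaustive permutation cap (%d); use a sampled subset of permutations instead",
      nrow(h), max_ploidy))
  }
  if (!length(cutset)) return(h)
  m <- unclass(h)
  best <- h
  best_mec <- mec(x, h)
  for (p in permutations(nrow(h))[-1]) {
    cand <- m
    cand[, cutset] <- m[p, cutset]
    cand <- haplotype_set(cand)
    mm <- mec(x, cand)
    if (mm < best_mec) {
      best <- cand
      best_mec <- mm
    }
  }
  best
}

# propose a replacement column for the perturbation step
random_column <- function(h, col, genotype = NULL) {
  p <- nrow(h)
  if (p == 2) {
    # heterozygous state: the only alternatives are (0,1) and (1,0)
    a <- sample(c(0L, 1L), 1)
    return(c(a, 1L - a))
  }
  ones <- if (!is.null(genotype)) genotype[col] else sum(h[, col])
  cc <- integer(p)
  if (ones > 0) cc[sample.int(p, ones)] <- 1L
  cc
}

#' Random pair perturbation of CutSet SNPs
#'
#' \code{floor(nc * |cutset|)} CutSet SNPs are drawn without replacement and
#' processed in consecutive pairs; for each pair a random alternative
#' allele-column combination is substituted (heterozygous columns in the
#' diploid case; columns with the genotype's allele counts in the polyploid
#' case when a genotype is supplied, otherwise preserving the current
#' counts). A substitution is kept only if the MEC does not increase.
#'
#' @inheritParams polyploid_update
#' @param nc perturbation fraction in [0, 1].
#' @param genotype optional per-site counts of the `1` allele (polyploid).
#' @param seed optional integer seed.
#' @return list with the (possibly) updated \code{haplotypes} and their
#'   \code{mec}.
#' @export
perturb_pairs <- function(x, h, cutset, nc, genotype = NULL, seed = NULL) {
  stopifnot(inherits(h, "haplotype_set"), nc >= 0, nc <= 1)
  if (!is.null(seed)) set.seed(seed)
  cur_mec <- mec(x, h)
  ns <- floor(nc * length(cutset))
  if (ns < 2) return(list(haplotypes = h, mec = cur_mec))
  idx <- if (length(cutset) == 1) cutset else sample(cutset, ns)
  m <- unclass(h)
  for (p in seq_len(ns %/% 2L)) {
    cols <- idx[c(2L * p - 1L, 2L * p)]
    old <- m[, cols, drop = FALSE]
    for (ci in seq_along(cols)) {
      m[, cols[ci]] <- random_column(m, cols[ci], genotype)
    }
    new_mec <- mec(x, haplotype_set(m))
    if (new_mec <= cur_mec) {
      cur_mec <- new_mec
    } else {
      m[, cols] <- old
    }
  }
  list(haplotypes = haplotype_set(m), mec = cur_mec)
}

#' Connected fragment blocks of a SNP matrix
#'
#' Two SNP columns belong to the same block when some chain of fragments
#' links them (each fragment connects all columns it covers). Relative phase
#' between blocks is not identifiable from the fragments.
#'
#' @param x a \code{\link{fragment_matrix}}.
#' @return list of strictly increasing integer column-index vectors, one per
#'   block, ordered by first column.
#' @export
fragment_blocks <- function(x) {
  n <- n_snps(x)
  if (n == 0) return(list())
  pairs <- do.call(rbind, lapply(seq_len(n_fragments(x)), function(i) {
    cov <- which(!is.na(x$alleles[i, ]))
    if (length(cov) < 2) return(NULL)
    cbind(cov[-length(cov)], cov[-1])  # chain suffices for connectivity
  }))
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (!is.null(pairs)) g <- igraph::add_edges(g, t(pairs))
  comp <- igraph::components(g)$membership
  blocks <- split(seq_len(n), comp)
  blocks <- lapply(blocks, as.integer)
  names(blocks) <- NULL
  blocks[order(vapply(blocks, min, 0L))]
}

#' Iterative haplotype assembly
#'
#' The full iterative core. Diploid input is first cleaned of homozygote
#' columns; a random haplotype set is then improved for up to
#' \code{config$iterations} rounds. Each round (i) re-assigns fragments to
#' their nearest haplotypes, (ii) computes the pair-SNP consistency matrix,
#' (iii) builds the shared-KNN weighted hypergraph and bipartitions it,
#' (iv) applies the CutSet move (diploid flip or polyploid row-permutation
#' search) and (v) perturbs random CutSet pairs; every candidate state is
#' accepted only if its MEC does not increase, so the accepted-MEC trace is
#' non-increasing. The loop stops early after \code{config$patience} rounds
#' without strict improvement, or when MEC reaches zero. When requested (and
#' the filtered matrix is long enough) the finished haplotypes are refined
#' via confidence scoring and chaos-game local projection
#' (\code{\link{refine_haplotypes}}).
#'
#' @param x a \code{\link{fragment_matrix}} (original coordinates).
#' @param ploidy number of haplotypes to reconstruct (>= 2).
#' @param config an \code{\link{assembly_config}}.
#' @param genotype optional per-site `1`-allele counts (original
#'   coordinates), used by the polyploid perturbation and refinement.
#' @param refine logical: run the refinement phase (subject to its
#'   \code{min_length}).
#' @param refine_config a \code{\link{refinement_config}}.
#' @param seed optional integer seed controlling the whole run.
#' @return a list of class \code{hrch_assembly}: \code{haplotypes} (in
#'   filtered coordinates), \code{mec}, \code{trace}, \code{assignment},
#'   \code{column_map}, \code{blocks}, \code{ploidy}, \code{refined},
#'   \code{iterations_run}.
#' @export
assemble <- function(x, ploidy = 2, config = assembly_config(),
                     genotype = NULL, refine = TRUE,
                     refine_config = refinement_config(), seed = NULL) {
  stopifnot(inherits(x, "fragment_matrix"), ploidy >= 2,
            inherits(config, "assembly_config"))
  if (n_fragments(x) == 0 || !any(!is.na(x$alleles))) {
    stop("cannot assemble an empty or all-gap fragment matrix")
  }
  if (!is.null(seed)) set.seed(seed)

  if (ploidy == 2) {
    pp <- remove_homozygous_columns(x, config$homozygous_threshold)
  } else {
    covered <- which(colSums(!is.na(x$alleles)) > 0L)
    pp <- list(fragments = subset_snps(x, covered),
               column_map = column_map(covered, n_snps(x)))
  }
  xf <- pp$fragments
  cmap <- pp$column_map
  np <- n_snps(xf)
  if (np < 2) stop("fewer than 2 informative SNP columns remain after preprocessing")
  gf <- if (!is.null(genotype)) as.integer(genotype)[cmap$kept]

  h <- initialize_haplotypes(ploidy, np)
  cur_mec <- mec(xf, h)
  trace <- numeric(config$iterations)
  stagnant <- 0L
  it <- 0L
  while (it < config$iterations) {
    it <- it + 1L
    prev <- cur_mec
    asg <- assign_fragments(xf, h)
    pc <- pair_consistency(xf, h, asg)
    knn <- knn_sets(pc$omega, config$k)
    hg <- mine_hyperedges(knn, config$sc, config$edge_weighting)
    # augment the partitioner input with violated pairs (omega > 0) as
    # negative-weight edges: cutting between inconsistent SNPs lowers the
    # cut, so the search is drawn to the boundaries that need re-phasing
    hga <- add_violation_edges(hg, pc$omega, pc$tcount)
    cands <- if (length(hga$edges)) {
      partition_candidates(hga, config$balance_floor, config$restarts,
                           mixed_balance = TRUE)
    } else list()
    cutset <- if (length(cands)) cands[[1]]$cutset else integer(0)
    # candidate CutSets: every restart's smaller side, plus each connected
    # component of the hypergraph (a zero-cut side whose flip re-phases one
    # weakly-tethered cluster); all are scored by MEC and the best kept
    cutsets <- lapply(cands, `[[`, "cutset")
    if (length(hg$edges)) {
      cutsets <- c(cutsets, hypergraph_components(hg))
    }
    if (ploidy == 2) {
      # matrix-edge regions are tethered on one side only, so mis-phased
      # prefixes are common; an O(entries) sweep finds the best prefix flip
      pf <- cpp_prefix_flip_mec(xf$alleles, as_haplotype_matrix(h))
      jbest <- which.min(pf) - 1L
      if (jbest >= 1) cutsets <- c(cutsets, list(seq_len(jbest)))
      # steepest single-column flip, from an O(entries) delta sweep
      cd <- cpp_column_flip_deltas(xf$alleles, as_haplotype_matrix(h))
      if (min(cd) < 0) cutsets <- c(cutsets, list(which.min(cd)))
    }
    best_h <- NULL
    best_mec <- Inf
    for (cs in cutsets) {
      cand <- if (ploidy == 2) diploid_update(h, cs)
              else polyploid_update(xf, h, cs)
      cand_mec <- mec(xf, cand)
      if (cand_mec < best_mec) {
        best_h <- cand
        best_mec <- cand_mec
        cutset <- cs
      }
    }
    if (ploidy > 2) {
      # best prefix re-permutation, the polyploid analog of the prefix flip
      pm <- do.call(rbind, permutations(ploidy))
      pp_mec <- cpp_prefix_perm_mec(xf$alleles, as_haplotype_matrix(h), pm)
      jq <- arrayInd(which.min(pp_mec), dim(pp_mec))
      if (jq[1] > 1 && jq[2] > 1 && pp_mec[jq[1], jq[2]] < best_mec) {
        cols <- seq_len(jq[1] - 1L)
        cand <- unclass(h)
        cand[, cols] <- cand[pm[jq[2], ], cols]
        best_h <- haplotype_set(cand)
        best_mec <- mec(xf, best_h)
        cutset <- cols
      }
    }
    # strict improvement only: accepting MEC-equal CutSet moves lets the
    # state drift between equal-MEC phasings and out of good basins
    if (!is.null(best_h) && best_mec < cur_mec) {
      h <- best_h
      cur_mec <- best_mec
    }
    pt <- perturb_pairs(xf, h, cutset, config$nc, genotype = gf)
    h <- pt$haplotypes
    cur_mec <- pt$mec
    if (ploidy == 2) {
      # steepest-descent polish: flip the best single column while it
      # strictly lowers MEC (same move class as the pair perturbation,
      # applied greedily)
      repeat {
        cd <- cpp_column_flip_deltas(xf$alleles, as_haplotype_matrix(h))
        jmin <- which.min(cd)
        if (cd[jmin] >= 0) break
        h <- diploid_update(h, jmin)
        cur_mec <- cur_mec + cd[jmin]
      }
    } else {
      # polyploid analog: per-column coordinate descent over the allele
      # arrangements consistent with the (genotype) allele count
      counts <- if (!is.null(gf)) gf else colSums(unclass(h))
      hp <- haplotype_set(cpp_poly_column_polish(
        xf$alleles, as_haplotype_matrix(h), as.integer(counts), 5L))
      mp <- mec(xf, hp)
      if (mp <= cur_mec) {
        h <- hp
        cur_mec <- mp
      }
    }
    trace[it] <- cur_mec
    stagnant <- if (cur_mec < prev) 0L else stagnant + 1L
    if (cur_mec == 0 || stagnant >= config$patience) break
  }
  trace <- trace[seq_len(it)]
  asg <- assign_fragments(xf, h)

  refined <- FALSE
  if (isTRUE(refine) && np >= refine_config$min_length) {
    h <- refine_haplotypes(h, xf, asg, genotype = gf, config = refine_config)
    asg <- assign_fragments(xf, h)
    refined <- TRUE
  }
  structure(list(haplotypes = h, mec = mec(xf, h), trace = trace,
                 assignment = asg, column_map = cmap,
                 blocks = fragment_blocks(xf), ploidy = as.integer(ploidy),
                 refined = refined, iterations_run = it, config = config),
            class = "hrch_assembly")
}

#' @export
print.hrch_assembly <- function(x, ...) {
  cat(sprintf(
    "hrch_assembly: ploidy %d, %d SNPs (%d blocks), MEC %g after %d iterations%s\n",
    x$ploidy, ncol(x$haplotypes), length(x$blocks), x$mec, x$iterations_run,
    if (x$refined) ", refined" else ""))
  invisible(x)
}
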