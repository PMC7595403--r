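#' K nearest neighbours of each SNP under the consistency matrix
#'
#' The neighbours of SNP \code{i} are the \code{k} SNPs with the smallest
#' consistency values (most consistent, toward -1). Ties are broken by the
#' lower SNP index. When \code{k >= N} it is clamped to \code{N - 1} with a
#' warning. When pair cover counts are supplied, only SNPs actually
#' co-covered with \code{i} by at least one fragment are eligible, so a
#' neighbour set may hold fewer than \code{k} SNPs (consistency with a
#' never co-observed SNP is vacuous, and padding with such SNPs would glue
#' unrelated parts of the matrix into spurious hyperedges).
#'
#' @param omega symmetric N x N consistency matrix (from
#'   \code{\link{pair_consistency}}).
#' @param k neighbour count (>= 1).
#' @param tcount optional pair cover-count matrix (from
#'   \code{\link{pair_consistency}}) restricting eligibility.
#' @return list of integer neighbour vectors, one per SNP.
#' @export
knn_sets <- function(omega, k, tcount = NULL) {
  n <- ncol(omega)
  stopifnot(k >= 1, n >= 2)
  if (k >= n) {
    warning(sprintf("k = %d >= number of SNPs (%d); clamped to %d",
                    k, n, n - 1L))
    k <- n - 1L
  }
  lapply(seq_len(n), function(i) {
    v <- omega[i, ]
    v[i] <- Inf
    if (!is.null(tcount)) v[tcount[i, ] == 0L] <- Inf
    ord <- order(v)[seq_len(k)]  # order() breaks ties by index
    ord[is.finite(v[ord])]
  })
}

#' Mine weighted hyperedges from shared nearest-neighbour structure
#'
#' Each SNP contributes one transaction, its neighbour set augmented with the
#' SNP itself. Maximal itemsets of size >= 2 contained in at least \code{sc}
#' transactions become hyperedges. Under the default \code{"support"}
#' weighting the edge weight is the itemset's support count; under
#' \code{"sknn"} it is the number of SNPs shared by all members' neighbour
#' sets, and edges with fewer than \code{sc} shared neighbours are dropped.
#'
#' The miner enumerates the closure of the transactions under pairwise
#' intersection (every maximal frequent itemset is the intersection of its
#' supporting transactions, hence closed), then filters by support and
#' maximality; this is equivalent to FP-growth restricted to maximal
#' itemsets at the transaction sizes that arise here.
#'
#' @param knn neighbour table from \code{\link{knn_sets}}.
#' @param sc minimum support count (>= 1).
#' @param weighting \code{"support"} or \code{"sknn"}.
#' @return a list of class \code{snp_hypergraph} with \code{n_vertices},
#'   \code{edges} (integer vertex vectors, each of size >= 2) and
#'   \code{weights}.
#' @export
mine_hyperedges <- function(knn, sc = 2, weighting = c("support", "sknn")) {
  weighting <- match.arg(weighting)
  stopifnot(sc >= 1)
  n <- length(knn)
  trans <- lapply(seq_len(n), function(i) sort(unique(c(i, knn[[i]]))))
  # inverted index: item -> transactions containing it
  inv <- vector("list", n)
  for (t in seq_len(n)) for (v in trans[[t]]) inv[[v]] <- c(inv[[v]], t)

  key_of <- function(s) paste(s, collapse = " ")
  seen <- new.env(parent = emptyenv())
  cands <- list()
  frontier <- list()
  for (t in trans) {
    kk <- key_of(t)
    if (length(t) >= 2 && is.null(seen[[kk]])) {
      seen[[kk]] <- TRUE
      cands[[length(cands) + 1L]] <- t
      frontier[[length(frontier) + 1L]] <- t
    }
  }
  while (length(frontier)) {
    nxt <- list()
    for (a in frontier) {
      touching <- unique(unlist(inv[a], use.names = FALSE))
      for (t in touching) {
        s <- a[a %in% trans[[t]]]   # intersection, stays sorted
        if (length(s) >= 2) {
          kk <- key_of(s)
          if (is.null(seen[[kk]])) {
            seen[[kk]] <- TRUE
            cands[[length(cands) + 1L]] <- s
            nxt[[length(nxt) + 1L]] <- s
          }
        }
      }
    }
    frontier <- nxt
  }

  support_of <- function(s) {
    ids <- inv[[s[1]]]
    for (v in s[-1]) {
      ids <- ids[ids %in% inv[[v]]]
      if (!length(ids)) break
    }
    length(ids)
  }
  supp <- vapply(cands, support_of, 0L)
  freq <- which(supp >= sc)
  edges <- cands[freq]
  weights <- supp[freq]
  # maximality: drop itemsets strictly contained in another frequent itemset
  if (length(edges) > 1) {
    ord <- order(lengths(edges), decreasing = TRUE)
    edges <- edges[ord]; weights <- weights[ord]
    keep <- rep(TRUE, length(edges))
    for (i in seq_along(edges)) {
      if (!keep[i]) next
      for (j in seq_len(i - 1L)) {
        if (keep[j] && length(edges[[i]]) < length(edges[[j]]) &&
            all(edges[[i]] %in% edges[[j]])) {
          keep[i] <- FALSE
          break
        }
      }
    }
    edges <- edges[keep]; weights <- weights[keep]
  }
  if (weighting == "sknn") {
    weights <- vapply(edges, function(e) {
      shared <- Reduce(intersect, knn[e])
      length(shared)
    }, 0L)
    ok <- weights >= sc
    edges <- edges[ok]; weights <- weights[ok]
  }
  structure(list(n_vertices = n, edges = edges,
                 weights = as.numeric(weights)),
            class = "snp_hypergraph")
}

#' @export
print.snp_hypergraph <- function(x, ...) {
  cat(sprintf("snp_hypergraph: %d vertices, %d hyperedges (total weight %g)\n",
              x$n_vertices, length(x$edges), sum(x$weights)))
  invisible(x)
}

#' Cut weight of a bipartition
#'
#' Sum of the weights of hyperedges with vertices on both sides.
#'
#' @param hg a \code{snp_hypergraph}.
#' @param side integer vector of side labels (two distinct values) per vertex.
#' @return numeric cut weight.
#' @export
cut_weight <- function(hg, side) {
  if (!length(hg$edges)) return(0)
  sum(hg$weights[vapply(hg$edges, function(e) {
    length(unique(side[e])) > 1
  }, TRUE)])
}

#' Connected components of a hypergraph
#'
#' Vertex groups linked through shared hyperedges. Any union of components
#' is a zero-cut side, so the components are the natural candidate CutSets
#' late in an assembly, when the remaining defects are whole weakly-tethered
#' clusters whose internal consistency is high but whose phase relative to
#' the rest is wrong.
#'
#' @param hg a \code{snp_hypergraph}.
#' @param min_size smallest component size to report.
#' @return list of integer vertex vectors.
#' @export
hypergraph_components <- function(hg, min_size = 2) {
  if (!length(hg$edges)) return(list())
  pairs <- do.call(rbind, lapply(hg$edges, function(e) {
    cbind(e[-length(e)], e[-1])
  }))
  g <- igraph::make_empty_graph(hg$n_vertices, directed = FALSE)
  g <- igraph::add_edges(g, t(pairs))
  comp <- igraph::components(g)$membership
  out <- split(seq_len(hg$n_vertices), comp)
  out <- out[lengths(out) >= min_size]
  names(out) <- NULL
  lapply(out, as.integer)
}

#' Bipartition a weighted SNP hypergraph
#'
#' Seeded multi-restart Fiduccia-Mattheyses move heuristic: each restart
#' begins from a balanced random split and repeats best-prefix improvement
#' passes until the cut stops decreasing; the best restart wins. Both sides
#' always hold at least \code{max(1, floor(balance_floor * n))} vertices.
#' Vertices in no hyperedge are placed by the (seeded) random split, hence
#' arbitrarily but deterministically.
#'
#' @param hg a \code{snp_hypergraph} with at least 2 vertices.
#' @param balance_floor minimum fraction of vertices on each side.
#' @param restarts number of random restarts.
#' @param seed optional integer seed (otherwise the current RNG stream is
#'   used).
#' @return a list of class \code{bipartition}: \code{side} (1/2 labels),
#'   \code{cut_weight}, and \code{cutset} (the vertices of the smaller side;
#'   ties go to side 1).
#' @export
partition_hypergraph <- function(hg, balance_floor = 0.2, restarts = 8,
                                 seed = NULL) {
  cand <- partition_candidates(hg, balance_floor, restarts, seed)
  cand[[which.min(vapply(cand, `[[`, 0, "cut_weight"))]]
}

#' All restart partitions of the FM heuristic
#'
#' Same search as \code{\link{partition_hypergraph}} but returning every
#' restart's local optimum (duplicates removed) instead of only the
#' smallest cut. The assembly loop scores each candidate CutSet by MEC, so
#' ties and near-ties in cut weight — which are frequent, since any
#' boundary not spanned by a hyperedge cuts at zero cost — are resolved by
#' the objective that actually matters.
#'
#' @inheritParams partition_hypergraph
#' @param mixed_balance when \code{TRUE}, half of the restarts run with the
#'   balance floor and half with an (almost) unconstrained floor of one
#'   vertex: balanced cuts repair large-scale phase structure, while
#'   low-balance cuts can isolate the small weakly-connected islands of
#'   defective SNPs that remain late in the assembly.
#' @return list of \code{bipartition} objects, ordered by cut weight.
#' @export
partition_candidates <- function(hg, balance_floor = 0.2, restarts = 8,
                                 seed = NULL, mixed_balance = FALSE) {
  stopifnot(inherits(hg, "snp_hypergraph"), hg$n_vertices >= 2, restarts >= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- hg$n_vertices
  min_side <- max(1L, as.integer(floor(balance_floor * n)))
  # restart schedule (cycle of 4): balanced/random, low/interval,
  # balanced/interval, low/interval
  min_sides <- rep(min_side, restarts)
  interval <- rep(0L, restarts)
  if (mixed_balance && restarts > 1) {
    phase <- (seq_len(restarts) - 1L) %% 4L
    min_sides[phase %in% c(1L, 3L)] <- 1L
    interval[phase != 0L] <- 1L
  }
  res <- cpp_fm_partition(hg$edges, hg$weights, n, min_sides, interval)
  ord <- order(res$cut_weights)
  out <- list()
  seen <- character(0)
  for (r in ord) {
    side <- res$sides[[r]]
    n1 <- sum(side == 1L)
    small <- if (n1 <= n - n1) 1L else 2L
    cutset <- which(side == small)
    key <- paste(cutset, collapse = " ")
    if (key %in% seen) next
    seen <- c(seen, key)
    out[[length(out) + 1L]] <- structure(
      list(side = side, cut_weight = res$cut_weights[r], cutset = cutset),
      class = "bipartition")
  }
  out
}

# Internal: extend a mined hypergraph with one pair edge per violated SNP
# pair (omega > 0), weighted by minus the summed violation so that the FM
# heuristic prefers cuts through inconsistent boundaries.
add_violation_edges <- function(hg, omega, tcount) {
  idx <- which(omega > 0 & tcount > 0 & upper.tri(omega), arr.ind = TRUE)
  if (!nrow(idx)) return(hg)
  ve <- lapply(seq_len(nrow(idx)), function(r) as.integer(idx[r, ]))
  vw <- -omega[idx] * tcount[idx]
  structure(list(n_vertices = hg$n_vertices,
                 edges = c(hg$edges, ve),
                 weights = c(hg$weights, vw)),
            class = "snp_hypergraph")
}
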