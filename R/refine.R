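#' Refinement configuration
#'
#' @param theta confidence threshold below which a locus is flagged for
#'   re-estimation. By default it applies to a coverage-normalised posterior
#'   (see \code{\link{locus_confidence_diploid}}); set
#'   \code{scale = "raw"} to threshold the raw emission product instead.
#' @param em delay-embedding dimension for the local projection (1 or 2).
#' @param k_lp neighbour count of the local-projection predictor.
#' @param default_q constant per-allele sequencing-error probability used
#'   when the fragment matrix carries no qualities.
#' @param min_length minimum number of (filtered) SNP columns for the
#'   refinement to run; shorter series do not support the delay-embedding
#'   prediction and pass through unchanged.
#' @param scale \code{"posterior"} or \code{"raw"} thresholding.
#' @return a list of class \code{refinement_config}.
#' @export
refinement_config <- function(theta = 0.9, em = 2, k_lp = 5,
                              default_q = 0.05, min_length = 500,
                              scale = c("posterior", "raw")) {
  stopifnot(em %in% c(1, 2), k_lp >= 1, default_q > 0, default_q < 1,
            theta > 0, theta < 1)
  structure(list(theta = theta, em = as.integer(em), k_lp = as.integer(k_lp),
                 default_q = default_q, min_length = as.integer(min_length),
                 scale = match.arg(scale)),
            class = "refinement_config")
}

#' Per-locus confidence of a diploid haplotype pair
#'
#' For each column j the emission probability is the product over covering
#' fragments of \code{1 - Q_ij} when the fragment's allele matches the allele
#' its assigned haplotype carries at j, and \code{Q_ij} on mismatch. Because
#' the raw product shrinks with coverage, the returned \code{posterior}
#' rescales it against the column-flipped alternative,
#' \code{P(X_j|h_j) / (P(X_j|h_j) + P(X_j|complement))}; an uncovered column
#' has raw emission 1 (empty product) and posterior 0.5.
#'
#' @param x a \code{\link{fragment_matrix}}.
#' @param h a diploid \code{\link{haplotype_set}}.
#' @param assignment fragment assignment (from
#'   \code{\link{assign_fragments}}).
#' @param default_q error probability used where \code{x$error_probs} is
#'   absent.
#' @return list with numeric vectors \code{raw} and \code{posterior}, one
#'   entry per column.
#' @export
locus_confidence_diploid <- function(x, h, assignment, default_q = 0.05) {
  stopifnot(inherits(x, "fragment_matrix"), inherits(h, "haplotype_set"),
            nrow(h) == 2, length(assignment) == n_fragments(x))
  n <- n_snps(x)
  a <- x$alleles
  q <- if (!is.null(x$error_probs)) x$error_probs else {
    qm <- a * 0 + default_q
    qm
  }
  hm <- unclass(h)
  expected <- hm[assignment, , drop = FALSE]  # allele of the assigned row
  match <- a == expected
  lmatch <- log1p(-q)
  lmis <- log(q)
  l1 <- ifelse(match, lmatch, lmis)   # NA at gaps
  l2 <- ifelse(match, lmis, lmatch)   # column-flipped alternative
  log_p1 <- colSums(l1, na.rm = TRUE)
  log_p2 <- colSums(l2, na.rm = TRUE)
  posterior <- 1 / (1 + exp(log_p2 - log_p1))
  list(raw = exp(log_p1), posterior = posterior)
}

#' Flag polyploid loci inconsistent with the genotype
#'
#' A locus is flagged when the multiset of alleles in the haplotype column
#' differs from the genotype's allele multiset, i.e. when the column's count
#' of `1` alleles differs from the genotype count.
#'
#' @param h a \code{\link{haplotype_set}}.
#' @param genotype integer vector of per-site `1`-allele counts.
#' @return integer vector of flagged column indices.
#' @export
flag_low_confidence_polyploid <- function(h, genotype) {
  stopifnot(inherits(h, "haplotype_set"), length(genotype) == ncol(h))
  which(colSums(unclass(h)) != as.integer(genotype))
}

#' Chaos-game coordinate series of a binary sequence
#'
#' Line CGR on [0, 1] with vertex 0 at coordinate 0 and vertex 1 at
#' coordinate 1: the first point is placed half-way between the centre (0.5)
#' and the vertex of the first symbol, and each subsequent point half-way
#' between the previous point and the current symbol's vertex. The map is
#' invertible: \code{v_j = 2 cs_j - cs_{j-1}}, and thresholding at 0.5
#' recovers the sequence exactly (\code{v_j = 1} iff \code{cs_j > 0.5}).
#'
#' @param v binary vector (no \code{NA}).
#' @return numeric vector of positions in (0, 1).
#' @export
cgr_map <- function(v) {
  stopifnot(length(v) >= 1, all(v %in% c(0L, 1L)))
  cs <- numeric(length(v))
  prev <- 0.5
  for (j in seq_along(v)) {
    prev <- (prev + v[j]) / 2
    cs[j] <- prev
  }
  cs
}

#' Threshold a coordinate series back to alleles
#'
#' @param cs numeric coordinate series.
#' @return integer vector: 1 where \code{cs > 0.5}, else 0 (the boundary maps
#'   to 0).
#' @export
cgr_threshold <- function(cs) as.integer(cs > 0.5)

#' Impute missing coordinate-series values by local projection
#'
#' Nearest-neighbour prediction in delay coordinates: for each missing index
#' j (in increasing order) the query is the vector of the \code{em} last
#' defined values preceding j; among all historical delay vectors (built
#' from runs of \code{em} consecutive originally-defined values followed by
#' a defined value) the \code{k_lp} nearest in Euclidean distance are found
#' and the mean of their successors, clipped to [0, 1], fills the gap.
#' Filled values count as defined for later gaps. A missing index with
#' fewer than \code{em} preceding values falls back to the mean of the
#' defined series.
#'
#' @param cs numeric series with \code{NA} at masked positions.
#' @param em embedding dimension (1 or 2).
#' @param k_lp neighbour count.
#' @return the series with missing values imputed. If fewer than
#'   \code{em + k_lp} values are defined the series is returned unchanged
#'   with a warning.
#' @export
local_projection_fill <- function(cs, em = 2, k_lp = 5) {
  stopifnot(em >= 1, k_lp >= 1)
  missing_idx <- which(is.na(cs))
  if (!length(missing_idx)) return(cs)
  defined <- which(!is.na(cs))
  if (length(defined) < em + k_lp) {
    warning("too few defined values for local projection; series returned unchanged")
    return(cs)
  }
  # history from originally-defined consecutive windows
  starts <- if (length(cs) > em) {
    which(vapply(seq_len(length(cs) - em), function(p) {
      all(!is.na(cs[p:(p + em)]))
    }, TRUE))
  } else integer(0)
  hist_mat <- do.call(rbind, lapply(starts, function(p) cs[p:(p + em - 1)]))
  hist_succ <- cs[starts + em]
  fallback <- mean(cs[defined])
  out <- cs
  for (j in missing_idx) {
    prior <- which(!is.na(out[seq_len(j - 1)]))
    if (length(prior) < em || is.null(hist_mat)) {
      out[j] <- min(1, max(0, fallback))
      next
    }
    qv <- out[prior[(length(prior) - em + 1):length(prior)]]
    d2 <- colSums((t(hist_mat) - qv)^2)
    nb <- order(d2)[seq_len(min(k_lp, length(d2)))]
    out[j] <- min(1, max(0, mean(hist_succ[nb])))
  }
  out
}

#' Refine low-confidence loci of an assembled haplotype set
#'
#' Diploid: loci whose confidence (see
#' \code{\link{locus_confidence_diploid}}) falls below \code{theta} are
#' flagged. Polyploid: loci whose column allele counts contradict the
#' genotype are flagged (no genotype: refinement is skipped with a warning).
#' Each haplotype row is mapped to its chaos-game coordinate series using
#' the current alleles for propagation; the series entries at flagged loci
#' are masked, imputed by \code{\link{local_projection_fill}}, and converted
#' back: a flagged locus becomes 0 when its imputed coordinate is <= 0.5 and
#' 1 otherwise. Unflagged loci are never touched. For diploid input the
#' second row is re-derived as the complement of the first.
#'
#' @param h the assembled \code{\link{haplotype_set}} (filtered
#'   coordinates).
#' @param x the \code{\link{fragment_matrix}} it was assembled from.
#' @param assignment fragment assignment against \code{h}.
#' @param genotype optional per-site `1`-allele counts (polyploid).
#' @param config a \code{\link{refinement_config}}.
#' @return the refined \code{haplotype_set}.
#' @export
refine_haplotypes <- function(h, x, assignment, genotype = NULL,
                              config = refinement_config()) {
  stopifnot(inherits(h, "haplotype_set"), inherits(config, "refinement_config"))
  if (ncol(h) < config$min_length) return(h)
  if (nrow(h) == 2) {
    conf <- locus_confidence_diploid(x, h, assignment, config$default_q)
    score <- if (config$scale == "posterior") conf$posterior else conf$raw
    flagged <- which(score < config$theta)
  } else {
    if (is.null(genotype)) {
      warning("polyploid refinement requires a genotype vector; skipped")
      return(h)
    }
    flagged <- flag_low_confidence_polyploid(h, genotype)
  }
  if (!length(flagged)) return(h)
  m <- unclass(h)
  rows <- if (nrow(m) == 2) 1L else seq_len(nrow(m))
  for (i in rows) {
    cs <- cgr_map(m[i, ])
    cs[flagged] <- NA_real_
    filled <- suppressWarnings(local_projection_fill(cs, config$em, config$k_lp))
    ok <- flagged[!is.na(filled[flagged])]
    m[i, ok] <- cgr_threshold(filled[ok])
  }
  if (nrow(m) == 2) m[2, ] <- 1L - m[1, ]
  haplotype_set(m)
}
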