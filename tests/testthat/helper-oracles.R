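# Independent brute-force oracles; deliberately naive and separate from the
# package's own code paths.

# direct double-loop MEC: assign each fragment to the nearest row, sum HDs
naive_mec <- function(x, h) {
  m <- x$alleles
  hm <- unclass(h)
  total <- 0
  for (i in seq_len(nrow(m))) {
    ds <- apply(hm, 1, function(row) {
      sum(!is.na(m[i, ]) & m[i, ] != row)
    })
    total <- total + min(ds)
  }
  total
}

# direct evaluation of the pair-consistency definition for every SNP pair
naive_omega <- function(x, h, assignment) {
  m <- x$alleles
  hm <- unclass(h)
  n <- ncol(m)
  omega <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    cov <- which(!is.na(m[, i]) & !is.na(m[, j]))
    if (!length(cov)) next
    terms <- vapply(cov, function(f) {
      fp <- paste0(m[f, i], m[f, j])
      hp <- paste0(hm[assignment[f], i], hm[assignment[f], j])
      if (fp == hp) -1 else 1
    }, 0)
    omega[i, j] <- mean(terms)
  }
  omega
}

# exhaustive minimum cut over all bipartitions respecting the balance floor
brute_min_cut <- function(hg, min_side) {
  n <- hg$n_vertices
  best <- Inf
  for (mask in 1:(2^n - 2)) {
    side <- as.integer(intToBits(mask)[seq_len(n)])
    s1 <- sum(side)
    if (s1 < min_side || n - s1 < min_side) next
    cut <- cut_weight(hg, side + 1L)
    if (cut < best) best <- cut
  }
  best
}

# exhaustive optimal row-mapping reconstruction rate for small P
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

brute_rr_polyploid <- function(truth, recon) {
  p <- nrow(truth)
  n <- ncol(truth)
  best <- Inf
  for (pm in all_perms(p)) {
    d <- sum(unclass(recon)[pm, , drop = FALSE] != unclass(truth))
    if (d < best) best <- d
  }
  1 - best / (n * p)
}

# random fragment matrix with gaps, for property tests
random_fragment_matrix <- function(m, n, gap_prob = 0.4) {
  a <- matrix(sample(c(0L, 1L), m * n, replace = TRUE), m, n)
  a[matrix(runif(m * n) < gap_prob, m, n)] <- NA_integer_
  # every fragment keeps at least one observed allele
  for (i in seq_len(m)) {
    if (all(is.na(a[i, ]))) a[i, sample(n, 1)] <- sample(c(0L, 1L), 1)
  }
  fragment_matrix(a)
}

random_hypergraph <- function(n, n_edges) {
  edges <- lapply(seq_len(n_edges), function(e) {
    sort(sample(n, sample(2:min(4, n), 1)))
  })
  structure(list(n_vertices = n, edges = edges,
                 weights = as.numeric(sample(1:5, n_edges, replace = TRUE))),
            class = "snp_hypergraph")
}

hap_from_strings <- function(...) {
  rows <- lapply(list(...), function(s) as.integer(strsplit(s, "")[[1]]))
  haplotype_set(do.call(rbind, rows))
}

frag_from_strings <- function(...) {
  rows <- lapply(list(...), function(s) {
    ch <- strsplit(s, "")[[1]]
    match(ch, c("0", "1")) - 1L  # '-' maps to NA
  })
  fragment_matrix(do.call(rbind, rows))
}
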