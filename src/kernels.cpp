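#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Hamming distance of fragment row i of X against haplotype row p of H,
// counting only non-gap fragment positions (gap = NA).
static inline int frag_hd(const IntegerMatrix& X, const IntegerMatrix& H,
                          int i, int p) {
  int d = 0, N = X.ncol();
  for (int j = 0; j < N; ++j) {
    int x = X(i, j);
    if (x != NA_INTEGER && x != H(p, j)) ++d;
  }
  return d;
}

// Assign each fragment to its nearest haplotype row (ties -> lowest row
// index) and accumulate the MEC score. Fragments with no covered SNP get
// assignment 1 and distance 0.
// [[Rcpp::export]]
List cpp_assign_mec(IntegerMatrix X, IntegerMatrix H) {
  int M = X.nrow(), P = H.nrow();
  IntegerVector assign(M), dist(M);
  double mec = 0.0;
  for (int i = 0; i < M; ++i) {
    int best = 0, bestd = frag_hd(X, H, i, 0);
    for (int p = 1; p < P; ++p) {
      int d = frag_hd(X, H, i, p);
      if (d < bestd) { bestd = d; best = p; }
    }
    assign[i] = best + 1;
    dist[i] = bestd;
    mec += bestd;
  }
  return List::create(_["assignment"] = assign, _["dist"] = dist,
                      _["mec"] = mec);
}

// Pair-SNP consistency matrix. For each fragment and each pair (i, j) of
// SNPs it covers, the term is -1 when the fragment's two-allele pattern
// equals the assigned haplotype's pattern at (i, j) and +1 otherwise;
// omega(i, j) averages the terms over covering fragments and is 0 where no
// fragment covers the pair. Returns omega plus the pair cover counts.
// [[Rcpp::export]]
List cpp_pair_consistency(IntegerMatrix X, IntegerMatrix H,
                          IntegerVector assignment) {
  int M = X.nrow(), N = X.ncol();
  NumericMatrix omega(N, N);
  IntegerMatrix tcount(N, N);
  std::vector<int> cov; cov.reserve(N);
  std::vector<char> match; match.reserve(N);
  for (int f = 0; f < M; ++f) {
    cov.clear(); match.clear();
    int hp = assignment[f] - 1;
    for (int j = 0; j < N; ++j) {
      int x = X(f, j);
      if (x != NA_INTEGER) {
        cov.push_back(j);
        match.push_back(x == H(hp, j) ? 1 : 0);
      }
    }
    int k = (int)cov.size();
    for (int a = 0; a < k; ++a) {
      for (int b = a + 1; b < k; ++b) {
        double term = (match[a] && match[b]) ? -1.0 : 1.0;
        omega(cov[a], cov[b]) += term;
        omega(cov[b], cov[a]) += term;
        tcount(cov[a], cov[b]) += 1;
        tcount(cov[b], cov[a]) += 1;
      }
    }
  }
  for (int i = 0; i < N; ++i)
    for (int j = 0; j < N; ++j)
      if (tcount(i, j) > 0) omega(i, j) /= tcount(i, j);
  return List::create(_["omega"] = omega, _["tcount"] = tcount);
}

struct HyperGraph {
  int n;
  std::vector<std::vector<int> > edges;  // 0-based vertex lists
  std::vector<double> w;
  std::vector<std::vector<int> > inc;    // vertex -> incident edge ids
};

static double cut_of(const HyperGraph& hg, const std::vector<char>& side) {
  double cut = 0.0;
  for (size_t e = 0; e < hg.edges.size(); ++e) {
    int c1 = 0, sz = (int)hg.edges[e].size();
    for (int v : hg.edges[e]) c1 += side[v];
    if (c1 > 0 && c1 < sz) cut += hg.w[e];
  }
  return cut;
}

// Gain of moving vertex v to the other side, given per-edge side-1 counts.
static double gain_of(const HyperGraph& hg, const std::vector<char>& side,
                      const std::vector<int>& cnt1, int v) {
  double g = 0.0;
  for (int e : hg.inc[v]) {
    int sz = (int)hg.edges[e].size();
    int a = side[v] ? cnt1[e] : sz - cnt1[e];  // count on v's side
    if (a == 1 && sz > 1) g += hg.w[e];        // edge becomes uncut
    else if (a == sz && sz > 1) g -= hg.w[e];  // edge becomes cut
  }
  return g;
}

// One Fiduccia-Mattheyses pass: move every vertex once in best-gain order
// (respecting the balance floor), then keep the best prefix if it strictly
// improves the cut. Returns the improvement achieved.
static double fm_pass(const HyperGraph& hg, std::vector<char>& side,
                      int min_side) {
  int n = hg.n;
  std::vector<int> cnt1(hg.edges.size(), 0);
  for (size_t e = 0; e < hg.edges.size(); ++e)
    for (int v : hg.edges[e]) cnt1[e] += side[v];
  int size1 = 0;
  for (int v = 0; v < n; ++v) size1 += side[v];

  std::vector<char> locked(n, 0), work = side;
  std::vector<double> gain(n);
  for (int v = 0; v < n; ++v) gain[v] = gain_of(hg, work, cnt1, v);

  std::vector<int> moved; moved.reserve(n);
  double cum = 0.0, best_cum = 0.0;
  int best_k = 0, size1w = size1;

  for (int step = 0; step < n; ++step) {
    int pick = -1; double bestg = 0.0;
    for (int v = 0; v < n; ++v) {
      if (locked[v]) continue;
      int src = work[v] ? size1w : n - size1w;
      if (src - 1 < min_side) continue;  // would starve v's side
      if (pick < 0 || gain[v] > bestg) { pick = v; bestg = gain[v]; }
    }
    if (pick < 0) break;
    // apply move
    locked[pick] = 1;
    cum += gain[pick];
    int from1 = work[pick];
    work[pick] = !work[pick];
    size1w += from1 ? -1 : 1;
    for (int e : hg.inc[pick]) cnt1[e] += from1 ? -1 : 1;
    moved.push_back(pick);
    if (cum > best_cum + 1e-12) { best_cum = cum; best_k = (int)moved.size(); }
    // refresh gains of vertices sharing an edge with the moved one
    for (int e : hg.inc[pick]) {
      for (int u : hg.edges[e]) {
        if (!locked[u]) gain[u] = gain_of(hg, work, cnt1, u);
      }
    }
  }
  if (best_cum <= 1e-12) return 0.0;
  for (int k = 0; k < best_k; ++k) side[moved[k]] = !side[moved[k]];
  return best_cum;
}

// Multi-restart FM bipartitioning of a weighted hypergraph. Initial sides
// are balanced random splits drawn from R's RNG (deterministic under
// set.seed). Returns the side labels (1/2) and the cut weight.
// [[Rcpp::export]]
List cpp_fm_partition(List edges, NumericVector w, int n,
                      IntegerVector min_sides, IntegerVector interval_init) {
  int restarts = min_sides.size();
  HyperGraph hg;
  hg.n = n;
  hg.inc.assign(n, std::vector<int>());
  for (int e = 0; e < edges.size(); ++e) {
    IntegerVector ev = edges[e];
    std::vector<int> vs(ev.size());
    for (int i = 0; i < ev.size(); ++i) {
      vs[i] = ev[i] - 1;
      hg.inc[vs[i]].push_back(e);
    }
    hg.edges.push_back(vs);
    hg.w.push_back(w[e]);
  }
  List sides(restarts);
  NumericVector cuts(restarts);
  for (int r = 0; r < restarts; ++r) {
    // initial split via R's RNG: either a balanced random split, or a
    // contiguous prefix interval (vertices are genomically ordered SNPs,
    // so the hyperedge structure is local and interval splits start close
    // to the cuts that matter)
    std::vector<char> side(n, 0);
    if (interval_init[r]) {
      // random contiguous interval: mis-phased runs of SNPs are intervals,
      // and FM slides interval boundaries onto the nearest zero-cost cut
      int lo = min_sides[r], hi = n - min_sides[r];
      if (lo > hi) { lo = 1; hi = n - 1; }
      int len = lo + (int)(unif_rand() * (hi - lo + 1));
      if (len > hi) len = hi;
      int start = (int)(unif_rand() * (n - len + 1));
      if (start > n - len) start = n - len;
      for (int i = start; i < start + len; ++i) side[i] = 1;
    } else {
      NumericVector u = runif(n);
      IntegerVector ord(n);
      for (int i = 0; i < n; ++i) ord[i] = i;
      std::sort(ord.begin(), ord.end(),
                [&](int a, int b) { return u[a] < u[b]; });
      for (int i = 0; i < n / 2; ++i) side[ord[i]] = 1;
    }
    while (true) {
      if (fm_pass(hg, side, min_sides[r]) <= 0.0) break;
    }
    cuts[r] = cut_of(hg, side);
    IntegerVector lab(n);
    for (int v = 0; v < n; ++v) lab[v] = side[v] ? 1 : 2;
    sides[r] = lab;
  }
  return List::create(_["sides"] = sides, _["cut_weights"] = cuts);
}

// MEC of the diploid haplotype pair after flipping both rows at columns
// 1..j, for every prefix length j = 0..N. Uses the complementary-pair
// structure: each covered fragment allele matches exactly one row, so
// flipping a column moves one mismatch between the rows. O(covered entries).
// [[Rcpp::export]]
NumericVector cpp_prefix_flip_mec(IntegerMatrix X, IntegerMatrix H) {
  int M = X.nrow(), N = X.ncol();
  std::vector<int> d1(M, 0), d2(M, 0);
  for (int i = 0; i < M; ++i) {
    for (int j = 0; j < N; ++j) {
      int x = X(i, j);
      if (x == NA_INTEGER) continue;
      if (x != H(0, j)) ++d1[i];
      if (x != H(1, j)) ++d2[i];
    }
  }
  double cur = 0.0;
  for (int i = 0; i < M; ++i) cur += std::min(d1[i], d2[i]);
  NumericVector out(N + 1);
  out[0] = cur;
  for (int j = 0; j < N; ++j) {
    for (int i = 0; i < M; ++i) {
      int x = X(i, j);
      if (x == NA_INTEGER) continue;
      cur -= std::min(d1[i], d2[i]);
      if (x == H(0, j)) { ++d1[i]; --d2[i]; } else { --d1[i]; ++d2[i]; }
      cur += std::min(d1[i], d2[i]);
    }
    out[j + 1] = cur;
  }
  return out;
}

// MEC change from flipping each single column of a diploid pair (both rows).
// delta[j] = sum over fragments covering j of the change in min(d1, d2).
// [[Rcpp::export]]
NumericVector cpp_column_flip_deltas(IntegerMatrix X, IntegerMatrix H) {
  int M = X.nrow(), N = X.ncol();
  std::vector<int> d1(M, 0), d2(M, 0);
  for (int i = 0; i < M; ++i) {
    for (int j = 0; j < N; ++j) {
      int x = X(i, j);
      if (x == NA_INTEGER) continue;
      if (x != H(0, j)) ++d1[i];
      if (x != H(1, j)) ++d2[i];
    }
  }
  NumericVector delta(N);
  for (int j = 0; j < N; ++j) {
    double dd = 0.0;
    for (int i = 0; i < M; ++i) {
      int x = X(i, j);
      if (x == NA_INTEGER) continue;
      int n1 = d1[i], n2 = d2[i];
      if (x == H(0, j)) { ++n1; --n2; } else { --n1; ++n2; }
      dd += std::min(n1, n2) - std::min(d1[i], d2[i]);
    }
    delta[j] = dd;
  }
  return delta;
}

// Greedy column polish for polyploid haplotypes: for each column, try every
// arrangement of the column's allele count (the genotype count when given)
// over the P rows and keep the best by MEC; sweeps repeat until stable.
// Returns the updated haplotype matrix.
// [[Rcpp::export]]
IntegerMatrix cpp_poly_column_polish(IntegerMatrix X, IntegerMatrix Hin,
                                     IntegerVector counts, int max_sweeps) {
  int M = X.nrow(), N = X.ncol(), P = Hin.nrow();
  IntegerMatrix H(clone(Hin));
  // distance matrix fragments x rows
  std::vector<std::vector<int> > D(M, std::vector<int>(P, 0));
  std::vector<std::vector<int> > covers(N);  // column -> fragments covering it
  for (int i = 0; i < M; ++i)
    for (int j = 0; j < N; ++j) {
      int x = X(i, j);
      if (x == NA_INTEGER) continue;
      covers[j].push_back(i);
      for (int p = 0; p < P; ++p)
        if (x != H(p, j)) ++D[i][p];
    }
  // enumerate binary patterns of length P grouped by popcount
  std::vector<std::vector<std::vector<int> > > pats(P + 1);
  for (int mask = 0; mask < (1 << P); ++mask) {
    std::vector<int> pat(P);
    int ones = 0;
    for (int p = 0; p < P; ++p) { pat[p] = (mask >> p) & 1; ones += pat[p]; }
    pats[ones].push_back(pat);
  }
  for (int sweep = 0; sweep < max_sweeps; ++sweep) {
    bool changed = false;
    for (int j = 0; j < N; ++j) {
      int k = counts[j];
      if (k < 0 || k > P) continue;
      const std::vector<int>& cov = covers[j];
      double best_contrib = R_PosInf;
      const std::vector<int>* best_pat = nullptr;
      for (const auto& pat : pats[k]) {
        double contrib = 0.0;
        for (int i : cov) {
          int mn = INT_MAX;
          int x = X(i, j);
          for (int p = 0; p < P; ++p) {
            int d = D[i][p] - (x != H(p, j) ? 1 : 0) + (x != pat[p] ? 1 : 0);
            if (d < mn) mn = d;
          }
          contrib += mn;
        }
        if (contrib < best_contrib - 1e-9) {
          best_contrib = contrib;
          best_pat = &pat;
        }
      }
      if (!best_pat) continue;
      bool same = true;
      for (int p = 0; p < P; ++p) if ((*best_pat)[p] != H(p, j)) same = false;
      if (same) continue;
      for (int i : cov) {
        int x = X(i, j);
        for (int p = 0; p < P; ++p)
          D[i][p] += (x != (*best_pat)[p] ? 1 : 0) - (x != H(p, j) ? 1 : 0);
      }
      for (int p = 0; p < P; ++p) H(p, j) = (*best_pat)[p];
      changed = true;
    }
    if (!changed) break;
  }
  return H;
}

// MEC of a polyploid haplotype set after applying row permutation q to the
// prefix of columns 1..j, for every prefix j = 0..N and every permutation
// in `perms` (rows, 1-based). Incremental in j: O(entries * P * n_perms).
// [[Rcpp::export]]
NumericMatrix cpp_prefix_perm_mec(IntegerMatrix X, IntegerMatrix H,
                                  IntegerMatrix perms) {
  int M = X.nrow(), N = X.ncol(), P = H.nrow(), Q = perms.nrow();
  std::vector<std::vector<int> > pre(M, std::vector<int>(P, 0));
  std::vector<std::vector<int> > tot(M, std::vector<int>(P, 0));
  std::vector<std::vector<int> > covers(N);
  for (int i = 0; i < M; ++i)
    for (int j = 0; j < N; ++j) {
      int x = X(i, j);
      if (x == NA_INTEGER) continue;
      covers[j].push_back(i);
      for (int p = 0; p < P; ++p)
        if (x != H(p, j)) ++tot[i][p];
    }
  // cost[i][q]: current min-row distance of fragment i under permutation q
  std::vector<std::vector<double> > cost(M, std::vector<double>(Q));
  NumericVector totq(Q);
  for (int i = 0; i < M; ++i) {
    for (int q = 0; q < Q; ++q) {
      int mn = INT_MAX;
      for (int p = 0; p < P; ++p) {
        int pp = perms(q, p) - 1;  // prefix rows come from pp
        int d = pre[i][pp] + tot[i][p] - pre[i][p];
        if (d < mn) mn = d;
      }
      cost[i][q] = mn;
      totq[q] += mn;
    }
  }
  NumericMatrix out(N + 1, Q);
  for (int q = 0; q < Q; ++q) out(0, q) = totq[q];
  for (int j = 0; j < N; ++j) {
    for (int i : covers[j]) {
      int x = X(i, j);
      for (int p = 0; p < P; ++p)
        if (x != H(p, j)) ++pre[i][p];
      for (int q = 0; q < Q; ++q) {
        int mn = INT_MAX;
        for (int p = 0; p < P; ++p) {
          int pp = perms(q, p) - 1;
          int d = pre[i][pp] + tot[i][p] - pre[i][p];
          if (d < mn) mn = d;
        }
        totq[q] += mn - cost[i][q];
        cost[i][q] = mn;
      }
    }
    for (int q = 0; q < Q; ++q) out(j + 1, q) = totq[q];
  }
  return out;
}
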