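---
title: "Haplotype assembly by hypergraph partitioning with chaos-game refinement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotype assembly by hypergraph partitioning with chaos-game refinement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrch)
```

## The problem

Single-individual haplotyping reconstructs the $P$ haplotype sequences
$H = \{h_1,\dots,h_P\}$, $h_i \in \{0,1\}^N$, of one organism from aligned
sequencing fragments. The input is the SNP matrix $X_{M\times N}$ over
$\{0,1,-\}$: each row is a fragment, each column a biallelic SNP site, and
`-` marks sites the fragment does not cover. Distances are gap-aware Hamming
distances: a position contributes 1 only when both sequences are non-gap and
unequal.

The clustering objective is minimum error correction,
$$\mathrm{MEC}(X,H) = \sum_{i=1}^{P}\sum_{f\in C_i} \mathrm{HD}(f, h_i),$$
where each fragment belongs to the cluster $C_i$ of its nearest haplotype.
On error-free data the true haplotypes reach MEC $=0$; with sequencing
errors, MEC counts the alleles that would have to be corrected. Exact MEC
optimisation is NP-hard, so the package implements a seeded stochastic
search.

## The iterative core

Assembly starts from a random haplotype set ($h_2 = \bar h_1$ for diploids,
independent uniform rows otherwise) and repeats, for up to `iterations`
rounds (default 100):

1. **Assignment.** Every fragment is assigned to its nearest haplotype row;
   ties go to the lowest row index so runs are reproducible.
2. **Pair-SNP consistency.** For each SNP pair $(i,j)$ jointly covered by
   $T_{ij}$ fragments,
   $$\omega_{ij} = \frac{1}{T_{ij}} \sum_{f \in \mathrm{cov}(i,j)}
     \begin{cases} -1 & \text{fragment pair pattern} = \text{assigned
     haplotype pair pattern} \\ +1 & \text{otherwise,} \end{cases}$$
   so $\omega_{ij}\in[-1,1]$, $-1$ meaning the current haplotypes explain
   every covering fragment at that pair and $0$ meaning the pair is never
   co-covered. Fragments with a gap at either site are excluded from the
   pair's cover set, whose concatenated patterns would otherwise be
   undefined.
3. **Hypergraph construction.** Each SNP's $k$ (default 5) most consistent
   partners (smallest $\omega$, ties to the lower index) form its neighbour
   set; each SNP contributes one transaction — its neighbour set plus
   itself — and maximal itemsets of size $\ge 2$ supported by at least `sc`
   (default 2) transactions become hyperedges weighted by their support.
   The miner enumerates the closure of the transactions under pairwise
   intersection, which yields exactly the closed (and hence all maximal)
   frequent itemsets at these transaction sizes; an alternative weighting by
   the number of shared neighbours is available (`edge_weighting = "sknn"`).
4. **Partitioning.** A multi-restart Fiduccia–Mattheyses heuristic
   bipartitions the SNPs. Violated pairs ($\omega_{ij}>0$) enter the
   partitioner's input as negative-weight pair edges, so minimising the cut
   simultaneously preserves consistent clusters and draws the boundary
   through inconsistencies — the property the consistency matrix is built
   to expose. Restarts mix balanced and nearly unconstrained floors and
   random versus contiguous-interval initial splits, because SNP indices
   are genomic positions and mis-phased runs are intervals.
5. **CutSet move.** Candidate CutSets are the smaller side of every restart,
   every connected component of the mined hypergraph (any union of
   components is a zero-cut side), the best prefix flip (diploid; an
   $O(\text{entries})$ sweep, since matrix-edge regions are tethered on one
   side only), and the best prefix row-permutation (polyploid). For
   diploids the CutSet columns are complemented in both rows — flipping the
   complementary set yields the same unordered pair, so one side suffices;
   for polyploids all $P!$ row permutations of the CutSet block are scored.
   The best candidate replaces the incumbent only on a *strict* MEC
   improvement: accepting MEC-equal moves lets the state drift between
   equal-score phasings and, empirically, out of good basins.
6. **Perturbation and polish.** A fraction `nc` (default 20%) of CutSet
   SNPs is drawn and processed in pairs; each pair receives a random
   allele-column substitution (heterozygous columns for diploids;
   genotype-count-preserving columns for polyploids) kept only if MEC does
   not increase. The same move class is then applied greedily: diploids
   flip the steepest single column while it strictly lowers MEC, polyploids
   run a per-column coordinate descent over genotype-consistent
   arrangements.

The loop stops at `iterations`, when MEC reaches zero, or after `patience`
(default 15) rounds without strict improvement. The accepted-MEC trace is
non-increasing by construction.

### Diploid preprocessing

For diploid input, the most frequent allele among the non-gap entries of
each column is computed and columns whose frequency strictly exceeds 0.8
are removed as homozygote sites, along with all-gap columns (their
frequency is undefined and they break reconstruction-rate denominators).
The comparison is strict, so a 4:1 column (frequency exactly 0.8) is kept.
The filter is not applied to polyploid input. A `column_map` records the
surviving columns so results can be reported in original coordinates
(`expand_haplotypes()` fills removed columns with the majority allele).

## Confidence scoring and chaos-game refinement

After the iterative phase, each locus gets a confidence score. For diploids
the emission probability of column $j$ multiplies, over covering fragments,
$1-Q_{ij}$ on a match against the assigned haplotype's allele and $Q_{ij}$
on a mismatch, where $Q$ holds per-entry error probabilities (Phred-decoded
from hapcut qualities, or the constant `default_q = 0.05`). Because the raw
product shrinks with coverage, thresholding uses the coverage-normalised
posterior $P(X_j\mid h_j) / (P(X_j\mid h_j) + P(X_j\mid \bar h_j))$ by
default ($\theta = 0.9$); raw-product thresholding is available
(`scale = "raw"`). For polyploids a locus is flagged when its column's
allele multiset contradicts the genotype's allele counts; without a
genotype the refinement is skipped with a warning.

Each haplotype row is then mapped to the unit interval by the line
chaos-game representation: $cs_1 = (0.5 + v_1)/2$ and
$cs_j = (cs_{j-1} + v_j)/2$, vertex 0 at coordinate 0 and vertex 1 at 1.
The map is exactly invertible and thresholding at 0.5 recovers the sequence
($v_j = 1 \iff cs_j > 0.5$; the boundary maps to 0). Series entries at
flagged loci are masked (propagation itself uses the current alleles) and
imputed by a local-projection predictor: the query is the `em` (1 or 2)
last defined values before the gap, its `k_lp = 5` nearest historical delay
vectors are found, and the mean of their successors, clipped to $[0,1]$,
fills the gap; filled values count as defined for later gaps, and a gap
with too short a history falls back to the series mean. Flagged loci are
converted back through the 0.5 threshold; unflagged loci are never touched,
and the diploid second row is re-derived as the complement of the first.

Delay-embedding prediction needs a long series, so refinement runs only
when at least `min_length = 500` columns survive preprocessing — in the
benchmark grids, the length-700 instances.

## The synthetic benchmark generator

`simulate_haplotypes()` + `simulate_fragments()` emulate the structure of
the classic diploid and polyploid simulation benchmarks: a complementary
(all-heterozygous) haplotype pair, or $P$ uniform rows with monomorphic
columns resampled; contiguous-block fragments whose source row is uniform;
symmetric allele flips at rate $e$; gap-dominated rows.

Defaults, chosen once and fixed:

* fragment span uniform on $[3, 7]$ SNPs at $l = 100$, scaling linearly
  with $l$ (mean span $\approx l/20$);
* with probability 0.5 a fragment is a mate pair: two read blocks around an
  uncovered insert of 1–3 SNPs, which *extends* the fragment's reach (the
  standard mate-pair reading of an interior gap);
* fragments are drawn until the observed-allele total reaches
  $c \cdot l$ *and* every column is covered; while uncovered columns
  remain, placement is steered onto one of them. This enforces the
  coverage floor constructively — naive rejection of instances with an
  uncovered column would essentially never terminate at $c = 3$ — while
  keeping mean coverage at the target.

What the generator does *not* emulate: read-level sequence errors and
indels, quality-value distributions, LD structure in the truth rows
(they are uniform), non-biallelic sites, and — importantly — the fragment
length distribution of the original benchmark data, which is not publicly
documented. Passing tests therefore demonstrate correct behaviour under
*this* fragment model, not performance on any particular real dataset.

### Connected blocks and the reconstruction rate

The diploid reconstruction rate is
$RR = 1 - \frac{1}{2N}\min(\mathrm{HD}(h_1,\hat h_1)+\mathrm{HD}(h_2,\hat h_2),
\mathrm{HD}(h_1,\hat h_2)+\mathrm{HD}(h_2,\hat h_1))$; the polyploid form
minimises over all one-to-one row mappings, solved by maximum-weight
bipartite matching (an exhaustive $P!$ search is the test oracle).
`rr_diploid()`/`rr_polyploid()` implement these global definitions exactly.

With short fragments at low coverage an instance usually splits into
several connected blocks (column sets linked by no fragment), and the
relative phase between blocks is not identifiable by any method. Benchmark
evaluation therefore reports the length-weighted mean of per-block rates
(`reconstruction_rate(truth, recon, blocks)`), which equals the global rate
whenever the instance is a single block. Rates are computed in
kept-column coordinates; re-expansion through the column map is available
when original-coordinate reporting is needed.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `iterations` | 100 | improvement rounds |
| `k` | 5 | consistency neighbours per SNP |
| `sc` | 2 | minimum support of a hyperedge (transactions) |
| `nc` | 0.20 | fraction of CutSet SNPs perturbed per round |
| `patience` | 15 | rounds without strict improvement before stopping |
| `balance_floor` | 0.2 | minimum side fraction for balanced FM restarts |
| `restarts` | 8 | FM restarts per round |
| `homozygous_threshold` | 0.8 | diploid column-removal frequency (strict) |
| `theta` | 0.9 | posterior confidence threshold for refinement |
| `em` | 2 | local-projection embedding dimension |
| `k_lp` | 5 | local-projection neighbours |
| `default_q` | 0.05 | error probability when qualities are absent |
| `min_length` | 500 | minimum columns for refinement |

## Numerical and design choices

* Assignment ties, neighbour-rank ties and the FM move-selection ties all
  break toward the lowest index; every stochastic step draws from R's RNG,
  so a single `seed` reproduces an entire run bit-for-bit.
* The consistency comparison follows the literal pattern-equality rule: the
  term is $-1$ exactly when the fragment matches its assigned haplotype at
  *both* sites. Relative to the assigned (nearest) haplotype this
  approximates phase agreement, and it is invariant under joint relabeling
  of a column pair in fragments and haplotypes together.
* `perturb_pairs` interprets "preserving allele counts" against the
  genotype when one is supplied (this also repairs columns whose counts the
  random initialisation got wrong) and against the current column
  otherwise.
* The polyploid permutation search is capped at $P \le 6$ ($P! \le 720$
  candidate blocks); beyond that the exhaustive search refuses and asks for
  a sampled subset.
* Degenerate inputs: empty or all-gap matrices are rejected; an all-gap
  column is dropped by preprocessing at any ploidy; a hypergraph with no
  edges skips the CutSet move for that round; `k` is clamped to $N'-1$ with
  a warning.
* A CGR coordinate of exactly 0.5 converts to allele 0 (the threshold rule
  uses $\le$).

## Known limitations

* MEC is the objective, and at weak junctions it can *prefer* a wrong
  phasing: if the few alleles tethering two regions are themselves
  sequencing errors, the mis-phased state scores strictly better. Under
  this generator's short spans this dominates residual error in the noisy
  length-100 regime; it is an identifiability limit of the fragment model,
  not a search failure (greedy descent started from the truth confirms the
  search reaches MEC at or below the truth's score).
* Low-coverage polyploid instances (c ≤ 10 with spans of ~5 SNPs) are
  substantially under-determined for the same reason; the packaged
  qualitative check runs the triploid comparison at c = 15, the mid-point
  of the polyploid benchmark grid, where the instances carry enough linkage
  for the comparison to be meaningful.
* The local-projection predictor exploits serial dependence in the
  coordinate series; on uniform-random truth haplotypes its gain comes
  from re-estimating confidently-wrong loci rather than from long-range
  structure, and it is near-neutral when the flagged loci are genuinely
  ambiguous.
* Phasing across disconnected blocks, reference panels, indels and
  non-biallelic sites are out of scope.

## Problem sizes in the packaged checks

The test-suite experiments use the benchmark operating point
($t=100$, $k=5$, $sc=2$, $nc=20\%$) on 30 instances of $l=100$ at $c=3$
(error-free) and $c=8$ ($e=0.1$), 10 instances of $l=700$ at $c=10$
(error-free), 30 corrupted-haplotype refinement instances at $l=700$, and
6 triploid instances at $l=100$, $c=15$, $e=0.1$; property tests run on
matrices of up to ~14 SNPs where exhaustive enumeration is the oracle.
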