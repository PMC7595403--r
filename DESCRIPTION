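Package: hrch
Title: Haplotype Assembly by Weighted-Hypergraph Partitioning with
    Chaos-Game Refinement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Single-individual haplotype assembly for diploid and polyploid
    genomes under the minimum error correction (MEC) objective. A randomly
    initialised haplotype set is improved iteratively: fragments are assigned
    to their nearest haplotypes, pair-SNP consistency is summarised in a
    weighted hypergraph via shared k-nearest-neighbour frequent itemsets, and
    bipartitioning the hypergraph yields a CutSet of SNPs whose alleles are
    flipped (diploid) or re-permuted (polyploid) whenever the move does not
    increase MEC. Low-confidence loci of the finished haplotypes are refined
    by mapping each haplotype to a chaos-game coordinate series and imputing
    masked positions with a local-projection predictor. Includes a
    benchmark-style fragment simulator (gapped, error-injected contiguous
    reads at a target coverage), reconstruction-rate metrics, and fragment
    file I/O, so the full pipeline can be exercised without external data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
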