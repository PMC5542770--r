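Package: pdatools
Title: Phylogenetic Discriminant Analysis of Alignment Positions and
    Ensemble Paralog-Matched Direct Coupling Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Supervised discriminant analysis of multiple sequence
    alignments: scores every position triplet of a phylogenetically
    annotated alignment by the cluster-purity (Shannon mixing entropy) of
    sequences embedded in a principal-component subspace of the reduced
    three-column alignment, with empirical p-values, per-position
    selection frequencies and a uniform-prior null model for calling
    discriminating positions.  Also implements an ensemble
    random-paralog-matching strategy for inter-protein direct coupling
    analysis: per-organism one-to-one matchings, a regularized mean-field
    coupling scorer with average-product correction, and aggregation of
    inter-protein residue pairs that recur across matching realizations.
    Includes alignment filters (gap fraction, zinc-finger motif
    disambiguation), synthetic-data generators with planted ground truth,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    optparse,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
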