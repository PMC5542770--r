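---
title: "Methods: entropy-based discriminant analysis of alignment positions and ensemble paralog-matched DCA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: entropy-based discriminant analysis of alignment positions and ensemble paralog-matched DCA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdatools)
```

# The scientific problem

Protein families with a shared fold often split into phylogenetic or
functional sub-classes — for example the class A and class B J-proteins
(Hsp70 cochaperones), where class A carries a zinc-finger-like region and
the two classes play distinct, partly cooperative roles in
disaggregation.  Two questions recur for such families:

1. **Which alignment positions discriminate the sub-classes?**  Single
   conserved positions rarely suffice; small *combinations* of positions
   often carry the class signal.
2. **Which residue pairs co-evolve between two interacting families?**
   Direct coupling analysis (DCA) answers this for concatenated
   alignments of interacting partners, but in eukaryotes the pairing of
   paralogs within an organism is unknown, and genomic-adjacency tricks
   that work for bacterial operons do not transfer.

`pdatools` implements one method for each question, plus the alignment
filters both need and synthetic generators that make every stage testable
with known ground truth.

# Phylogenetic discriminant analysis (PDA)

## The procedure

For a phylogenetically annotated alignment of width $N_{pos}$, every
position triplet $(i<j<k)$ is scored as follows:

1. **Reduce** the alignment to the three columns and one-hot encode each
   sequence over the 22-symbol alphabet (20 amino acids, `X`, gap), giving
   a point in $\{0,1\}^{66}$ with exactly three ones.
2. **Project** by PCA onto the leading components that explain a fraction
   `variance_kept` (default 0.95) of the variance.
3. **Cluster** the projected sequences by agglomerative hierarchical
   clustering (average linkage by default) on Euclidean distances, cutting
   the dendrogram at a height equal to the *average pairwise sequence
   distance*.  The number of clusters is therefore data-driven, never
   chosen by hand.  Merges at exactly the cutoff height are kept merged,
   which fixes the two-sequence boundary case deterministically (two
   distinct points form one cluster).
4. **Score** the clustering by the mixing entropy
   $$H(C) = \sum_{c \in C} w(c)\, h(c), \qquad
     h(c) = -\sum_i P(i_c)\,\log P(i_c),$$
   where $P(i_c)$ is the fraction of cluster $c$ belonging to
   phylogenetic group $i$ and $w(c)$ is the fraction of sequences in
   $c$.  $H$ is the cluster-size-weighted average Shannon entropy of the
   group labels: $H = 0$ means every cluster is pure, so the triplet
   separates the groups perfectly; large $H$ (up to $\log G$ for $G$
   groups) means the clusters mix the groups thoroughly.

The scan is exhaustive over all $\binom{N_{pos}}{3}$ triplets when
affordable (54,740 at the J-domain width of 70) and a uniform random
subsample (50,000 by default) otherwise.

A triplet's **empirical p-value** is the fraction of scanned triplets
with equal or lower $H$ (self-inclusive, so the minimum is $1/T$).  A
**reference score** converts the table into a position-level signal:
either the score of a biologically motivated reference triplet (such as
the experimentally characterized RRR charge-reversal triplet), or, when
none exists, the score delimiting a low percentile of the $H$
distribution (default the 5th).  The **selection frequency** of position
$i$ is the fraction of strongly discriminating triplets containing $i$.
In reference-triplet mode "strongly discriminating" means strictly lower
$H$ than the reference, so the reference triplet is never in its own
selected set; in percentile mode ties at the cut are included, because a
percentile cut with strict selection would select nothing whenever the
low tail is degenerate at a single value (with a perfectly pure planted
triplet a third of all triplets score exactly 0).  Frequencies always sum
to exactly 3 when any triplet is selected.

## The null model and its limits

Under a uniform prior — selected triplets spread evenly over positions —
each position's expected frequency is $p_{null} = 3/N_{pos}$ with
standard error $\sigma_p = \sqrt{p_{null}(1-p_{null})/m}$ for $m$
selected triplets.  Positions above $p_{null} + k\sigma_p$ are reported
at the $k\sigma$ level; the conservative default reports both $3\sigma$
and $10\sigma$ calls.

This null is deliberately simple and *understates* the spread of
frequencies on real (and realistic synthetic) data, for a structural
reason worth knowing: all $\binom{N_{pos}-1}{2}$ triplets containing a
given column move together.  If one column happens to correlate with the
group labels — which occurs by chance in finite samples — all of its
triplets shift coherently into the low-$H$ tail, so the effective number
of independent draws behind a frequency is closer to $N_{pos}$ than to
$m$.  On signal-free data (purity 0, permuted labels, $2\times100$
sequences, $N_{pos}=25$) we measure that the single most label-associated
column (by chi-square, a chance association) crosses the $10\sigma$
threshold in roughly a fifth of replicates, while the across-position
mean frequency always sits at $3/N_{pos}$ exactly.  The $10\sigma$ call
should therefore be read as "extremely concentrated relative to a
uniform prior", not as a calibrated $10^{-23}$ tail probability; that is
also why the package reports the $3\sigma$ level alongside.

## Robustness checks

`regroup_and_rescan()` repeats the analysis under a coarser or finer
partition of the group labels (e.g. two super-kingdoms vs six clades) —
discriminating positions should be stable.  Subsample stability is
checked by splitting the triplet set into disjoint halves: the frequency
profiles of the halves should agree (linear correlation of the profiles
and identity of the top positions).  Rank correlation across *all*
positions is not a meaningful stability measure here, because background
positions are exchangeable and their relative ranks are pure noise.

# Ensemble paralog-matched DCA

## The pairing problem

To detect inter-family couplings, DCA needs a concatenated alignment in
which each record joins two sequences that actually interact.  With
paralogs, per-organism pairing is unknown, paralog counts vary across
organisms, and matching all-against-all dilutes the signal.  The
strategy implemented here: draw a random one-to-one matching per
organism (each A sequence paired with a distinct, uniformly chosen B
sequence of the same organism; the excess side subsampled uniformly),
concatenate, score couplings, and repeat for $R$ realizations (default
300).  A residue pair is **recorded** in a realization when its
normalized coupling score reaches `score_threshold` (default 0.8) and
**selected** overall when it is recorded in at least
`appearance_threshold` (default 5%) of realizations.  Couplings that
depend on a particular lucky matching wash out; couplings robust across
matchings recur.

Realizations with identical matchings (inevitable when organisms carry a
single paralog per family) reuse cached scores, which changes nothing in
the results.

## The built-in coupling scorer

The default scorer is a regularized mean-field DCA, deterministic and
fast enough for desk-scale ensembles:

* sequences reweighted by $1/n_s$, where $n_s$ counts alignment members
  within 90% full-width identity (gap-gap columns count as matches);
* weighted single and pair frequencies over the 20 non-gap states
  (`X` and unknown letters are pooled with the gap state);
* a shrinkage covariance with relative pseudocount $\lambda$ (default
  0.5): off-diagonal blocks $(1-\lambda)(f_{ij} - f_i f_j)$, diagonal
  blocks the smoothed multinomial covariance
  $\mathrm{diag}(\tilde f_i) - \tilde f_i \tilde f_i^\top$ with
  $\tilde f_i = (1-\lambda) f_i + \lambda/q$.  Smoothing joint and
  marginal frequencies separately — the textbook mean-field recipe —
  leaves a spurious covariance
  $\lambda(1-\lambda)(f_i - 1/q)(f_j - 1/q)$ between *independent*
  columns, which is maximal for conserved ones and can dominate the
  final ranking; the shrinkage form vanishes exactly for independent or
  strictly conserved column pairs, which restores the property that a
  conserved-column pair never outscores a genuinely covarying one;
* couplings $J = -C^{-1}$, scored per position pair by the Frobenius
  norm of the zero-sum-gauge coupling block, followed by the average
  product correction (APC);
* only inter-family (A-block × B-block) pairs are thresholded; scores
  are min-max normalized within each realization so the 0.8 threshold
  is scale-free (a single pair normalizes to 1 by convention; an
  all-equal score vector normalizes to all zeros — both warn).

The asymmetric pseudo-likelihood scorer used in large-scale studies is
not reimplemented; `ensemble_dca(scorer = ...)` accepts any function
with the same contract, so such a scorer can be plugged in.

# Alignment filters

Two pre-processing rules are provided. `filter_by_gap_fraction()` drops
records with *more than* 20% gaps (ties at exactly 20% are kept — the
rule is a strict inequality).  `partition_by_motif()` disambiguates
classes by the zinc-finger signature `CxxCxGxG`, counted in possibly
overlapping windows on the complete unaligned sequence: at least two
motifs for class A (the canonical zinc finger has four, but a glycine is
variable in some lineages), zero for class B, everything else
unassigned.  `X` satisfies the wildcard slots, never the literal C/G
slots; ambiguity codes beyond `X` are deliberately not special-cased.

# The synthetic generators

`make_grouped_msa()` emulates the structure PDA assumes: background
columns i.i.d. uniform over the 20 amino acids, and a planted triplet
where each sequence carries its group's signature residue with
probability `purity` (signatures drawn deterministically from a fixed
amino-acid ordering, distinct across groups within each column, so
fixtures are stable).  `purity = 1` makes the triplet a perfect
discriminator; `purity = 0` makes the planted columns exactly
background.

`make_paired_family()` emulates the inter-protein coevolution structure
the matching strategy assumes: per-organism paralogs with a recorded
true-partner map, and planted column pairs where — in true partners
only — the family B residue follows a fixed residue permutation of the
family A residue with probability `coupling_strength`.  Both planted
columns keep the uniform background marginal, so the coupling lives
purely in the joint distribution.  An earlier design restricted planted
columns to a two-residue alphabet; it was abandoned because two binary
columns among 20-state background form the top APC-corrected pair even
at zero coupling strength — a marginal-composition artifact that
violated the generator's contract that `coupling_strength = 0` is
indistinguishable from background.

What the generators do **not** emulate: phylogenetic correlation between
sequences (no tree-based evolution), indels, composition bias, or
alignment error.  Passing tests on these fixtures therefore demonstrate
that the machinery recovers the signals it is designed for under clean
conditions; they do not quantify performance on real alignments, where
phylogenetic autocorrelation in particular inflates apparent couplings
and class signals.

# Numerical choices and conventions

* Positions, cluster labels and residue indices are 1-based everywhere,
  including file outputs.
* Logarithms are natural; rankings and empirical p-values are
  base-invariant.
* PCA component signs follow the largest-magnitude-loading-positive
  convention, so projections are deterministic.
* Zero-variance encodings project to a single all-zero coordinate and
  cluster into one cluster.
* The percentile reference uses the empirical distribution without
  interpolation: for 100 scores the 5th percentile is the 5th-smallest.
* Every stochastic step (triplet subsampling, matchings, generators)
  takes an explicit integer seed and records it in its output; repeated
  runs are bit-identical.
* Problem sizes used in the test-suite study conditions: planted-triplet
  recovery and null calibration scan all 2,300 triplets of a 25-column,
  200-sequence alignment over 20 replicate seeds; ensemble recovery uses
  60 organisms, 20+20 columns and 50 realizations.  These sizes give
  each check enough replicates for a stable pass/fail verdict while
  keeping a full run on one CPU in minutes.

# Known limitations

* The uniform-prior null is anti-conservative position-wise (see above);
  treat $k\sigma$ calls as rankings with a conventional cutoff.
* Mean-field DCA with strong shrinkage underestimates couplings for
  small effective sequence numbers; the ensemble appearance fraction is
  the robust quantity, not the raw score.
* Min-max normalization guarantees some pair reaches 1.0 in every
  realization, so with only one realization (deterministic matching) at
  least one pair is always recorded; selection is meaningful relative to
  the recurrence threshold, not per-realization.
* Modularity-based clustering, used elsewhere as a robustness check for
  the clustering step, is not built in; `cluster_sequences()` is the
  single clustering implementation and alternatives must be applied
  upstream by the caller.
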