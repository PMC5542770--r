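# pdatools

Supervised analysis of phylogenetically annotated protein alignments,
built around two methods:

* **Phylogenetic discriminant analysis (PDA)** — given a multiple
  sequence alignment whose sequences carry phylogenetic group labels,
  score every position triplet `(i < j < k)` by how cleanly the
  sequences, clustered on just those three columns, separate the
  groups.  The score is the mixing entropy

  `H(C) = Σ_c w(c) h(c)`,  `h(c) = −Σ_i P(i_c) log P(i_c)`,

  the cluster-size-weighted Shannon entropy of group labels within
  clusters formed in a PCA subspace of the one-hot-encoded three-column
  alignment (hierarchical clustering, dendrogram cut at the average
  pairwise distance).  `H = 0` means the triplet discriminates the
  groups perfectly.  The scan yields empirical p-values, per-position
  selection frequencies among the strongly discriminating triplets, and
  discriminating-position calls against a uniform-prior null
  (`p_null = 3/N_pos`, `σ_p = sqrt(p_null(1−p_null)/m)`, 3σ and 10σ
  levels).

* **Ensemble paralog-matched DCA** — for two interacting protein
  families whose within-organism paralog pairing is unknown, draw many
  random one-to-one per-organism matchings, concatenate each matched
  alignment, score inter-family residue couplings with a regularized
  mean-field DCA (90%-identity reweighting, zero-sum-gauge Frobenius
  norm, average-product correction), and select the residue pairs whose
  normalized score clears 0.8 in at least 5% of the (default 300)
  realizations.  Robust couplings recur across matchings; artifacts of
  any one matching wash out.

Supporting modules: FASTA/Stockholm alignment I/O, the `>20%`-gap
record filter, zinc-finger `CxxCxGxG` motif counting for class A/B
disambiguation, synthetic-data generators with planted ground truth,
and a command-line interface (`filter`, `pda`, `dca`, `simulate`).

Intended users: molecular evolution and coevolution researchers who
have annotated alignments of a sub-classified protein family (the
motivating case: class A/B J-protein cochaperones) and want to locate
class-discriminating positions or inter-family contact candidates
without trusting any single paralog pairing.

## Worked example

```r
library(pdatools)

## a 25-column alignment, two groups of 100 sequences, with a perfectly
## discriminating triplet planted at positions 3, 11, 20
fx <- make_grouped_msa(c(bacteria = 100, eukaryotes = 100), 25,
                       planted_triplet = c(3, 11, 20), purity = 1,
                       seed = 42)
res <- run_pda(fx$alignment, fx$annotations, mode = "exhaustive")
res
#> Phylogenetic discriminant analysis (exhaustive scan, 2300 triplets)
#>   reference H = 0.000000 (percentile), empirical p = 0.2496
#>   selected triplets m = 574
#>   positions above 3-sigma: 3, 11, 20
#>   positions above 10-sigma: 3, 11, 20

round(head(sort(res$selection_frequency, decreasing = TRUE), 5), 3)
#> [1] 0.373 0.373 0.373 0.105 0.099
```

Reading the output: the reference score is the 5th percentile of the H
distribution, here 0 because a quarter of all triplets (every triplet
touching a planted position) separates the two groups perfectly — that
fraction is the empirical p-value 0.2496.  Each planted position
appears in 37.3% of the 574 selected triplets, far above the uniform
expectation 3/25 = 0.12 plus ten standard errors (0.256), so exactly
the three planted positions are called at 10σ.

```r
## two interacting families, 60 organisms, one paralog each, with a
## coupled column pair planted at (A:3, B:7)
pfx <- make_paired_family(60, N_a = 20, N_b = 20,
                          planted_pairs = list(c(3, 7)),
                          coupling_strength = 0.9, seed = 42)
ens <- ensemble_dca(pfx$family, R = 50, base_seed = 42)
ens
#> Ensemble DCA: 50 realizations, score >= 0.80, appearance >= 0.05
#>   1 inter-protein pair(s) selected
#>   pos_a pos_b appearance_fraction
#> 1     3     7                   1
```

The planted pair is the only selection: its normalized coupling clears
the 0.8 threshold in every realization (appearance fraction 1 ≥ 0.05).

The same pipelines are scriptable:

```sh
inst/bin/pdatools simulate --type grouped --groups A:100,B:100 \
    --n-pos 25 --planted-triplet 3,11,20 --seed 42 --out-prefix fix
inst/bin/pdatools pda --msa fix.fasta --annotations fix.tsv \
    --mode exhaustive --out-prefix run1
```

## Documentation

The methods vignette (`vignettes/methods.Rmd`) documents the model, the
tunable parameters and defaults, the null model and its known limits,
the coupling scorer, what the synthetic generators do and do not
emulate, and the package's numerical conventions.
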