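# cistf

Predicting transcription factors (TFs) that bind short cis-regulatory
sequences conserved in the promoters of co-regulated genes — and
benchmarking those predictions against experimentally verified
(yeast one-hybrid) TF–DNA interactions.

Finding conserved promoter motifs in a set of co-induced genes is easy;
naming the proteins that bind them is not. `cistf` implements the
database-assisted route for regulatory genomicists: compare the query
motif against an annotated motif–TF database, transfer the cognate TFs
to a target proteome by homology, and keep only candidates whose
DNA-contacting residues are conserved.

## The method

For a query cis-sequence (or position frequency matrix) *q*:

1. **Motif similarity.** *q* is aligned (ungapped, both strands, mean
   per-column Pearson correlation *r̄* over ≥ 5 overlapping columns)
   against every database motif. Significance uses the summed statistic
   *S = r̄·k* over *k* aligned columns; the tail *P(S ≥ s)* is computed
   by exact convolution of an empirical column-score null built from
   seeded, column-shuffled decoys, and *E = N·p* over the *N* database
   motifs. Default cutoff *E* ≤ 1e-3.
2. **Homology transfer.** TFs linked to the similar motifs are aligned
   (Smith–Waterman, BLOSUM62, gaps 11/1) against the target proteome;
   Karlin–Altschul significance *E = K·m·n·e^(−λS)* with λ = 0.267,
   K = 0.041. Default cutoff *E* ≤ 1e-10.
3. **Interface filter.** Interface residues are protein residues with a
   heavy atom within 4.5 Å of a DNA base atom in a protein–DNA complex
   structure. A candidate is kept when ≥ 50% of the database TF's
   interface positions align to residues with a positive BLOSUM62
   score.
4. **Benchmark.** Predictions are scored against a packaged gold
   standard of verified interactions (sensitivity, specificity over a
   candidate universe, predictions per validated TF), with parameter
   sweeps and a predictable/unpredictable classification per element.

Supporting modules: motif I/O (TRANSFAC, MEME minimal, JASPAR PFM),
UPGMA motif-family trees with Newick export and branch-length cutting,
promoter extraction/scanning with a hypergeometric "in-silico
expression" drought filter, a seeded synthetic-data generator with
planted ground truth, and a command-line front-end
(`inst/cli/cistf.R`: `compare`, `cluster`, `predict`, `scan`,
`expr-filter`, `benchmark`, `simulate`).

## Worked example

Overlap of verified R2R3-MYB interactors between two AC-rich elements,
straight from the packaged gold standard:

```r
library(cistf)
gold <- load_gold_standard()
gold
#> <gold_standard> 15 elements, 81 (element, TF) interactions
overlap_stats(gold, "CACCTAAC", "GGTTGTGGT", family = "R2R3-MYB")
#> $set_a_size   16
#> $set_b_size   14
#> $intersection 12
#> $union        18
#> $pct_of_a     75
#> $pct_of_union 66.7
```

Sixteen and fourteen R2R3-MYBs bind the two elements; twelve (66.7% of
the 18 distinct loci) bind both.

End-to-end prediction on a synthetic database with planted truth:

```r
sim  <- generate_database(synth_config(seed = 42))
sim$db
#> <motif_tf_db> 20 motifs, 20 TFs (5 families)
null <- build_null(sim$db$motifs, 8, seed = 42)
predict_tfs(sim$truth$FAM01$site_query, sim$db, sim$proteome, null = null)
#>   db_motif_id motif_evalue db_tf_id candidate_protein_id homology_evalue interface_similarity
#> 1    MOT01_01 2.041801e-05  TF01_01          HOM_TF01_03    3.388645e-33             91.66667
#> 2    MOT01_01 2.041801e-05  TF01_01          HOM_TF01_04    2.684984e-30            100.00000
#> 3    MOT01_01 2.041801e-05  TF01_01          HOM_TF01_01    4.579890e-30             75.00000
#> 4    MOT01_01 2.041801e-05  TF01_01          HOM_TF01_02    3.282170e-28             91.66667
```

The family-1 site query finds its family's motif (*E* = 2e-5, below the
1e-3 cutoff), and all four planted FAM01 homologs pass the homology
(≤ 1e-10) and interface (≥ 50%) filters — the planted truth is
recovered exactly.

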