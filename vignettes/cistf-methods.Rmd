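---
title: "Methods: predicting TFs that bind conserved cis-sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: predicting TFs that bind conserved cis-sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cistf)
```

# The problem

Motif-discovery tools readily find short sequences conserved in the
promoters of co-regulated genes -- for instance genes induced together
by drought stress -- but identifying the transcription factors (TFs)
that actually bind those cis-sequences is much harder. `cistf`
implements a database-assisted prediction pipeline for this problem and
the machinery needed to benchmark it against experimentally verified
interactions (yeast one-hybrid screens):

1. a query cis-sequence or position frequency matrix (PFM) is compared
   against an annotated motif--TF database;
2. the TFs linked to significantly similar database motifs are carried
   to a target proteome by local protein alignment;
3. candidates whose DNA-contacting interface residues are poorly
   conserved are filtered out;
4. surviving candidates are ranked and scored against a gold standard.

Alongside the prediction engine the package provides motif-family
clustering (UPGMA over all-vs-all motif distances), promoter scanning
with an expression-based ("in-silico expression") filter, and a seeded
synthetic-data generator that plants known ground truth.

# Motif comparison and significance

## Score

Motifs are W x 4 count matrices in fixed A,C,G,T column order,
normalised row-wise to frequencies. Two motifs are compared by ungapped
sliding alignment over every offset with at least `min_overlap = 5`
overlapping columns, in forward and reverse-complement orientation. The
per-column statistic is the Pearson correlation of the two frequency
4-vectors; a zero-variance column (e.g. the uniform column) scores 0
against anything, which avoids an undefined correlation without
rewarding uninformative positions. The alignment score is the *mean*
column correlation over the overlap, with ties broken by larger
overlap, then smaller absolute offset, then forward orientation.
`min_overlap = 5` matches the shortest motif width the pipeline is
designed for (discovery motifs of 5--10 nt).

## E-values

Significance is calibrated against a seeded decoy null: decoys are
column-shuffled database motifs, each aligned to a query-width motif
resampled from the database, and the best-alignment scores are
recorded. Two properties of short, sharp motifs drive the design of the
tail estimate:

* the mean-score scale does not separate a full-width match from a
  short lucky overlap (both can reach a mean near 1), so the
  *significance statistic* is the summed column similarity
  `score x ncols`;
* with 5--10 informative columns the tail probabilities that matter sit
  around `1e-4`--`1e-6` -- far beyond what 1000 decoy samples resolve,
  and an extreme-value fit by moments of the decoy bulk badly
  underestimates that depth.

The tail is therefore computed exactly under a null of independent
column scores: the empirical distribution of decoy column correlations
is discretised (bin width 0.01) and convolved k-fold for an overlap of
k columns, and the tail probabilities are summed over every admissible
offset and orientation (a union bound over the alignment search space).
Whenever at least one decoy alignment reaches the observed statistic
the p-value is floored at the rank-based empirical tail
`k / (n_decoys + 1)`, so the extrapolation can never claim more
significance than the decoys themselves support in the observed range.
`E = db_size x p` is monotone non-increasing in the score and linear in
the database size. The decoy best-score list and a Gumbel fit by
moments of the summed scores are kept on the null object as recorded
diagnostics.

The default cutoff for calling a database motif "similar" is
`E <= 1e-3`. A stricter `1e-5` is noticeably more specific but loses
true short-element matches; both are exposed as plain parameters.

# Motif families

All-vs-all distances are `d = (1 - score) / 2`, mapping alignment
scores in [-1, 1] onto [0, 1]. UPGMA (average-linkage agglomeration,
via `hclust`) produces an ultrametric tree exported as Newick; leaf ids
are sorted lexicographically before clustering so ties resolve
deterministically. Groups are cut by removing every branch of length
`>= 0.05` (on this package's [0, 1] distance scale) and collecting the
leaves of each remaining component -- motifs connected only through
short branches cluster together, and a motif on a long branch becomes a
singleton. The rule is applied to *all* edges, pendant ones included,
which matches the intuition of "clustering motifs on short branches";
the cut threshold applies to this package's distance scale and is not
calibrated to reproduce any particular external tree layout. A manual
override mapping lets curators reassign individual motifs after
cutting (the classical use case being a motif grouped by a conserved
core rather than by tree position).

# Interface residues and the interface filter

From a protein--DNA complex structure (PDB format, parsed with
`bio3d`), a protein residue is an *interface residue* iff any of its
heavy atoms lies within 4.5 Angstroms (inclusive) of at least one DNA
*base* atom -- the fixed base-moiety atom-name sets for DA/DC/DG/DT;
sugar and phosphate contacts do not count, because backbone contacts
carry no sequence specificity. Hydrogens are ignored on both sides
(deposited structures frequently lack them).

Interface similarity between a database TF and a candidate homolog is
computed through their local alignment: an annotated position counts as
conserved when it aligns to a candidate residue (not a gap, not outside
the aligned region) whose substitution score is strictly positive. The
similarity is the conserved percentage, and the default filter keeps
candidates with at least 50% (inclusive). The substitution matrix is a
pluggable parameter defaulting to BLOSUM62. TFs lacking an interface
annotation pass the filter with similarity recorded as absent --
structures exist only for a fraction of TFs and dropping all
unannotated records would silently bias predictions; a strict mode
drops them instead.

# Homology transfer

The homology step is an exact Smith--Waterman local alignment under
BLOSUM62 with affine gaps (open 11, extend 1), scored for significance
as `E = K m n exp(-lambda S)` with the conventional gapped-BLOSUM62
constants `lambda = 0.267`, `K = 0.041`. This keeps the step
deterministic and in-process; the E-value threshold (default `1e-10`)
is the only quantity consumed downstream, and the constants are
configurable. Candidates are deduplicated keeping the single best
`(motif E-value, homology E-value)` chain per protein, and that pair is
also the ranking key -- a composite rank is not attempted because the
two E-values live on unrelated scales.

A bare cis-sequence query is treated as a single-copy column-pure
motif. The tandem-repeat (`concatemer`) helper reproduces multimerised
bait construction, where composite sites (such as an E-box `CANNTG`)
can arise at repeat junctions; junction scanning is exposed through
`iupac_scan`.

# Promoter screen and expression filter

Promoters are the 1000 bases 5' of the transcription start site, or of
the start codon where no TSS is annotated; windows are truncated (not
padded) at contig edges and flagged. The window excludes the anchor
base itself. Genes at least 2-fold induced over the untreated control
(inclusive) count as up-regulated; an optional exclusive upper bound
supports band selections such as two- to tenfold.

For the expression filter, per-condition enrichment of motif-containing
genes among the condition's up-regulated set is scored with the
hypergeometric tail probability (population: all genes of the
expression matrix). Presence/absence per gene is used rather than
occurrence counts -- robust to repeat-rich promoters. The published
tool this emulates does not document its statistic; the hypergeometric
tail is the canonical choice and is recorded here as a substitution.
The filter itself is verbatim: a motif passes when at least two
drought-associated conditions rank among its top three.

# Synthetic data and what the tests show

The generator plants a fully known truth: each TF family gets a
consensus binding motif (default width 8, consensus-base probability
0.9 per column) and a conserved DNA-binding domain (DBD, 60 residues);
members carry multinomial motif variants and a DBD mutated at 10% of
sites, embedded in random flanks; the proteome holds one planted
homolog per TF (same DBD lineage, fresh flanks) plus one unrelated
decoy protein per TF; interface positions (20% of the DBD) are
annotated on every database TF. Expression matrices draw up-regulated
fold changes uniformly from [2, 10] and background noise log-normally
around 1. These defaults mirror the study conditions the pipeline is
designed for (5 families x 4 members unless stated otherwise) and are
fixed; all randomness flows from a single integer seed, so outputs are
byte-reproducible.

Two query modes are generated per family: a *site* query (one
column-pure consensus site) and a *whole-motif* query -- the soft
consensus matrix flanked by two noise columns on each side, emulating
de-novo discovery output whose edges are poorly determined. The noisy
flanks are the concrete mechanism by which whole-motif queries admit
spurious or weakened alignments, so per-site queries recover planted
homologs at least as precisely and markedly more completely -- the
qualitative direction expected of real data.

What passing tests do *not* show: real motif databases are far larger,
their families overlap in specificity (E-boxes and G-boxes share
cores), real promoters have composition bias, and real interface
annotations cover only TFs with solved structures. Synthetic recovery
rates are therefore upper bounds on real-data behaviour, and the
package makes no attempt to reproduce benchmark figures that depend on
a particular historical database snapshot and proteome release.

# Numerical and interface conventions

* Coordinates are 1-based and inclusive everywhere (the R and
  Bioconductor convention), including occurrence tables and interface
  positions.
* All cutoff comparisons are inclusive ("at least", "within").
* Pseudocounts default to 0.01, distributed by a background
  (default uniform), and are applied only where frequencies feed
  downstream consumers; comparison scoring uses raw frequencies so a
  motif aligns to itself at exactly 1.
* The IUPAC consensus reports a single base above 50% frequency, else
  the smallest base set with each member at 25%+ jointly holding 50%+,
  else N.
* Degenerate inputs: uniform query columns yield E-values near the
  database size (nothing is significant); empty proteomes or empty hit
  lists propagate as empty prediction tables, not errors.
* Gold-standard TF identity is the locus id, not a protein isoform.
  Zero-interactor elements stay in the benchmark tables but contribute
  to neither sensitivity numerator nor denominator; the specificity
  universe defaults to the configured candidate TF list, emulating a
  cloned TF library.

# Problem sizes

The shipped tests and the acceptance script run on synthetic databases
of 5 families x 4 members (20 motifs, 40 proteome entries), 1000-decoy
nulls, four seeds for recovery statistics, and oracle batteries of
50--200 random instances; these sizes give stable statistics while
keeping a full run in the low minutes on one core.

# Known limitations

* The alignment is ungapped and pairwise; no multiple-motif alignment
  or familial binding profiles.
* The column-independence assumption of the E-value null ignores
  inter-column correlation in real motifs; E-values are calibrated, not
  exact.
* Interface annotation takes coordinates at face value: no structure
  superposition or homology modelling, and contacts from hydrogens are
  not considered.
* The promoter screen starts from a ready fold-change table;
  normalisation of raw expression data is out of scope.
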