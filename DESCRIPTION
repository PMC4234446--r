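Package: cistf
Title: Predicting Transcription Factors That Bind Conserved Cis-Regulatory Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting transcription factors (TFs) that bind
    conserved cis-sequences of co-regulated genes. Implements position
    weight matrix comparison with empirical E-values, UPGMA motif-family
    clustering with Newick export, annotation of protein-DNA interface
    residues from complex structures, homology-based transfer of binding
    specificity to a target proteome with an interface-similarity filter,
    promoter scanning with an in-silico expression (drought enrichment)
    filter, and benchmarking of predictions against a packaged yeast
    one-hybrid gold standard. A seeded synthetic-data generator provides
    motif-TF databases, proteomes, promoters and expression matrices with
    planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    bio3d,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
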