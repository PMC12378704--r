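Package: imprior
Title: Genome-Wide Prioritization of i-Motif Candidate Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scans genome sequences for C-rich (C3 N1-12)3 C3 motifs on both
    strands, aligns the matches per chromosome and strand, derives a
    position-specific similarity matrix (PSSM) from the alignment, scores
    every match by the positive-sum PSSM rule, assigns permutation-based
    significance (one-sided t p-values, Benjamini-Hochberg correction,
    Z-scores), retains the top-ranked fraction as high-confidence i-motif
    candidates, annotates them against gene models, and validates them
    against positive and negative control sequence sets with edit-distance
    and k-mer Jaccard triage, rank-sum comparisons, and a nucleotide
    composition random-forest classifier. Includes a synthetic-genome
    fixture generator so the entire pipeline can be exercised without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    randomForest,
    pROC,
    jsonlite,
    yaml,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
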