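---
title: "Prioritizing i-motif candidate sequences with an alignment-derived PSSM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing i-motif candidate sequences with an alignment-derived PSSM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

i-Motifs (iMs) are four-stranded DNA structures that form in cytosine-rich
sequence, held together by hemi-protonated C:C+ base pairs. Naive pattern
matching for C-rich motifs produces hundreds of thousands of loci per
mammalian genome, far too many for experimental follow-up. `imprior`
implements a prioritization strategy built on one idea: positional
conservation across the matched loci is a proxy for structural relevance, so
loci that agree with an alignment-wide consensus deserve to be ranked first.

The procedure has four stages.

1. **Scan.** Both strands of the genome are searched with the grammar
   (C3 N1-12)3 C3 — four runs of three cytosines separated by three loops of
   1-12 arbitrary nucleotides. Matching is non-overlapping, leftmost, and
   greedy, the semantics of a standard regex engine; with the default
   grammar every match is between 15 and 48 nt long. Reverse-strand hits
   are found on the reverse complement and mapped back to reference
   coordinates (`start_ref = L - end_rc`, 0-based half-open). Loops admit
   only A/C/G/T, so a match can never span an N.
2. **Align.** Matches are grouped by chromosome and strand, extended by up
   to three reference nucleotides on each side (in motif orientation,
   truncated at contig ends), and aligned. The builtin engine is a
   deterministic progressive aligner: a UPGMA guide tree over shared 3-mer
   Jaccard distances, then profile-profile Needleman-Wunsch with match +1,
   mismatch -1, and a linear gap penalty of -2. An external engine (any
   FASTA-in/FASTA-out aligner, `mafft` by default) can be substituted; the
   builtin engine exists so that every stage runs with no external binary.
3. **Score.** Per alignment column, nucleotide frequencies are computed over
   non-gap characters, and each base gets the log2 ratio of its
   pseudocount-adjusted frequency to a uniform 25% background. A row's score
   is the sum of the *strictly positive* column scores of its residues:
   negative columns are disregarded so longer matches are not penalized, and
   gaps contribute nothing (no gap penalties). Significance comes from a
   permutation null: the row's residues are shuffled within its own non-gap
   columns B = 1,000 times and re-scored, giving a null mean and standard
   deviation, a Z-score, a one-sided t-type p-value, Benjamini-Hochberg
   q-values across all candidates, and finally the selection rule: among
   candidates with q < 0.05, keep the `floor(0.05 * N)` highest Z-scores,
   where N is the total scanned candidate count.
4. **Annotate and validate.** Selected candidates overlapping a gene body
   are labelled `correct`; the rest get their nearest gene and signed
   distance (`nearest`). Genic regions follow the fixed precedence
   promoter > 5'UTR > 3'UTR > exon > intron > distal intergenic, with the
   promoter a strand-aware window (default -2000/+200) around the TSS.
   Gene-class enrichment (immune vs housekeeping) uses Fisher's exact test
   on deduplicated symbols. Validation against control sets uses
   Levenshtein and 3-mer Jaccard triage (each candidate is labelled by its
   best similarity to positive vs negative controls), a Wilcoxon rank-sum
   comparison of PSSM scores (negatives are scored by sliding the sequence
   across every offset of the matrix and taking the maximal positive sum),
   and a random forest over five features: the four nucleotide frequencies
   and the sequence length.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `run_len`, `n_runs` | 3, 4 | cytosine-run geometry of the grammar |
| `loop_min`, `loop_max` | 1, 12 nt | loop length bounds |
| `flank` | 3 nt | context added before alignment |
| `pseudocount` | 0.25 / base / column | avoids log(0); see below |
| `B` | 1000 | permutations per candidate |
| `q_threshold` | 0.05 | BH significance filter |
| `top_frac` | 0.05 | fraction of all scanned candidates retained |
| `promoter_window` | 2000 up / 200 down | promoter definition around the TSS |
| `k` | 3 | k-mer size for Jaccard triage and the guide tree |
| `split`, `folds` | 0.7, 10 | classifier train fraction and CV folds |
| `ntree`, `mtry_grid` | 500, 1..5 | random-forest ensemble settings |

## Numerical choices

* **Log base.** Column scores use log2. Any base only rescales the ranking,
  and ranking is all the selection uses.
* **Pseudocount.** 0.25 per nucleotide per column. Because negative column
  scores are truncated to zero at scoring time, the result is insensitive
  to the exact value for depleted bases; the pseudocount mainly keeps
  absent bases finite. `pseudocount = 0` is allowed and yields `-Inf` for
  absent bases, which the positive-sum rule ignores.
* **Gap handling.** Gaps are excluded from column frequency denominators
  and contribute zero when scoring; all-gap columns are flagged and scored
  zero.
* **Sliding score.** "All possible alignments by shifting" is aggregated
  with the maximum over offsets — the only aggregation that yields a single
  score comparable with the aligned-row score. Overhangs are allowed and
  out-of-matrix positions contribute zero.
* **The t statistic.** The observed score is one draw from the permutation
  null, so the package's default compares it to that null with the
  predictive form `t = (S - mean) / (sd * sqrt(1 + 1/B))` on B - 1 degrees
  of freedom. This form is calibrated: for sequences generated under the
  null the p-values are uniform, which we verify explicitly in the test
  suite. An alternative reading — dividing by the standard error of the
  null *mean*, `sd / sqrt(B)` — is exposed as `t_scale = "mean_se"`. It is
  far more aggressive (essentially every candidate with a positive Z passes
  BH, reproducing the near-saturated significance filter of genome-scale
  runs), but it is not calibrated, so it is not the default. The Z-score,
  which drives the actual ranking, is identical under both.
* **Degenerate nulls.** If shuffling cannot change a row (e.g. a
  homopolymer), the null standard deviation is zero; we return z = 0 and
  p = 1 when the observed score does not exceed the null mean, else the
  permutation resolution floor 1/(B + 1).
* **Tie-breaks.** Selection ties in Z fall back to score, then genomic
  coordinate. Guide-tree joins and the profile DP traceback have fixed
  preferences (diagonal, then gap-in-second-profile, then
  gap-in-first-profile), so the builtin aligner is deterministic for a
  given input order; the pipeline feeds sequences in genomic order.
* **Similarity ties.** A candidate equally similar to the positive and the
  negative control set is called negative — the conservative choice. The
  Jaccard ROC cutoff is Youden's J.
* **Classifier.** Stratified 70/30 split, stratified 10-fold CV over the
  mtry grid by accuracy (ties to the smallest mtry), refit on the full
  training set, all metrics on the held-out 30%. With a fixed seed every
  metric is bit-reproducible.

## What the synthetic fixtures emulate — and what they do not

`simulate_genome()` builds a chromosome with a background that never emits
a third consecutive C *or* G (a GGG run on the forward strand is a CCC run
on the reverse strand, so both must be excluded for the background to be
match-free on both strands), implants motif-grammar draws at non-overlapping
positions with non-C/G guard bases at the boundaries, places half of the
implants on the minus strand as reverse complements, and lays a toy gene
track in which a configurable fraction of implants sit inside
immune-labelled genes while housekeeping genes occupy an implant-free tail.
Implant loops avoid CC and GG dinucleotides and C at the loop edges, so the
four designed C-runs are the only ones on either strand and the truth BED
is exact scanner ground truth.

The classifier negatives from `generate_negative_sequences()` follow the
published recipe exactly — only the CCC triplet is excluded, lengths are
uniform on 15-50 nt — because they model non-iM-forming sequence, not a
scan background.

These fixtures establish that every stage does what it claims on inputs
with known truth. They do **not** emulate real genome composition: no GC
skew, no repeats, no CpG islands, no chromosome-scale heterogeneity in
motif density. Passing fixtures therefore demonstrates correctness of the
machinery, not the biological yield of a genome-scale run, which further
depends on the assembly and the aligner used.

Test and example problem sizes are deliberately modest so the whole suite
runs in minutes on one CPU: fixture genomes of 10-130 kb with 5-160
implants, candidate sets of up to 1,000, 150-1,000 permutations in unit
tests (1,000 in the acceptance script), 250-300 sequences per class for the
classifier checks, and exhaustive Fisher enumeration for all 2x2 tables
with grand total up to 16 plus random larger-margin tables. A genome-scale
run is the same code with a genome FASTA: `run_pipeline()` or
`imprior run-all --fasta hg38.fa ...`.

## Known limitations

* The builtin progressive aligner is intentionally simple (linear gaps,
  profile frequencies, no iterative refinement). On large heterogeneous
  groups it accumulates more gap columns than a production MSA tool;
  positive-sum scoring is tolerant of this, but genome-scale PSSMs are
  better built with the external engine.
* The promoter definition and the region precedence are conventions; data
  sets annotated with different conventions will shift the region
  percentages.
* Overlapping or nested motif instances are not enumerated — one leftmost
  greedy match per locus per strand — so total match counts are specific to
  this matching semantics.
* The random forest is a validation device, not a deliverable model; any
  conformant ensemble yields equivalent conclusions.

## A minimal run

```{r example}
library(imprior)

sim <- simulate_genome(genome_length = 30000, n_implants = 24, seed = 11,
                       dir = "fixture")
cfg <- pipeline_config(fasta = sim$paths$fasta, gtf = sim$paths$gtf,
                       out_dir = "run", B = 1000, top_frac = 0.25,
                       immune_genes = sim$paths$immune,
                       housekeeping_genes = sim$paths$housekeeping,
                       seed = 11)
out <- run_pipeline(cfg)
out$report$counts
```
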