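---
title: "lncLink: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{lncLink: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

lncLink identifies long non-coding RNAs (lncRNAs) in multi-tissue bulk
RNA-seq data and infers candidate regulatory relations between
differentially expressed lncRNAs (DELs) and differentially expressed
protein-coding genes (DEGs). This vignette documents the models behind each
stage, the tunable parameters and their defaults, the synthetic-data
generator that the test suite exercises the pipeline on, and the numerical
and design choices a maintainer should know about.

## The pipeline at a glance

Given a transcript annotation (GTF), transcript sequences (FASTA), a raw
count matrix, a sample sheet (three tissues — testis `T`, epididymis `E`,
ductus deferens `DD` — with replicates), a reference lncRNA FASTA and
optionally protein sequences, `runPipeline()` executes:

1. **Known-lncRNA annotation** — local sequence similarity against the
   reference lncRNA set; a transcript whose best hit exceeds 90 % identity
   at E < 1e-10 is a known lncRNA.
2. **Structural filtering** of the remaining candidates — remove
   protein-coding-annotated transcripts, transcripts with a summed raw
   count of 10 or less, transcripts of 200 nt or less, and mono-exonic
   transcripts, in that cascade order.
3. **Coding-potential consensus** — seven independent scorers each vote
   coding/noncoding; at least 5 of 7 noncoding votes are required, followed
   by a protein-domain (PSSM) filter on every translated ORF of at least
   90 nt. Survivors are novel lncRNAs.
4. **Differential expression** at the gene level for the three pairwise
   tissue comparisons, called only when confirmed by two independent
   methods (below). DE lncRNAs are DELs; DE protein-coding genes are DEGs.
5. **Profile grouping** — `T_vs_rest`, `E_vs_rest`, `DD_vs_rest` for
   features DE with a consistent sign in both comparisons involving that
   tissue.
6. **Relation inference** per comparison, four independent tiers: CIS
   (genomic span gap < 100 kbp), TRANS (|Pearson r| > 0.9, p < 0.05 across
   all samples), direct RNA-RNA (duplex ndG < -0.1 kcal/mol/nt), and
   RNA-protein (interaction probability > 0.90). No tier gates another.
7. **Reporting** — per-stage TSV tables, MA/volcano and Z-score matrices,
   cumulative relation counts, SIF/GraphML network exports and a protein
   list for external enrichment lookups.

Every threshold above lives in `pipelineConfig()` and nowhere else; the
values quoted are its defaults.

## Similarity engine

Known-lncRNA annotation uses an internal seed-and-score engine rather than
an external aligner: exact 11-mer seeds select candidate query/reference
pairs, each selected pair is scored by affine-gap Smith-Waterman (match
+2, mismatch -3, gap open 5, gap extend 2, the classic nucleotide BLAST
scheme), and significance comes from the Karlin-Altschul formula
`E = K m n e^(-lambda S)` with `lambda` solved numerically for this score
scheme at uniform base composition and `K = 0.41`, the documented constant
for these scores; the database size `n` is the total reference length.
Percent identity is computed over the best-scoring local alignment's
length. The test suite checks the aligner against
`Biostrings::pairwiseAlignment` as an independent oracle.

## The seven coding-potential scorers

Each scorer captures one feature family that the widely used
coding-potential classifiers rely on. None of them calls an external
binary or a trained deep model; each is a transparent statistic with a
decision threshold calibrated once at the equal-error-rate point on a
fixed-seed synthetic training set (5,000 coding + 5,000 noncoding
sequences) and shipped as a plain-text data file:

| scorer | statistic | coding-like direction |
|---|---|---|
| `orf_length` | longest-ORF length (nt; ATG through stop, inclusive; forward frames only) | high |
| `orf_coverage` | longest-ORF length / transcript length | high |
| `fickett` | TESTCODE statistic from the published position/content lookup tables | high |
| `hexamer` | mean log-likelihood ratio of in-frame hexamers (coding vs noncoding tables) in the longest-ORF frame | high |
| `kmer_spectrum` | logistic score over all k-mer frequencies, k = 1..5 (1,364 features) | high |
| `triplet_frame` | max-over-frames mean log-odds of adjacent codon pairs (64 x 64 matrix) | high |
| `stop_density` | min-over-frames stop-codon rate minus 0.2 x GC | low |

A transcript is consensus-noncoding iff at least 5 of the 7 votes are
noncoding — of the 128 possible vote vectors exactly 29 qualify. The vote
is monotone: flipping any single vote towards noncoding can never flip the
consensus back towards coding.

ORF conventions: ORFs are scanned in the three forward frames only
(spliced transcripts are stranded); an ORF runs from the first in-frame
ATG of a stop-delimited segment through the stop codon inclusive; with no
downstream stop it runs to the last complete codon and is flagged
incomplete.

The domain filter translates every ORF of at least 90 nt and scans the
peptides against a small bundled PSSM library patterned on classic domain
signatures (Walker A, C2H2 zinc finger, homeobox helix, ...). Each motif
carries its own threshold at 80 % of its maximal score, which random
30-residue peptides essentially never reach. The library is a desk-scale
stand-in for a full domain-database scan; `readMotifLibrary()` accepts any
library in the same plain-text format, so a larger scan can be substituted
without code changes. The filter is applied to all consensus-noncoding
candidates; a consensus-coding transcript is coding regardless of motifs.
An empty motif library is a configuration error, not a silent pass.

## Differential expression

Two deliberately different methods must agree:

* **Primary — negative-binomial Wald test.** Median-of-ratios size
  factors across the two groups jointly; per-feature method-of-moments
  dispersion shrunk to a fitted mean-dispersion trend
  `alpha(mu) = a0 + a1/mu`; Wald statistic on the log group-mean contrast
  with variance `(1/n_g)(1/mu_g + alpha)` per group; two-sided normal
  p-value. The fold change is `log2((m1 + 0.5)/(m2 + 0.5))` on normalised
  means — the 0.5 pseudo-count keeps one-sided zeros finite
  (`log2(100.5/0.5) ~ 7.65` for a group mean of 100 against zeros).
* **Secondary — exact rank-sum test on FPKM.** For up to 10 replicates
  per group the two-sided p-value is exact over all `choose(n1+n2, n1)`
  relabellings using midranks for ties. This matters: on integer counts
  ties are routine, and the textbook exact test silently degrades to a
  normal approximation under ties, which costs most of its power at
  n = 6/6 (the most extreme achievable p is 2/924 ~ 0.00216).

P-values are Benjamini-Hochberg adjusted within each comparison across
features with non-zero total counts. A feature is DE iff both adjusted
p-values are below 0.01 **and** |log2FC| > 1. The fold-change rule is
applied to the absolute value, so down-regulated features are called
symmetrically. FPKM uses per-sample library size = total counts over the
matrix, `fpkm = count / ((length/1e3)(libsize/1e6))`.

Profile groups: a feature joins `X_vs_rest` when DE in both comparisons
involving tissue X with a consistent sign relative to X. A fully monotone
profile (significant in all three comparisons) can satisfy two group
definitions; since groups are disjoint, such a feature is assigned to the
group with the larger minimum |log2FC| across its two comparisons.

## Relation tiers

* **CIS** — gap between the two gene spans (not TSSs) on the same
  chromosome, strand-agnostic, overlap = 0; strictly below 100,000 bp, so
  a pair at exactly 100 kbp is not CIS. The interval-indexed finder is
  checked against an all-pairs brute-force oracle.
* **TRANS** — Pearson correlation across all samples; two-sided p from
  `t = r sqrt(n-2)/sqrt(1-r^2)`, df = n-2. The threshold is on |r|, with
  the sign reported: tissue-specific lncRNAs can be strong *negative*
  regulator candidates and a positive-only rule would discard them.
  P-values in this tier are deliberately unadjusted (the conventional
  screen applies the raw p < 0.05 alongside the much stronger |r| > 0.9
  condition).
* **RNA-RNA** — best contiguous-stack duplex between the two sequences
  over all antiparallel offsets, scored with a bundled nearest-neighbor
  stack table (10 Watson-Crick stack free energies at 37 °C plus two G-U
  wobble terms; no loop/bulge penalties, the usual target-prediction
  simplification). The normalised energy is `ndG = dG / min(len1, len2)`
  in kcal/mol/nt, the target-prediction convention: a chance short
  complementary run in long RNAs stays above the -0.1 threshold while a
  planted long duplex falls below it. For equal-length exact complements
  this equals dG per paired base. `N` never pairs and counts toward
  length; `U` is a synonym of `T`. The dynamic programming scan is tested
  for exact dG equality against an exhaustive enumeration oracle on short
  sequences.
* **RNA-protein** — the lncRNA is encoded as sliding-window composition
  profiles (GC content as a base-pairing propensity proxy, plus A
  content), the protein as hydrogen-bonding, Van der Waals and
  helix-propensity profiles from bundled residue scales; both are reduced
  to fixed length by truncated cosine (Fourier) series (8 coefficients per
  channel), and the score is a logistic of the bilinear form `r' W p`.
  `W` and the logistic calibration were estimated once on a fixed-seed
  synthetic set of positive/negative pairs (the positives'
  proteins carry interface-tilted residue composition) and shipped as
  versioned parameters; the scoring architecture is fixed. The logistic
  uses a fixed-scale calibration (class-mean midpoint to 0.5, class means
  to plogis(+-6)) and the linear predictor is clamped to +-30 so scores
  are always strictly inside (0, 1). Unknown residues are an error; `X`
  is imputed at mean propensity.

Relations are computed per comparison over the DELs and DEGs significant
in that comparison (a CIS pair must be significant in the same
comparison). `assembleRelations()` merges the tiers, collapses duplicates
with a warning count, tabulates cumulative counts per comparison and kind
(for all DEGs and for an optional curated gene subset), and classifies
genes by the set of relation kinds they appear in.

## The synthetic-data generator

`simulateDataset(simParams(seed))` is first-class, tested code: it builds
a genome, an exon-resolved annotation, spliced transcript sequences, a
reference lncRNA set, proteins, a count matrix and a truth manifest, all
as pure functions of the parameter object (same seed, byte-identical
files). It emulates:

* a mixed transcriptome — protein-coding mRNAs (UTRs from a first-order
  Markov background, ORFs of 150–300 codons sampled from a human-style
  codon-usage table), known and novel lncRNAs (AT-rich, CpG-poor Markov
  sequences post-processed so that no ORF reaches 100 nt), and bait
  transcripts that each violate exactly one structural filter;
* known lncRNAs mirrored in the reference set at ~98 % identity (2 %
  point mutations), plus unrelated decoy references;
* planted CIS neighbours placed at an exact span gap (default 50 kbp);
* planted co-expressed DEL-DEG pairs sharing a per-sample lognormal
  latent factor (sd 0.08, opposite sign for negative pairs), with base
  means floored at 300 — on the raw FPKM scale an anti-correlated
  lognormal factor attenuates Pearson r by a factor of e^(-sd^2) and a
  down-scaled profile is noise-compressed, so the latent coupling must
  stay small and both profiles well-measured for the pairs' defining
  |r| > 0.9 to hold for negative pairs too;
* planted duplex pairs: an exact reverse-complement window (default
  60 nt) of the partner mRNA inserted into the lncRNA, with ORF-breaking
  repair that never touches the planted window;
* planted RNA-protein partners whose ORFs use interface-tilted codon
  usage;
* negative-binomial counts (mean m, dispersion alpha, variance
  m + alpha m^2) at 3 tissues x 6 replicates, with planted |log2FC| = 3
  effects in each pair's designated tissue, filled to a 40 % DE fraction.

Default choices and why: the planted |log2FC| of 3 reflects the magnitude
typical of tissue-specific lncRNAs in reproductive tissue (reported
fold-changes in such comparisons span log2FC ~ 2.4–10). The default
dispersion is 0.02: planted co-expressed pairs are *defined* by an
expected FPKM correlation above 0.9, and with independent NB noise the
attainable correlation between two planted profiles is capped at roughly
`s^2/(s^2 + alpha E[mu^2])`; at alpha = 0.1 that cap sits near 0.87 no
matter how large the fold change, so the co-expression contract itself
pins the default to the low end of the bulk-RNA-seq dispersion range —
appropriate for six same-age, same-flock biological replicates. The same
contract bounds the latent-factor sd from above for negative pairs (see
the list above). The DE
fraction of 0.4 keeps the BH-adjusted exact rank-sum arm attainable at
n = 6/6 (with ~260 genes, a q < 0.01 call requires the most extreme exact
p of 2/924 to survive adjustment, which needs a substantial fraction of
truly changed features); it is the planted-truth density of a validation
design, not an estimate of any real tissue contrast.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: read-level artefacts (the generator produces
counts, not reads), isoform complexity (one transcript per gene, so
gene-level DE is exact rather than aggregated), mappability and GC bias,
batch effects, library-composition shifts that challenge normalisation,
and the soft boundary between coding and noncoding sequence in real
transcriptomes (planted classes are cleanly separable by construction, so
scorer accuracies on synthetic data overstate real-data accuracy).

## Numerical choices and degenerate inputs

* ORF-breaking in the generator only accepts a stop-codon insertion that
  strictly lowers the total length of remaining long ORFs; overlapping
  ORFs in different frames can otherwise undo each other's inserted stops
  indefinitely.
* Zero-variance expression profiles are skipped by the TRANS finder with
  a warning record rather than producing NaN correlations.
* All-zero features in both DE groups get p = 1 and log2FC = 0; an
  all-zero sample column is a validation error for FPKM.
* The Fickett lookup uses the published degenerate-bin values for absent
  bases (e.g. a homopolymer).
* Duplex ties (equal dG at several offsets) resolve to the first offset
  scanned — deterministic for a given input.
* Low-expression baits are redrawn (bounded, seeded) if sampling pushes
  their summed count above the 10-count contract.
* Scorer thresholds sit exactly at the calibrated equal-error-rate point;
  scores equal to the threshold vote against the scorer's coding-like
  direction (strict comparison).

## Problem sizes

The bundled validation runs use desk-scale problem sizes chosen to give
stable estimates: the default synthetic dataset has 150 coding genes, 40
known and 60 novel lncRNAs and 9 baits on a 3 x 4 Mbp genome with 18
samples; scorer validation uses 500 + 500 held-out sequences; DE
calibration uses 2,000-gene simulations (10 null seeds); the CIS oracle
comparison uses 200 random genes; the duplex oracle comparison uses 100
random short pairs. `scripts/acceptance.R` re-runs all of these from
scratch against the installed package.

## Known limitations

* The seven scorers are stand-ins that share feature families with the
  tools they replace, not re-implementations of those tools; their scores
  are not comparable to the originals' outputs.
* The duplex model omits loop, bulge and dangling-end terms, so dG is an
  upper bound on duplex stability rather than a full secondary-structure
  energy.
* The RNA-protein scorer is calibrated on generator-produced pairs; on
  real lncRNA-protein data it should be re-calibrated with
  experimentally supported positives (the parameter file format supports
  drop-in replacement).
* The similarity engine's E-values use ungapped Karlin-Altschul
  parameters with the gapped alignment score — standard practice for a
  screen, but approximate.
* DE is gene-level; the exact rank-sum arm loses power below 6 replicates
  per group (at n = 4/4 the most extreme exact p is 2/70 ~ 0.029, which
  cannot pass q < 0.01 after any meaningful adjustment).
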