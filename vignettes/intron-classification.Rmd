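---
title: "Classifying U2- and U12-type introns: models, parameters and design choices"
author: "introntype"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying U2- and U12-type introns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(introntype)
```

## The problem

Eukaryotic genomes contain two classes of spliceosomal introns. The vast
majority are excised by the major (U2-type) spliceosome; a small minority —
typically well under 1% — are recognised by the minor (U12-type)
spliceosome. The two classes cannot be told apart by their terminal
dinucleotides alone (both classes contain GT-AG and AT-AC members); what
distinguishes them are extended sequence motifs at the 5' splice site and
at the branch point near the 3' end of the intron. `introntype` assigns a
class to every intron in an annotated genome from exactly those two
signals, and provides the downstream statistics used to study how the two
classes evolve: phase biases, the composition of the last exonic
nucleotide before the 5' splice site, terminal-dinucleotide usage,
within-gene clustering of U12-type introns, and grouping of orthologous
introns across species.

## Intron extraction

Introns are the gaps between adjacent exon or CDS features of a
transcript, taken from the longest isoform of each gene (the isoform
maximising summed feature length; ties break to the lexicographically
smallest transcript id so runs are reproducible). Two runs — one
exon-defined, one CDS-defined — are merged by exact genomic coordinates,
with the CDS-defined record winning because it carries a defined phase;
exon-only introns (UTRs, non-coding transcripts) are kept with undefined
phase. Coordinates stay 1-based inclusive throughout, matching the
GFF3/GTF convention.

Motif windows use signed positions that skip zero: +1 is the first intron
base, −1 the last. The 5' splice-site window spans −3..+9 (three exonic
plus nine intronic bases, 12 nt); the branch-point search region spans
−55..−5 from the intron's last base (51 nt). Two numerical choices matter
here:

* **Short introns.** Introns shorter than 30 nt are extracted but flagged
  `too_short` and never scored: below that floor the branch-point region
  would overlap the 5' splice-site window. The branch-point region of
  moderately short introns is truncated (never earlier than intron
  position 10) rather than padded, so no candidate 12-mer ever straddles
  the donor site. A padded candidate would score a log-ratio of 0 at each
  N and could spuriously outrank genuinely U2-like (negative-scoring)
  motifs.
* **Chromosome edges.** Exonic flanks and the 5' splice-site window are
  N-padded where they run off the sequence; an N contributes
  log2(pseudo-count/pseudo-count) = 0 to any score, i.e. it is neutral.

## Scoring model

Each motif is scored with a pair of position weight matrices (PWMs) as the
binary logarithm of the U12 over U2 probability ratio, so positive scores
are U12-like and negative scores U2-like. A pseudo-count of 0.001 is added
to every matrix cell at scoring time; it prevents zero probabilities while
still penalising rare bases by roughly ten bits. Matrices are
subtype-resolved: introns with AT-AC termini are scored with AT-AC U12
matrices, GC-AG introns with the GC-AG U2 donor matrix, and everything
else — including non-canonical termini — with the GT-AG matrices of both
classes.

U2-type introns have no extended branch-point consensus, so the U2
branch-point matrix is derived from the data being classified: the 95th
percentile (linear-interpolation quantile) of all 5' splice-site scores is
computed, every intron strictly below it is scanned for its best 12-mer
under the U12 branch-point matrix, and those 12-mers build the empirical
U2 branch-point PWM. This is deliberately conservative: the background
matrix is made of the *most U12-like* motifs that non-U12 introns can
offer, which pulls borderline branch-point scores toward zero. The matrix
is recomputed for each input set (e.g. each species). Scoring is two-pass:
pass one scores all donors, the empirical matrix is derived, pass two
scans each intron's region for the 12-mer with the highest U12/U2 log
ratio (ties resolve to the 3'-most, branch-point-proximal position).

When a U12 branch-point matrix must itself be estimated from training
regions, `refine_bps_pwm()` iterates scan-and-rebuild and keeps only
motifs with an adenosine at position 9 or 10 of the 12-mer — the branch-A
constraint used when curating U12 branch-point training data.

## Classification

Each intron contributes a two-dimensional score vector (5'SS bits, BPS
bits). A linear-kernel SVM is trained on labeled score vectors computed
with the same matrices — including the same empirical U2 branch-point
matrix — so training and genome scores share one scale. Features are
standardized (zero mean, unit variance on the training set; the transform
is stored in the model file). Class imbalance (U2 outnumbers U12 by
roughly 50:1 in a realistic training set) is addressed in model selection,
not by class weights: the penalty `C` is chosen by iterative stratified
cross-validation on **balanced accuracy** (mean of sensitivity and
specificity). The search starts from 13 log-spaced values spanning
10^−3..10^3, re-grids between the neighbours of each round's best value
for 3 rounds (5 folds each), and returns the arithmetic mean of the final
range; when several values tie, the largest wins, preferring the more
conservative (larger-`C`) margin. On well-separated data the CV curve has
a wide plateau, so results are insensitive to these defaults; all are
arguments.

Decision values are mapped to probabilities with a slope-only sigmoid,
`p = plogis(a·d)` with `a > 0` fitted by maximum likelihood on out-of-fold
decision values (5 folds). A full two-parameter (Platt) sigmoid was
rejected deliberately: its intercept shifts the probability midpoint away
from the decision boundary under class imbalance, whereas the contract
here is that a vector exactly on the boundary has probability 0.5. The
slope is bounded in [1e-4, 200] so perfectly separable data yields a
finite, reproducible model. An intron is called **U12-type when its
probability reaches 0.90**; the boundary itself (p = 0.5) is therefore a
U2-type call. All randomness (fold assignment) derives from a single seed
argument recorded in the model file; the same inputs and seed reproduce
the model file byte for byte.

## Evolutionary statistics

* `phase_bias_test()` — per class, a chi-squared goodness-of-fit of phase
  counts against a uniform null (1/3 each). The uniform null is the only
  assumption-free choice; the expected fractions are an argument for users
  who prefer an empirical null.
* `minus1_table()` — composition of the last exonic base upstream of the
  donor site (read from the 50-nt upstream flank), grouped by phase or by
  terminal-dinucleotide category.
* `terminal_dinucleotide_table()` — GT-AG / GC-AG / AT-AC / other
  percentages per class.
* `u12_clustering_test()` — under random placement, the number of genes
  with more than one U12-type intron among the `n` genes with at least one
  is Binomial(n, p) with `p = 1 − (1 − x)^(m−1)`, where `x` is the
  genome-wide U12 fraction and `m` the mean intron count per
  intron-containing gene. Both the point mass P(X = k) and the upper tail
  P(X ≥ k) are reported; the tail is labelled as the p-value since
  "probability of observing the observed count" is ambiguous between the
  two readings, and the tail is the conventional test.
* `dedup_splice_variants()` — alternative donors/acceptors of one intron
  inflate naive counts; building a graph with a node per coordinate and an
  edge per annotated intron makes each physical intron one connected
  component, whose lexicographically smallest coordinate pair serves as
  the representative.
* `wobble_g_families()` — groups the 61 sense codons into 20 families and
  counts those containing a codon ending in G (13 under the standard
  code). The −1 base of a phase 0 intron is a wobble position, so this
  bounds how many codon families can carry a −1 G silently — the
  mechanistic lever of the U12-to-U2 class-conversion argument.
* `length_summary()` / `length_genome_correlation()` — per-class mean
  intron lengths and their Pearson correlation with genome size across
  species.

## Orthologous introns

Reciprocal-best-hit detection and global protein alignment are consumed as
inputs (aligned-FASTA pairs), not executed. Each CDS-defined intron is
anchored to the residue containing or following its junction
(`floor(upstream CDS nt/3) + 1`) with its phase. Two anchored introns link
as orthologs when they map to the same alignment column, share phase, and
the alignment is at least 40% identical within ±10 residues of that column
(gap columns count in the denominator; windows truncate at alignment
ends — no padding, so edge columns are judged on what is actually
observable). Column-and-phase equality is the strictest reading of
"same position"; requiring phase equality is consistent with using the
groups for phase-distribution analyses. Links are grouped by maximal-clique
listing (links A–B, A–C, B–C, B–D yield groups {A,B,C} and {B,D}); a
clique guarantees every member pair was independently linked, and a node
may legitimately appear in several groups. `igraph`'s pivoting
Bron–Kerbosch implementation does the listing; a node-count ceiling guards
against accidentally dense inputs.

## The simulator, and what passing tests do and do not show

`simulate_genome()` generates single-transcript, fully coding genes on one
chromosome, with log-normal exon (median 150 nt) and intron (median
120 nt, floor 70 nt) lengths, a configurable fraction of minus-strand
genes, and planted motifs: each intron draws its donor 12-mer, acceptor
dinucleotide and — for U12-type introns — a branch-point 12-mer from its
class consensus, keeping each position with probability `motif_fidelity`
(default 0.95, a strong but not deterministic motif) and otherwise
substituting a random different base. The default consensus strings
(U2 donor `CAG|GTAAGTATC`, U12 donor `ATA|GTATCCTTT`, U12 branch point
`TTTCCTTAACTT`) follow the canonical motif structure of the two classes;
they are configuration values, not estimates from any particular genome.
The intron-length floor of 70 nt keeps the planted branch point inside
the −55..−5 search region. A truth table records every planted intron's
coordinates, class, phase, rank and realized motifs, and the test suite
verifies that annotation-driven extraction reproduces it exactly.

The simulator emulates motif content, strandedness, phase structure and
class imbalance. It does **not** emulate realistic codon usage, GC
content, alternative isoforms, overlapping genes, or degenerate splice
sites, so a perfect score on simulated data demonstrates correctness of
the machinery — windows, matrices, the empirical background, the
classifier — under clean conditions, not expected accuracy on a real
genome, where training-set curation dominates performance.

Problem sizes used in the validation suite are chosen to exercise every
code path at comfortable statistical power: the end-to-end recovery run
plants 1000 U2-type and 10 U12-type introns (202 genes × 5 introns,
fidelity 0.95, seed 42) and expects complete recovery with zero false
positives; classifier checks use a few hundred training vectors; the
binomial test is checked against 100 000 Monte-Carlo draws; the
chi-squared calibration uses 1000 replicates of 300 introns.

## Known limitations

* Training sequences and PWMs are inputs; no curated multi-species
  training collection ships with the package.
* Only the 5' splice-site and branch-point signals are modelled — no
  3' splice-site matrix, polypyrimidine tract, or intron-length feature.
* One linear kernel; the two-dimensional score space does not justify
  more, but strongly non-separable training data will surface as a low
  cross-validated balanced accuracy rather than an error.
* Orthology grouping trusts the upstream reciprocal-best-hit calls;
  paralogy mistakes propagate.
* Trans-splicing, fuzzy coordinates and multi-assembly liftover are out
  of scope.
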