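# introntype

Genome-wide classification of spliceosomal introns into **U2-type**
(major spliceosome) and **U12-type** (minor spliceosome) classes, with the
evolutionary statistics and orthologous-intron grouping needed to study
how the two classes change over time.

Most introns are U2-type; U12-type introns are a rare minority recognised
by distinct extended motifs at the 5' splice site and branch point — not
by terminal dinucleotides, which overlap between classes. `introntype` is
for genome annotators and molecular-evolution researchers who need
per-intron class calls from a FASTA genome plus GFF3/GTF annotation, and
reproducible downstream tables (phase bias, −1 nucleotide composition,
terminal dinucleotides, within-gene clustering, cross-species ortholog
groups).

## Method

For every intron extracted from the longest isoform of each gene (CDS- and
exon-defined runs merged, CDS winning), two scores are computed as binary
log-ratios of position-weight-matrix probabilities, with pseudo-count
0.001:

* **5'SS score** — the 12-nt window from −3..+9 around the first intron
  base: `sum_i log2((U12_i[b] + pc) / (U2_i[b] + pc))`, positive = U12-like;
* **BPS score** — the best-scoring 12-mer within −55..−5 of the last
  intron base. Because U2-type introns lack an extended branch-point
  consensus, the U2 branch-point matrix is derived empirically per input
  set from the best U12-scored 12-mers of all introns whose 5'SS score is
  below the 95th percentile.

The (5'SS, BPS) vectors are classified by a linear-kernel SVM trained on
labeled sequences scored on the same scale; the penalty `C` is chosen by
iterative cross-validation on balanced accuracy (imbalance-robust), the
decision value is calibrated to a probability with a boundary-preserving
sigmoid, and an intron is called **U12-type at ≥ 90% probability**.

A synthetic-genome generator with planted motifs provides ground truth for
validation, so the whole pipeline is testable without downloads.

## Worked example

Simulate a 40-gene genome with ~5% planted U12-type introns, then run the
full pipeline:

```r
library(introntype)

cfg <- simulation_config(seed = 42, n_genes = 40,
                         introns_per_gene = c(2, 5), u12_fraction = 0.05)
sim <- simulate_genome(cfg)
ann <- tempfile(fileext = ".gff3"); writeLines(sim$gff, ann)

training <- simulate_training_set(1000, 20, cfg)   # U2 >> U12, as in real data
res <- classify_genome(sim$genome, ann, simulate_pwm_set(cfg), training,
                       seed = 42, assembly = "sim1")

res$model
#> linear intron-class SVM: w = (0.3796, 0.2165), b = -1.8682, C = 996,
#>   calibration slope = 200, seed = 42

calls <- merge(res$results, sim$truth[, c("intron_id", "class")],
               by = "intron_id")
table(planted = calls$class, called = calls$call)
#>        called
#> planted U12-type U2-type
#>     U12        7       0
#>     U2         0     127
```

All 7 planted U12-type introns are recovered with no false positives. Each
call carries its two scores (in bits; positive = U12-like) and calibrated
probability:

```r
head(subset(res$results, call == "U12-type"), 3)
#>                  intron_id five_ss    bps p_u12
#> 36 sim1:chr1:14995:15112:+   46.00  6.116     1
#> 47 sim1:chr1:18883:18991:-   34.50  6.116     1
#> 56 sim1:chr1:22736:22842:-   40.25 10.448     1
```

Downstream statistics work on the classified table, e.g. the per-class
phase-bias test against a uniform null (no bias expected here, since the
simulator plants phases uniformly):

```r
phase_bias_test(merge(res$introns, res$results[, c("intron_id", "call")],
                      by = "intron_id"))
#>   class n0 n1 n2   chi2 df p_value
#> 1    U2 38 43 46 0.7717  2  0.6799
#> 2   U12  2  3  2 0.2857  2  0.8669
```

A thin command-line wrapper (`inst/scripts/introntype.R`) exposes
`classify`, `stats`, `stats-dedup` and `simulate` subcommands over the
same functions.

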