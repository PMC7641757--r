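---
title: "Codon usage bias metrics and alignment-free population identification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Codon usage bias metrics and alignment-free population identification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonpop)
```

## The problem

Synonymous codons encode the same amino acid but are not used interchangeably:
genes, genomes and — the focus of this package — human populations show
reproducible preferences among synonyms. Because codon choice affects
translation speed, mRNA structure and expression, population-specific codon
usage is a candidate modifier of the effect of synonymous variants on disease.
`codonpop` computes six families of codon-usage-bias metrics from coding
sequences (CDS), tests for population-level differences, and asks a sharper
question: do codon-level biases alone carry enough signal to identify an
individual's population of origin, without any sequence alignment?

The package is organised around a tidy coding-sequence table (one row per
sample × gene × isoform × allele, built by `cds_table()` or
`read_cds_fasta()`); every metric function takes that table first and returns
a tibble, so analyses chain with the pipe.

## The metrics

* **Codon frequency** (`codon_counts()`): the 64-entry count vector per gene.
* **Codon aversion** (`codon_aversion()`): the set of codons a gene never
  uses. Stop codons are part of the aversion universe by default (64 codons),
  switchable to the 61 sense codons.
* **Identical codon pairing** (`codon_pairing()`): recurrences of the same
  codon within a ribosomal window, by default 9 codons — the approximate
  footprint of a ribosome. Two occurrences at positions $i < j$ pair when
  $j - i \le w - 1$. Each position counts at most once: position $j$ is
  paired if *any* earlier identical codon lies within the window, so a run of
  $k$ identical codons contributes $k - 1$, never a quadratic number. This
  de-duplication rule is a deliberate design choice — window-counting
  semantics are ambiguous in prose — and it is pinned by brute-force
  pair-enumeration oracles in the test suite.
* **Co-tRNA pairing** (`cotrna_pairing()`): the same window rule for
  synonymous but non-identical codons, aggregated per amino acid. Identical
  pairs are excluded, so single-codon families (Met, Trp) always score zero.
* **RSCU** (`rscu()`): relative synonymous codon usage,
  $\mathrm{RSCU}_c = k \, X_c / \sum_{c' \in \mathrm{fam}} X_{c'}$ for a
  family of size $k$ — observed over expected count under uniform synonymous
  usage. Families with no observations are reported as missing, not zero.
* **Nucleotide composition** (`nucleotide_composition()`): A/C/G/T counts and
  GC fraction.

Stop codons participate in frequency and aversion (where the terminal stop is
real signal) but never in pairing, which is defined over the 61 sense codons.
Codons containing ambiguity characters (e.g. `N`) are excluded from all
counts — their positions still occupy space in the window arithmetic — and a
message reports how many were dropped.

## Ramp sequences

A ramp is a stretch of slowly translated codons at the start of a gene that
spaces out ribosomes and reduces downstream collisions. Detection
(`ramp_scan()`, `detect_ramps()`) uses reference RSCU values as per-codon
speed proxies (`rscu_reference()`, pooled over a reference CDS set such as the
longest isoform of every gene), computes harmonic-mean speeds in all sliding
ribosomal windows, and calls a ramp when an outlier-slow window starts within
the leading fraction of the gene. The harmonic mean is used because speeds
are ratios and single fast codons should not mask a slow stretch.

Two parameters needed a concrete definition where common usage is loose:

* **Outlier rule.** A window is an outlier when its harmonic mean falls below
  $\mathrm{mean} - z \cdot \mathrm{sd}$ of all window means, with $z = 2$ by
  default (`outlier_z`). This is the simplest defensible rule; it is exposed
  as a parameter and pinned by tests rather than asserted as canonical.
* **Leading fraction.** "The beginning of the gene" is taken literally as the
  first percentile (`leading_fraction = 0.01`) of codon positions, with the
  guarantee that at least the first window start is always eligible (for a
  300-codon gene the first percentile covers only 3 window starts). Both the
  fraction and the window are parameters.

The reported ramp spans the gene start through the end of the contiguous
outlier region containing the leading outlier, in nucleotides
(3 × codons). `detect_ramps()` drops a terminal stop before mapping speeds,
errors on internal stops or zero-RSCU codons (a zero speed is undefined dwell
time), and skips genes shorter than the window with a warning.

## Population statistics

`pop_anova()` is the classical equal-variance one-way F test; follow-up
`pairwise_t_tests()` use Student's pooled-variance test by default (Welch
behind `var_equal = FALSE`) so that the attached pooled-sd Cohen's d
(`cohens_d()`) is consistent with the test. `pop_tukey()` wraps the
studentized-range comparison. Significance bookkeeping is Bonferroni
(`bonferroni_threshold()`), computed from the number of tests actually run in
a scan (`count_pairwise_tests()` gives the full-scan count: genes × codons ×
group pairs). `minor_allele_frequency()` defines the minor allele on the
pooled cohort, so a single population's frequency of that allele may exceed
0.5 — the convention that makes cross-population comparisons meaningful.

The grouping column is deliberately generic: the same functions apply to
superpopulations, subpopulations, or any other stratification.

## Alignment-free population identification

Per gene, a **motif** is the sorted tuple of codons that either pair at least
once (`mode = "pairing"`) or are averted (`mode = "aversion"`); per genome,
the motifs of all genes form a **set**, discarding gene names
(`gene_motifs()`, `genome_motif_sets()`). Between two genomes the package
uses the Jaccard distance $1 - |A \cap B| / |A \cup B|$
(`motif_distance_matrix()`): the set-union-normalised dissimilarity is the
natural reading of a union-based comparison, and the function is pluggable if
another normalisation is wanted. Co-tRNA motifs can be added to pairing mode
behind `include_cotrna` (off by default: identical pairing is the
conservative reading of "codon pairing").

Trees come from standard Saitou–Nei neighbor-joining (`nj_tree()`, via
\pkg{ape}); negative branch lengths, which NJ produces on non-additive input,
are clamped to zero with a message. To count clusters on an unrooted tree the
package midpoint-roots it (configurable) and counts, per population, the
maximal clades containing only that population's individuals — the largest
discrete groupings uninterrupted by any other population
(`count_population_clusters()`). Each population's cluster count $c$ and size
$n$ give the **percent predictive accuracy**
$100\,(1 - (c - 1)/n)$ (`percent_predictive_accuracy()`): 100 when the
population is a single clade, $100/n$ when every individual is separate.
`cluster_populations()` runs the whole chain and returns an object with
`tidy()`, `glance()` and `autoplot()` methods.

## The synthetic cohort generator

Real cohorts of resequenced individuals (the intended input, read from FASTA
with one record per sample/gene/allele) cannot ship with a package, so
`simulate_cohort()` builds populations whose *only* differences are
synonymous:

1. One amino-acid sequence per gene, shared by the entire cohort (start Met,
   terminal stop), so every codon difference between any two individuals is
   synonymous by construction.
2. A shared **base profile** of synonymous preferences, geometrically
   decaying within each family with ratio `base_bias = 0.35`. The base is
   biased on purpose: species-level codon usage is biased in real genomes,
   and rare synonyms with RSCU well below 1 are exactly what RSCU-based ramp
   detection feeds on; a uniform base would make "slow synonyms" barely slow.
3. Per-population preference profiles drawn around the base from a Dirichlet
   with concentration `concentration × family size × base`
   (`simulate_profiles()`). The default `concentration = 1` produces strongly
   divergent populations; large values collapse all populations onto the
   base.
4. A per-population **consensus** codon sequence drawn from its profile, and
   individuals that carry the consensus except at a sparse set of positions
   resampled from the profile (`polymorphism = 0.01` per codon). This mirrors
   resequencing data, where individuals differ from a shared sequence only at
   variant sites; it is what gives within-population motif sets their
   overlap. Drawing every codon independently per individual would make
   every motif set unique and all Jaccard distances exactly 1 — a
   structurally unusable null, not a hard instance.

`plant_ramp()` converts the leading `slow_prefix` codons (default 9) of a
gene to synonyms whose reference RSCU is closest to `speed_factor` times the
current codon's value (`speed_factor = 0` picks the slowest synonyms, 1
leaves the gene untouched), restricted to synonyms actually observed in the
reference. `simulate_genotypes()` draws Binomial(2, p) genotype tables with
population-specific allele frequencies for the minor-allele-frequency and
Tukey workflows. All generators are seed-deterministic.

What the generator does **not** emulate: linkage and recombination, shared
demographic history (populations are drawn independently rather than along a
phylogeny), amino-acid-level variation, isoform structure, and realistic
human codon-usage values. Passing tests on this cohort show that the
pipeline's machinery is correct and that the motif signal is recoverable when
populations truly diverge; they do not certify accuracy levels on real human
cohorts, where between-population divergence is far subtler.

## Numerical and degenerate-input choices

* Windows: `window = 9` means positions pair iff their difference is ≤ 8;
  `window < 2` is a parameter error; genes shorter than the window are
  skipped (ramp) with a warning rather than failing a whole cohort.
* RSCU of an unobserved family is `NA`; downstream consumers treat missing
  as missing rather than imputing zero.
* Identical constant groups give a t-test of $t = 0$, $p = 1$ and
  $d = 0$ rather than an error; zero pooled variance makes Cohen's d `NA`.
* Jaccard distance between two empty motif sets is undefined and raised as
  an error rather than silently set to 0 or 1.
* NJ ties are resolved by \pkg{ape}'s deterministic scan order, making the
  pipeline byte-reproducible for identical inputs; negative branch lengths
  are clamped to zero.
* Midpoint rooting is the default for cluster counting because it is
  deterministic and does not privilege any population; `root = "asis"`
  respects a pre-rooted tree.

## Problem sizes used by the test suite

The shipped tests exercise the defaults the generator declares: end-to-end
clustering on 3 populations × 40 genomes with 50 genes × 300 codons;
planted-ramp detection over 200 replicate genes; ANOVA calibration over
1,000 null replicates of 5 × 20 values; pairing-counter validation on
exhaustive small alphabets plus 1,000 random sequences of up to 30 codons.
These sizes were chosen so the whole suite runs comfortably on a laptop while
leaving the statistical checks enough replicates to be meaningful.

## Known limitations

* The pairing de-duplication rule, the ramp outlier statistic and the Jaccard
  normalisation are documented package choices among several defensible
  conventions; all are parameterised or pluggable, and results can shift
  slightly under other conventions.
* Percent predictive accuracy depends on the rooting used for clade counting;
  midpoint rooting is deterministic but not unique in pathological
  (perfectly symmetric) trees.
* The statistics module assumes approximately normal within-group values;
  codon counts are discrete, so F-test calibration is approximate at small
  per-gene counts (the test suite checks the 5% level within ±1.5 points at
  the sizes above).
* Haplotype materialization handles phased SNVs in CDS coordinates only;
  projecting genomic VCFs through gene annotations is out of scope.
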