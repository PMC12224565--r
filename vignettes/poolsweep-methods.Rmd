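---
title: "Methods: pool-seq selection scans with poolsweep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pool-seq selection scans with poolsweep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

DNA-pool sequencing (pool-seq) sequences a single library made from
equimolar DNA of many individuals — for example a breed pool of 10–20
rabbits. Genotypes are meaningless for such a library; the atomic
observation at a biallelic site is the pair of read depths supporting the
reference and alternative alleles, and the pool allele frequency is simply
`alt / (ref + alt)`. poolsweep implements a complete selection-signature
scan on such data: site differentiation, windowed statistics, empirical
outlier windows, candidate-region annotation, variant prioritisation,
population structure and gene-set enrichment, validated end to end against
a synthetic generator with planted sweeps.

# Site statistics

**Karlsson per-SNP F~ST~.** Treating reads as sampled alleles, with alt/ref
counts $a_j, r_j$ and depth $N_j = a_j + r_j$ in pool $j$:

$$h_j = \frac{2 a_j r_j}{N_j (N_j - 1)}, \qquad
  h_b = \frac{a_1 r_2 + r_1 a_2}{N_1 N_2}, \qquad
  F_{ST} = 1 - \frac{h_1 + h_2}{2 h_b}.$$

The estimator is symmetric in pool order, equals exactly 1 for
differentially fixed sites, and is undefined when $h_b = 0$ (both pools
fixed for the same allele) or when either depth is below 2 (the unbiased
divisor $N_j(N_j-1)$ needs two reads). Reads are plugged in directly as
alleles, with no effective-pool-size correction; this matches the
read-count definition of pool frequency and common pool-seq practice, and
is a documented limitation — at low depth the read sample underestimates
the number of distinct chromosomes sampled.

Three deliberate numerical choices:

* **Negative values are kept.** The unbiased estimator is slightly negative
  for near-identical pools (e.g. $-1/19$ at identical 10:10 counts).
  Clipping at 0 before window averaging would bias window means upward, so
  per-site and per-window values stay unclipped. Only the pairwise distance
  matrix truncates negative pair means to 0, because distances must be
  non-negative.
* **Site inclusion.** Only sites segregating and not fixed in the two
  populations being compared are used. We read this as *combined*
  segregation: both alleles must be observed in the union of the two pools'
  reads, which retains differentially fixed sites ($F_{ST} = 1$) — the
  strongest possible sweep signal. The stricter within-population reading,
  which drops them, is available via `rule = "within"`.
* **Group contrasts sum read counts** across the pools of a group before
  estimation, consistent with the read-count frequency definition. The
  alternative (averaging per-pool frequencies) would weight pools equally
  regardless of depth.

**Pooled heterozygosity H~P~.** Per window, with $\Sigma n_{MAJ}$ and
$\Sigma n_{MIN}$ the window sums of major- and minor-allele read counts
(major = the more frequent allele at that site in that pool/group):

$$H_P = \frac{2\,\Sigma n_{MAJ}\,\Sigma n_{MIN}}
             {(\Sigma n_{MAJ} + \Sigma n_{MIN})^2} \in [0, 0.5],$$

maximal exactly when the two sums are equal and depressed where diversity
has been lost. Raw H~P~ with percentile thresholds is used; no Z
transformation.

# Window scan

Chromosomes are tiled into non-overlapping 250 kb windows (0-based
half-open; a terminal stub window is emitted and almost always removed by
the variant-count rule). A window is kept only with **strictly more than
200** informative variants. From the kept windows, the outlier set at
percentile $q$ contains the $k = \mathrm{round}(N(1-q))$ most extreme
values; this rounding rule uniquely reproduces counts such as 52 windows
from 10 441 at the 99.5th percentile and 21 at the 99.8th, which floor or
ceiling conventions do not. Ties at the cut are broken by genomic position
so the result is order-invariant. The percentile distribution is computed
per contrast over kept windows only — the variant-count filter precedes
threshold selection.

F~ST~ outliers are upper-tail. For H~P~ the lower tail is the default
(reduced heterozygosity = sweep), exposed as a parameter since upper-tail
extremes (balancing-selection-like) can also be of interest.

Adjacent outlier windows — exactly touching, same chromosome — merge into a
candidate region; windows separated by one non-outlier window stay
separate. Each region core is extended by 125 kb on both ends, clamped to
the chromosome, and the extended span is what gene annotation and variant
prioritisation use.

# Population structure

Per-site F~ST~ values are averaged per pool pair over that pair's
informative sites (site sets differ between pairs), giving a distance
matrix. Clustering is agglomerative with average linkage (UPGMA) —
conventional for distance-based breed trees; single and complete linkage
are available. "PCA" on a distance matrix is implemented as classical
metric multidimensional scaling (Torgerson double-centring +
eigendecomposition), the natural ordination when no per-sample feature
matrix exists; variance explained per axis is its eigenvalue over the sum
of positive eigenvalues.

# Prioritisation and enrichment

A simplified region classifier (not a codon-level effect predictor) assigns
each variant one consequence by overlap priority CDS > UTR > exon of a
non-coding transcript > intron > intergenic, against one representative
transcript per gene (the longest-CDS transcript). CDS indels are frameshift
iff their length is not a multiple of 3. Variants are prioritised when they
(i) lie in an extended sweep region, (ii) overlap an exon *including UTRs*
(interpreted as the union of CDS and UTR intervals of the representative
transcript), and (iii) have alternative-allele frequency **strictly above
0.45** in at least one target group (an any-of disjunction over a
configurable group list; frequencies from group-summed read counts — the
per-pool alternative is not used, for the same depth-weighting reason as
above). *Private* means alt-frequency 0 in every other group; *fixed* means
read-count frequency exactly 1.0 in the target group (a tolerance flag,
default off, admits stray reads at high depth).

Enrichment of region gene lists against catalog term sets is the one-sided
hypergeometric upper tail (Fisher's exact over-representation test) with
Benjamini–Hochberg adjustment. The universe defaults to all genes of the
supplied annotation and is a parameter; published enrichment p-values from
web services depend on their library-specific backgrounds and are not
reproduction targets.

# The synthetic generator

`simulate_pool_experiment()` emulates the study design the pipeline is
meant for, and its defaults are fixed once:

* **Pools and depth:** pools of 14 diploid individuals (within the 10–20
  range of real breed pools), mean depth 12× (within the 6–17× range),
  depth per site per pool Poisson with minimum 1 — uneven coverage without
  a mapping model.
* **Breed structure:** a shared ancestral frequency (Beta(0.8, 0.8))
  perturbed by a two-level Balding–Nichols cascade: a group-level draw
  (drift 0.05 for dwarf and non-dwarf, 0.25 for wild, so wild pools are the
  most diverged, as in real wild-vs-domestic panels) and then a pool-level
  draw (0.03). Pool frequencies are finally discretised to allele counts
  over the pool's 28 chromosomes. Balding–Nichols gives single-parameter
  control of background F~ST~ at each level.
* **Sweeps:** inside planted intervals, the dwarf group's polymorphic
  frequencies shift toward fixation of the alternative allele,
  $p' = p + s(1 - p)$ with shift $s \in [0, 1]$. $s = 0$ is an exact null.
* **Sites:** density 0.0012/bp (~300 variants per 250 kb window, so the
  >200 rule keeps full windows), ~10% monomorphic sites (so segregation
  filters are exercised), ~5% short indels.
* **Genes and catalog:** a fixed-template gene (5′UTR — three CDS exons —
  3′UTR, 15 kb) tiled every 40 kb, every 7th gene non-coding; deterministic
  and convenient for interval tests. The phenotype catalog marks 20% of
  genes "height"-associated (80% inside sweeps, so enrichment has signal)
  and 5% "dwarfism".

Everything is driven by one integer seed; the same configuration reproduces
byte-identical files. The generator deliberately omits linkage
disequilibrium and haplotype structure, sequencing error, within-pool
relatedness (individuals are exchangeable) and coalescent ancestry. Passing
tests therefore demonstrate the estimators and the scan logic, not
robustness to LD-induced autocorrelation of window statistics or to
base-calling error in real data.

# Problem sizes used in validation

Test and acceptance runs use desk-scale genomes chosen so the percentile
machinery is non-degenerate: a 2 × 125 Mb genome (1000 windows) for sweep
recovery — four planted sweep windows against five 99.5th-percentile
outlier slots — a 2 × 25 Mb genome for 20-replicate null calibration, and a
2 × 5 Mb genome for fast structural tests. Sweep recovery, clustering
recovery of the dwarf/non-dwarf partition, and null non-enrichment were all
verified by Monte-Carlo before the thresholds in the test suite were
frozen.

# Known limitations

* Reads-as-alleles F~ST~ ignores the two-stage sampling (individuals into
  the pool, reads from the pool); at depths near the number of chromosomes
  in the pool it underestimates sampling variance.
* Chromosome names are taken as given; no cross-assembly renaming or
  liftover.
* Multi-allelic records are split against the same reference, which treats
  the alternatives as independent biallelic sites.
* The consequence classifier is positional only — no splice-site,
  stop-gain or protein-level annotation.
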