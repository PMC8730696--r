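---
title: "Methods: mapping a recessive locus with bulkmapr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mapping a recessive locus with bulkmapr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

bulkmapr implements the analysis chain used to localize a monogenic
recessive fruit locus — the tomato all-flesh-fruit (locule-gel) trait is the
motivating case — from segregation ratios through bulked-segregant
sequencing, recombinant fine-mapping, promoter conservation, and
population-level nucleotide diversity. Every stage consumes and returns
tidy tables, and a synthetic-data module generates all inputs with the
statistical structure the analysis assumes, so the whole pipeline can be
exercised and tested without any external sequencing data. This vignette
explains the models, the parameters that matter, the numerical choices, and
what the synthetic tests do and do not establish about real data.

## Segregation ratios

A monogenic recessive model predicts phenotype ratios of 3:1 in an F2 and
1:1 in a backcross to the mutant parent. `chisq_gof()` tests observed
counts against any theoretical ratio with the statistic

$$\chi^2 = \sum_i \frac{(|O_i - E_i| - c)^2}{E_i},
\qquad E_i = N\,\frac{r_i}{\sum_j r_j},$$

where $c = 0.5$ is the Yates continuity correction, applied by default for
two-class (1-df) tests and ignored (with a warning) otherwise. P-values are
right-tail $\chi^2$ with $k - 1$ degrees of freedom; `classify_fit()` calls
a population consistent with its ratio when $p$ strictly exceeds
$\alpha = 0.05$.

The Yates default is deliberate: on a published backcross table of this
kind (46:42 against 1:1) the corrected statistic reproduces the printed
0.102 exactly, while the uncorrected value is 0.182. For the companion F2
row (150:41 against 3:1) neither the uncorrected statistic (1.272) nor the
corrected one (1.091) equals the printed 1.176; the package reports its own
arithmetic and makes no attempt to reverse-engineer that figure. Exact
multinomial tests are out of scope in this version.

## Simulating the cross

`simulate_f2()` generates F2 individuals as unions of two independent
gametes. Along a gamete the allele switches between adjacent loci with the
Haldane recombinant fraction

$$r = \tfrac12\left(1 - e^{-2d}\right),$$

with $d$ in Morgans derived from physical spacing through a configurable
`cm_per_mb` rate. Haldane (no interference) is the simplest standard map
function and is all the downstream analysis requires. The causal locus is
simulated jointly with the markers even when it is not itself a marker, and
the phenotype is fully penetrant recessive: mutant if and only if
homozygous for the mutant-parent (P1) allele. Phenotyping error and
incomplete penetrance are deliberately absent from the default model.

`cm_per_mb` defaults to 4. Plant genome-wide averages are lower (~1–2
cM/Mb), but crossover events are concentrated in gene-rich euchromatic
chromosome arms — where loci of this kind are mapped — at roughly 4–5
cM/Mb, and a single uniform-rate chromosome stands in for such an arm. At
markedly lower rates the delta-SNP-index plateau around the locus widens to
tens of megabases and peak localization degrades; this is a property of the
design, not of the implementation.

`make_bulks()` draws disjoint simple random subsets of each phenotype class
(30 + 30 by default, matching the motivating design), and
`simulate_bulk_reads()` draws per-marker depths (Poisson around 30× by
default, or fixed) and mutant-allele counts that are binomial at the bulk's
realized allele frequency. Read counts never exceed depth and sequencing
error is not modelled: the generator produces the idealized signal the
method assumes, which is exactly what makes ground-truth recovery tests
interpretable.

## The delta SNP-index scan

For each bulk the SNP-index at a site is the fraction of reads carrying the
mutant-parent allele; `delta_index()` is the mutant-bulk index minus the
wild-type-bulk index, oriented so a recessive locus selected into the
mutant bulk drives $\Delta$ towards $+1$ (mutant-bulk index near 1,
wild-type near 1/3). Upstream, `filter_variants()` keeps sites where both
parents are homozygous for different alleles and every sample has at least
3 supporting reads.

`window_profile()` averages per-site values over 200-kb windows advanced in
20-kb steps, tiled from position 1 — the unweighted mean over member SNPs,
with windows holding fewer than `min_snps = 3` usable sites flagged missing
and excluded from calling. No smoothing or interpolation bridges empty
windows. Window means are computed with a rolling-sum over step-sized bins,
so the profile is linear in the number of sites.

`null_envelope()` simulates the no-linkage null at window scale: each
bulk's allele frequency at a site is the realized frequency among
$2 \times \text{bulk size}$ freely segregating chromosomes (each
mutant-parent with probability 1/2), read counts are binomial at the site's
depth, and a null window is the mean of $m$ such site deltas, where $m$
matches the observed window's SNP count. The envelope rows are the 95th and
99th percentiles of $|\Delta|$ over 10 000 simulations per SNP count;
profile windows are compared against the row matching their own $m$.
`call_regions()` flags windows whose mean delta exceeds the envelope at the
chosen level (99% by default) and merges overlapping or book-ended
significant windows, each region reporting its peak window. All deltas live
in $[-1, 1]$ by construction; published delta values above 1 arise from
scalings this package does not reproduce.

## Recombinant fine-mapping

`infer_interval()` narrows the locus from a panel of genotyped individuals
with known phenotypes. A marker position is excluded as a candidate
whenever any individual contradicts the recessive model there: a mutant
that is not P1-homozygous, or — in a panel of homozygous (fixed) lines — a
wild-type that is P1-homozygous. Segregating wild-types are never
exclusionary (a heterozygote carries the recessive allele silently), and
missing calls are uninformative. The candidate interval is the contiguous
span covering every non-excluded marker, bounded by its flanking excluded
markers. Excluded islands strictly inside the span (created by double
recombinants) are counted but never clip it: under that rule the causal
position of an error-free panel is provably inside the interval, and adding
individuals can only shrink it. Clipping to the largest run instead would
occasionally discard the causal side when an island splits the candidate
set — a case that does occur in simulated 100-line panels.

`interval_length()` reports both coordinate conventions explicitly because
published sizes mix them: the span between two flanking markers is the
flank difference ($right - left$), while a feature given by its first and
last base is inclusive ($right - left + 1$). `genes_in_interval()` counts
annotation overlap of at least 1 bp, strand-agnostic, in 1-based inclusive
coordinates.

## Promoter conservation

`column_diversity()` scores each alignment column as the fraction of
unordered row pairs that differ. The gap character is a fifth state — a
deletion is a real sequence difference — while `N` is excluded from pairing
entirely, and all-`N` columns are missing. "Conservation level" in the
source analyses is simply one minus this diversity; the package reports
diversity to match the published threshold convention (conserved regions
sit below 0.3).

`window_diversity()` averages columns over 50-bp windows stepped by 10 bp,
defined in the ungapped coordinates of a designated reference row so that
the profile shares one axis with features (such as a structural variant)
annotated on the reference sequence; columns where the reference carries a
gap map to no reference position and are skipped. For reference length
$L \ge 50$ the profile has $\lfloor (L-50)/10 \rfloor + 1$ windows.
`call_conserved()` merges maximal runs of windows below the threshold, and
`sv_overlap()` reports how much of a reference interval falls inside each
conserved region. In the motivating analysis the deletion belongs to the
mutant line, which is *not* a row of the multi-species alignment, so the
deletion enters as external reference coordinates; placing the gap-carrying
lineage inside the alignment would depress the local conservation call by
construction.

The generator, `simulate_promoter_family()`, evolves lineages independently
from one random ancestor with per-site substitution probabilities of 0.3
outside and 0.03 inside configured conserved blocks. Those defaults give
pairwise diversities of roughly 0.48 and 0.06, matching the contrast deep
multi-species promoter alignments show, and a 10:1 rate ratio is the regime
under which block recovery is tested (Jaccard ≥ 0.6 against truth blocks,
typically ≈ 0.9). Because only substitutions occur (plus at most one
configured deletion), alignment columns coincide with ancestral coordinates
— the generator does not model insertions or alignment error, so tests
exercise the scoring, not the aligner.

## Nucleotide diversity

Per-site diversity for a biallelic site with allele counts $(a, b)$ among
$n = a + b$ haplotypes is $ab / \binom{n}{2}$, the mean pairwise
difference. `region_pi()` sums site values over a region and divides by the
full region length — the conventional windowed-π definition in which
monomorphic positions contribute through the denominator; averaging over
variant sites only is available behind `denominator = "sites"`. Sites with
missing genotypes use the haplotype count observed at that site, and only
biallelic SNPs are considered (the VCF reader counts and skips the rest).
`gene_regions()` builds strand-aware 3-kb upstream / gene-body / 3-kb
downstream regions, truncated at chromosome bounds, and `rank_gene()`
reports the percentage of other genes with strictly greater π — the sense
in which a strongly conserved promoter sits below most of the genome.

The published genome-scale values for the motivating locus (body π = 0.21,
downstream 0.46, upstream 0.026 below 93.8% of genes) require the external
360-accession variome and are not reproduced here. Instead
`simulate_variome()` provides ground truth: variants are scattered at
configurable per-region densities with alternate-allele counts uniform on
$\{1, \dots, n-1\}$, under which the expected per-site π is
$(n+1)/(3(n-1))$ and the expected per-bp region π is the density times that
factor. Tests check exact agreement with an all-pairs Hamming oracle
(to $10^{-12}$), recovery of the truth expectation (class means within a
few percent at 120 genes), and recovery of imposed region-class orderings.

## Assay utilities

`ddct_fold_change()` implements $2^{-\Delta\Delta C_T}$ with one or more
reference genes aggregated by the arithmetic mean of their Ct values
(equivalent to a geometric mean of linear abundances; the aggregation
choice is stated because source methods typically name reference genes
without stating it). Fold changes are invariant to uniform Ct shifts.
`luc_ren_ratio()` normalizes firefly by Renilla signal per sample and
summarizes replicate groups by mean and sample (n−1) SD.

## Reproducibility and problem sizes

Every stochastic function takes an integer `seed` and restores the caller's
RNG state afterwards; fixed seeds give byte-identical outputs, which
`run_demo()` exercises end to end (the demonstration writes TSV/BED/
FASTA/VCF/GFF3 outputs plus a checksum manifest). The test-suite and the
acceptance script use desk-scale designs chosen to finish in minutes on one
CPU while keeping Monte-Carlo tolerances meaningful: 50 replicates of the
study-like scan design (F2 of 200, bulks 30/30, ~30× depth, one SNP per
10 kb on a 50-Mb chromosome), 10 000-simulation envelopes, 120-gene
variomes, and 5-kb five-lineage promoter families.

## Known limitations

* Peak localization under the study-like design is intrinsically marginal
  at the 1-Mb scale: the within-1-Mb rate across seed sets measures
  ~85–92%, limited by wild-type-bulk haplotype-frequency drift (the peak
  occasionally wanders 1–2 Mb), not by the estimator. Larger bulks or
  multi-chromosome designs with unlinked genome background would sharpen
  it.
* The generators omit sequencing error, phenotyping error, alignment
  error, indels (beyond the single configured deletion), multiallelic
  sites and family structure in bulk sampling; passing ground-truth tests
  therefore demonstrates correctness of the statistics, not robustness to
  those artefacts. Error-rate knobs exist in the cross model's design
  space but are off by default.
* One uniform-recombination chromosome stands in for a real map;
  interference and centromeric suppression are not modelled.
* The segregation module offers no exact multinomial test, and the scan
  implements only the delta-SNP-index statistic (no G-statistic or
  distance-based variants).
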