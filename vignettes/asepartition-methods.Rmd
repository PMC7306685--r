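---
title: "Partitioning cis- and trans-regulatory divergence in introgression hybrids"
author: "asepartition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning cis- and trans-regulatory divergence in introgression hybrids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asepartition)
```

## The problem this package addresses

When two closely related species hybridize, aberrant gene expression in the
hybrids (misexpression: expression outside the range of both parents) can
have two very different causes. It can reflect *regulatory
incompatibilities* — mismatches between a gene's own regulatory sequences
(cis elements) and the diffusible factors that act on them (trans factors)
that diverged in separate lineages — or it can be a *downstream symptom* of
hybrid dysfunction itself, such as the disrupted tissue composition of a
sterile anther. Distinguishing the two requires a design in which defined
heterospecific genome segments can be scored for their regulatory effects
with and without a known incompatibility.

The package implements the count-level analysis for exactly that design:
two inbred parental lines (labelled IM62 for the *Mimulus guttatus*-type
donor and SF5 for the *M. nasutus*-type recurrent parent) and two classes
of advanced backcross introgression hybrids that segregate in the same
families — STE individuals carrying a heterozygous donor introgression on
chromosome 6 (with a hybrid-male-sterility allele, *hms1*, that is
incompatible with the recurrent-parent genotype at *hms2*) plus a
drive-associated introgression on chromosome 11, and FER individuals
carrying only the chromosome 11 introgression. RNA-seq of stamens and
carpels, three biological replicates each, gives 24 libraries in eight
genotype-tissue groups. Reads aligned competitively against a diploid
pseudoreference fall into allele-specific counts (reads overlapping a
diagnostic SNP) and totals.

## Stages and their models

### Normalization and differential expression

Total counts are filtered to expressed genes (CPM > 1 in at least 3 of the
libraries), normalized for RNA composition by trimmed mean of M-values
(TMM: doubly trimmed — 30% of each M tail, 5% of each A tail —
precision-weighted mean of log ratios against a reference column, factors
rescaled to geometric mean 1), and modeled per gene as negative binomial
with a log link and effective-library-size offsets.

Dispersions are estimated by maximizing the Cox–Reid adjusted profile
likelihood (APL) on a log-spaced grid: the common value maximizes the APL
summed over genes; tagwise values maximize each gene's APL plus a
common-likelihood prior weighted as `prior_df / residual_df` (default 20
prior degrees of freedom), which shrinks gene-level estimates toward the
common value. Group means are profiled out by refitting at the common
estimate; for the one-way layouts used throughout, the Cox–Reid term is a
sum of log group weight totals and the mean fits are vectorized Fisher
scoring, one scalar parameter per (gene, group).

Contrasts are pairwise group differences tested by likelihood ratio. With
a fold-change threshold `tau` (default 1.25 log2 units) the null is the
composite |log2FC| <= tau; the statistic is evaluated at both boundaries
through constrained fits (the contrast pinned at ±tau, which for a
pairwise contrast is a one-parameter offset fit), the two boundary tail
probabilities are summed, capped at 1, and floored at the unthresholded
p-value. The floor makes the threshold test conservative relative to the
plain test for every gene by construction, the behavior a threshold test
must have. Significance means BH-adjusted FDR <= 0.05 within the tested
gene set, per contrast.

On fully null simulated data this test holds its size: with 10,000 genes,
two groups of three replicates, dispersion 0.1, the fraction of raw
p-values at or below 0.05 is 0.051–0.058 across seeds (the acceptance
script recomputes this), and the p-value distribution passes a
Kolmogorov–Smirnov uniformity check.

The sample-level overview plot uses leading log-fold-change distances —
the root-mean-square of the 500 largest absolute log-CPM differences per
sample pair (prior count 2 on the CPM scale) — embedded by classical
metric scaling.

### Genotyping and introgression blocks

Per-gene genotypes come from the binary presence/absence of each parental
allele in the pooled allele-specific counts of a line (six libraries:
both tissues, three replicates). Pooled counts below 10 are treated as
absent; presence of both alleles is HET, one allele is IM62 or SF5, and
neither is nonexpressed. Two pooling orders are available: the default
sums replicates before applying the floor (the floor reads as a pooled
depth requirement); the alternative zeroes sub-threshold libraries first.
In hybrid lines, IM62-only calls are biologically impossible under the
crossing scheme and are flagged erroneous and treated as no-calls.

Introgression blocks are maximal runs of HET genes along the annotation
order. Nonexpressed (and flagged) genes never break a run; any confident
homozygous call does. Both an inner span (HET gene extremes) and an outer
span (to just inside the flanking terminating genes) are reported; the
inner span is the conservative bound used downstream. On simulated data
with expression high enough that every block gene passes the depth floor,
recovered blocks equal the planted blocks exactly; with weakly expressed
genes inside a block, a heterozygous gene whose minor allele misses the
floor is called homozygous and truncates the block — the same behavior the
binary rule produces on real data, which is why the depth floor matters.

### Inheritance categories

Each hybrid line and tissue is classified per gene from three threshold
DE results (hybrid vs SF5, hybrid vs IM62, parents) into eight
categories: similar, SF5-like (similar/divergent), IM62-like
(similar/divergent), intermediate (divergent), and misexpressed
(similar/divergent), with misexpression direction recorded as over- or
under-expression. "Between the parents" is determined by opposite signs
of the two hybrid-vs-parent fold-changes. Two cells of the 3-bit-by-sign
table are not named by the eight-category scheme and are resolved
explicitly:

* hybrid distinguishable from neither parent while the parents differ —
  the hybrid necessarily lies within the parental range, so the gene is
  assigned intermediate (divergent) and flagged `intermediate (no test
  significant)`;
* hybrid distinguishable from both parents, between them, parents not
  significantly different — no category fits; the gene is flagged
  `unclassifiable` and excluded from category tallies rather than forced.

Joint parental tissue bias (stamen vs carpel within each parent, same
threshold test) is collapsed to nine classes: biased the same way in
both parents, biased in one parent only, opposing, or unbiased. In
cross-tabulations, opposing genes count as stamen-biased and
carpel-biased in at least one parent simultaneously.

### Cis/trans partitioning

For heterozygous introgression genes, two log2 fold-changes are compared:

* **pFC** — SF5 vs IM62 parental totals (cis + trans divergence), tested
  *without* the fold-change threshold so compensatory changes are not
  overestimated;
* **aFC** — SF5 allele vs IM62 allele within the hybrid (cis divergence
  alone, both alleles sharing one trans environment), from a per-gene NB
  GLM on the six allelic counts with an allele factor and a replicate
  blocking factor.

Genes with significant pFC or aFC are tested for trans divergence by a
two-sample equal-variance Student's t between replicate-level parental
log ratios and hybrid allelic log ratios (replicates paired by index; a
CPM prior of 0.5 guards zeros), BH-corrected within the tested set. The
rule table then assigns cis only, trans only, cis + trans (reinforcing
when |pFC| > |aFC|, opposing otherwise; a tie falls to reinforcing, a
measure-zero event), cis × trans (opposite signs), compensatory,
conserved, or ambiguous. Trans only follows the rule's literal wording
(pFC significant, aFC not) without additionally requiring the trans test.

**Allelic offsets.** What to use as "library size" for an allelic count
is genuinely open. Genome-wide per-allele totals are dominated by the
homozygous recurrent-parent background (nearly all background reads are
SF5), and block-restricted per-allele totals are tilted by whichever cis
effects the block happens to carry; both choices shift every aFC by a
common composition term, which simulation makes visible as a systematic
bias of several tenths of a log2 unit. The default is therefore
symmetric: each sample's total allelic depth split equally between
alleles, since both alleles of a heterozygous gene are sequenced from the
same library and the replicate factor already absorbs depth. The
block-restricted alternative is exported (`block_allele_lib_sizes()`) and
can be passed through `allele_lib_sizes`.

Tissues whose misexpressed fraction exceeds 10% get a caution flag on
their regulatory inference: when a tissue is grossly disrupted,
allele-specific patterns may reflect altered cellular composition rather
than regulatory divergence.

The association between compensating regulation (cis + trans opposing,
cis × trans, compensatory) and misexpression is tested by Pearson
chi-square (no continuity correction) on 2×2 tables against conserved
genes and against other divergent classes.

### Pseudoreference construction

At toy scale the package reproduces the reference-building step: biallelic
SNPs filtered at mapping quality >= 40 and quality-by-depth >= 2 are
substituted into the reference FASTA (indels excluded by construction, so
coordinates stay shared between haplotypes; heterozygous calls are applied
like any other filtered SNP, since zygosity handling is not specified by
the construction being mirrored), and the two haplotypes are merged with
allele suffixes on chromosome, gene and transcript names. FASTA output is
fixed at 60 columns for determinism.

## The synthetic-data generator

The generator is the package's ground-truth instrument. Each gene gets a
baseline (log2 CPM, normal with mean 4, sd 2 — a realistic bulk RNA-seq
abundance spread), a stamen-vs-carpel effect (normal, sd 1.5, giving
substantial tissue-biased fractions at the 1.25 threshold), a cis effect
`c` and trans effect `r` set by its regulatory category, a hybrid trans
modifier `m`, a misexpression effect `delta` confined to STE stamens, and
an NB dispersion (0.05 by default, a typical inbred-line replicate
variance). On the log2 scale relative to baseline-plus-tissue:

| sample | total mean |
|---|---|
| SF5 parent | `b + t` |
| IM62 parent | `b + t + c + r` |
| hybrid, het gene | sum of alleles: SF5 `b + t - 1 + m r`, IM62 `b + t - 1 + c + m r` |
| hybrid, background gene | `b + t + m r` |

The `-1` halves each allele in heterozygotes so total hybrid expression is
conserved under `c = 0`: additive inheritance is the null. `m` defaults
to 0 (trans factor in the recurrent background) and is 0.5 for a
configurable 15% of trans-affected genes (trans factor flagged inside a
heterozygous introgression), reproducing the direction of incomplete
dominance of donor trans alleles without modeling factor positions.
`delta` (default 22% of genes, magnitudes 2–4, both signs) is a
phenomenological stand-in for the downstream consequences of sterility —
no mechanism linking the incompatibility to misexpression is modeled.

Counts are gamma–Poisson: one gamma noise multiplier per (gene, sample)
shared by the IM62-allele, SF5-allele and non-allele-specific Poisson
components, so each component is marginally NB with dispersion phi, the
components are positively correlated as reads from one library must be,
and the total is exactly NB. A configurable 43% of reads (the share of
primary alignments without a diagnostic SNP in the emulated design) is
non-allele-specific and counted in totals only. Category allocation is
deterministic by count (`round(fraction * n_genes)`); placement, signs
and magnitudes are drawn from a single seeded stream in documented order.

Default problem sizes are desk scale — 2,000 genes in the pipeline
default, ~500–1,000 in most tests, chosen so the whole suite and the
acceptance script run in minutes while every group still contains tens of
genes per category. The generator emulates count-level structure only: no
read-level effects (mapping bias, positional coverage), no linkage between
neighboring genes beyond block membership, no dominance beyond the `m`
modifier, and replicates are exchangeable. Passing recovery tests
therefore show the estimators are correct under the stated model, not
that real libraries satisfy that model.

## The crossing-scheme simulator

`simulate_rsb_cross()` forward-simulates the recurrent-selection
backcross: each generation a pollen-sterile (hms1-heterozygous)
individual is backcrossed to the recurrent parent, so final progeny are
heterozygous at hms1 with probability 1/2 — and sterile exactly then,
since the background is fixed for the incompatible recurrent-parent hms2
genotype. The chromosome-11 drive introgression is transmitted with
probability 0.98. Background heterozygosity per progeny is simulated as
400 unlinked markers each heterozygous with probability
`expected_het_fraction(n_backcrosses) = 0.5 / 2^n`, which for the
8-backcross design prints as 0.2% of the genome.

## Numerical choices

* Dispersion grid: 41 log-spaced points on [1e-6, 4] with local quadratic
  refinement; tagwise floor 1e-8. Two mean-fit passes (initial phi 0.1,
  then the common estimate).
* NB mean fits: Fisher scoring with step clamping (±5) and coefficient
  bounds (natural log ±45/15) so all-zero groups stay finite; likelihood
  contributions use a 1e-10 mean floor.
* Threshold-test p-values: floored at the plain-test p and capped at 1.
* Degenerate t-test inputs (zero pooled variance): t = 0, p = 1 when the
  means agree; ±Inf, p = 0 when they differ.
* Ties: |pFC| = |aFC| classifies as reinforcing; `sign(0)` counts as
  "between" in the inheritance table.
* The expression filter is applied once on the full design before any
  contrast; BH correction is per contrast within the tested gene set.
* TMM: genes zero in either column are excluded; an all-zero column is an
  error; a column identical to the reference returns factor 1 exactly.

## Known limitations

* Contrasts are pairwise group differences only — all contrasts the
  workflow needs — not arbitrary linear combinations.
* The dispersion model has no abundance trend; tagwise estimates shrink
  toward a single common value.
* The QL F-test machinery of the established DE toolchain is deliberately
  replaced by the LRT described above; significance calls, not exact
  p-values, are the contract, and the package's categories depend only on
  the calls.
* The t-based trans test inherits the replicate-pairing convention
  (pairing parental replicates by index); the pairing is arbitrary for
  independent plants, and alternative conventions would change per-gene
  p-values slightly but not the construction.
* The generator draws per-gene effects independently; co-regulated gene
  modules, which inflate between-gene correlation in real data, are not
  emulated, so genome-wide error rates on real data can exceed the
  nominal rates achieved here.

## A minimal run

```{r run, eval = FALSE}
cfg <- pipeline_config(sim = sim_config(n_genes = 500, seed = 7),
                       out_dir = "results_run", seed = 7)
bundle <- run_pipeline(cfg)
bundle$summaries$venn$stamen
table(bundle$inheritance$STE_stamen$category)
head(bundle$regdiv$STE_carpel)
```
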