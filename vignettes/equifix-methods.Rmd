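---
title: "Methods: diversity, inbreeding and fixed-variant scanning in small WGS cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diversity, inbreeding and fixed-variant scanning in small WGS cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(equifix)
```

`equifix` packages the downstream arm of a whole-genome resequencing study
of a small diploid cohort: once genotypes exist in a multi-sample VCF, it
summarizes the callset, quantifies diversity and inbreeding, and screens for
breed-specific fixed variants and known Mendelian-trait alleles. This
vignette documents the statistical models, the defaults and why they were
chosen, what the synthetic-data generator does and does not emulate, and the
numerical conventions.

## Data model

All analyses run off a `variant_cohort`: per-site chromosome, position,
reference/alternate alleles; per-genotype diploid allele indices and depth
(`DP`); and consequence annotations parsed from VEP `CSQ` or SnpEff `ANN`
strings into one schema (gene, consequence term, impact, exonic flag).
Impact is always *recomputed* from the consequence term through a fixed
mapping (nonsense/splice-site/frameshift → HIGH; protein-changing in-frame →
MODERATE; synonymous/splice-region → LOW; else MODIFIER), so a file whose
annotator disagreed with this mapping is normalized rather than trusted.

Matrix statistics use a `genotype_matrix`: samples × biallelic sites with
codes 0/1/2 counting **alternate**-allele copies and `NA` for missing. The
per-site frequency $p_i$ is always recomputed from the non-missing calls;
the INFO `AF` field is kept only for reporting. Counting the alternate
allele consistently (rather than "the minor" or "the reference" allele,
which the common formula statements mix freely) is safe because every
estimator here is invariant to which allele is focal — a property the test
suite checks by swapping ref/alt at every site.

Coordinates are 1-based inclusive (VCF convention); windows are 1-based
half-open $[s, s+W)$ and converted to 0-based half-open only when written as
BED.

## Heterozygosity and nucleotide diversity

Per biallelic site, $H_o$ is the fraction of heterozygous calls among
non-missing genotypes and $H_e = 2p(1-p)$. Genome means average across
sites (not individuals); per-sample heterozygous fractions are reported
separately for QC. $H_e$ is uncorrected by default; the $n/(n-1)$
small-sample factor is available as a flag so the default matches the
VCFtools-style convention used in cohort reports.

Nucleotide diversity uses the unbiased pairwise form per site,
$\pi_{site} = 2j(n-j)/(n(n-1))$ with $n$ the non-missing allele count and
$j$ the alternate count — equal to the mean number of differences over all
$\binom{n}{2}$ sequence pairs, which is exactly how the oracle in the test
suite computes it. Window diversity divides the summed site contributions
by the **full window length**, i.e. positions absent from the VCF are
assumed invariant. This is the standard VCF-only convention and is stated
explicitly because window size, step and denominator are rarely printed in
study methods; the defaults are 10 kb non-overlapping windows, both
configurable. The genome mean is the length-weighted mean over windows
(final windows on a chromosome may be short). The report also projects
$\pi$ onto a configurable genome size (default 2.5–2.7 Gb, the horse genome
range) as an expected count of pairwise differences.

Sites with fewer than two called alleles cannot contribute a pair and are
skipped but counted.

## GRM and the three inbreeding estimators

With $Z$ the dosage matrix centered per site ($x - 2p$, unscaled) the
relationship matrix is pooled-denominator VanRaden method 1:

$$\mathrm{GRM} = \frac{ZZ'}{2\sum_i p_i(1-p_i)}.$$

The three estimators are implemented exactly as their printed formulas:

- $F_{GRM,i} = \mathrm{GRM}_{ii} - 1$,
- $F_{HOM} = \dfrac{N_{OHom}-N_{EHom}}{N_{NonMiss}-N_{EHom}}$ with
  $N_{EHom} = \sum (1 - 2p_i(1-p_i))$ over the sample's non-missing sites,
- $F_{UNI} = \dfrac{1}{n}\sum_i
  \dfrac{x_i^2-(1+2p_i)x_i+2p_i^2}{2p_i(1-p_i)}$.

Two deliberate conventions, because the formulas as usually printed are
internally inconsistent about scaling:

1. The GRM pools its denominator while $F_{UNI}$ standardizes per site.
   Both are kept as printed; GCTA's default $F_{GRM}$ ("diagonal of GRM")
   uses per-site scaling instead, so `build_grm(scaling = "per_site")`
   provides that variant. The pooled and per-site diagonals differ on real
   data with a skewed frequency spectrum.
2. Missing genotypes are imputed to $2p_i$ (zero after centering) inside the
   GRM — this keeps it positive semidefinite — while $F_{HOM}$ and
   $F_{UNI}$ instead skip missing sites per sample with $n$ reduced
   accordingly.

$p_i$ for all estimators is the full-sample frequency including the focal
individual. The consequence, visible in both simulations and small real
cohorts, is a downward bias of order $1/(2N)$: with $N = 20$ individuals
each genome contributes $1/40$ of the frequency estimate, so truly
non-inbred cohorts tend to report slightly negative means. The package does
not "correct" this, because the estimators are implemented as defined; the
parameter-recovery tests therefore run at $N = 200$, where the bias
(≈ 0.0025) is far below the ±0.03 acceptance band.

Sites must be polymorphic ($0 < p < 1$) before any estimator runs — a
monomorphic site reaching `build_grm()` or `f_uni()` is a hard error, not a
silent skip — and the relationship-matrix site set applies the strict
`MAF > 0.05` filter on biallelic autosomal SNPs.

PCA eigendecomposes the (symmetrized) GRM; scores are
$v_k\sqrt{\lambda_k}$; explained variance is $\lambda_k / \sum \lambda$.
Eigenvector sign is fixed by making the largest-magnitude loading positive,
so plots reproduce across platforms.

## The fixed-variant cascade and candidate genes

The scan applies, in this order: **fixed alternative allele** (every sample
homozygous for the same alternate allele; a missing genotype disqualifies
the site under the strict default, with `allow_missing = TRUE` relaxing to
"all non-missing calls are hom-alt"), then **depth** (`DP >= 10` in every
sample, boundary inclusive; missing DP drops the site conservatively), then
**autosomes**, mirroring the order in which such cascades are narrated in
breed-scan studies. Candidate genes are those with at least 5 distinct
surviving variants whose per-gene most-severe consequence is exonic with
HIGH or MODERATE impact. "Exonic" excludes splice-donor/acceptor (intronic
positions) and, by default, UTR terms; `include_utr = TRUE` widens the
definition, and `impact_set` is a parameter because study descriptions
oscillate between "high" and "high or moderate". A variant annotated to
several genes counts once per gene.

Every stage's survivor set is a subset of the previous stage's, and all
outputs are invariant to input record order; both are enforced by tests.

## The synthetic cohort generator

The generator is first-class, tested code: it is the package's ground-truth
instrument. Defaults emulate the motivating study conditions: **20 diploid
individuals**, **31 autosomes + X**, per-genotype Poisson depth with mean
**21×** (the coverage implied by ~380 M 140-bp read pairs on a 2.5 Gb
genome), **8.5% indels** (the biallelic indel share of such callsets), and a
U-shaped **Beta(0.5, 0.5)** alternate-allele frequency spectrum, a standard
stand-in for a neutral site-frequency spectrum folded onto (0,1). Values
the study design does not pin down were chosen once at desk scale:
chromosome length 2 Mb and site density 2 × 10⁻⁴/bp (≈ 13 k sites over 32
chromosomes), small enough for fast test cycles and large enough for stable
genome-wide means.

Genotypes are drawn marginally from inbreeding-adjusted Hardy–Weinberg
proportions

$$P(0) = (1-p)^2 + Fp(1-p),\quad P(1) = 2p(1-p)(1-F),\quad
  P(2) = p^2 + Fp(1-p),$$

clamped at zero and renormalized (with a message) when $F$ lies outside the
feasible range for an extreme $p$. Inbreeding is therefore *marginal* per
genotype — there are no ROH tracts, no pedigree, no linkage disequilibrium
and no recombination map. That is sufficient for recovering the three
estimators and the diversity statistics, which are all single-site
functionals, but it means passing tests say nothing about haplotype-scale
structure in real data. Exonic consequence labels (missense, stop-gain,
frameshift, …) are *assigned* with configured proportions, not derived from
codons, since no coding sequence exists; downstream logic consumes labels
only. Positional classes are genuine geometry against simulated gene
models: intergenic beyond 5 kb of any gene (the VEP default flank, used
because annotation-tool distance options are rarely reported),
strand-aware upstream/downstream within 5 kb, intron inside a gene, exon
inside an exon, with the most gene-proximal class winning and ties broken
by lower gene id.

Planted truth is exact: fixed-variant injections set every genotype
homozygous-alternate; catalog injections place each variant at its stated
coordinate with exactly the requested number of heterozygotes (colliding
positions shift by +1 bp with a warning). The same spec and seed produce a
byte-identical VCF.

## Catalog scanning

Catalog variants match cohort records on normalized chromosome name (plain
names and RefSeq accessions are interconvertible through a bundled alias
table) and left-normalized position: shared suffix bases are trimmed, then
shared prefix bases with the position advanced, which reconciles HGVS-style
delins coordinates with anchor-base VCF records. "Segregating" is defined
as at least one observed non-reference allele and not fixed — studies
select "based on the number of heterozygote genotypes" without a formal
definition, so the package states one and reports `fixed` and `absent`
statuses separately. MAF is folded, $\min(q, 1-q)$, with missing genotypes
excluded from the denominator. Catalog `a1`/`a2` labels are reported as
given even where they are not the minor allele; frequencies always come
from genotypes.

## Numerical and reporting conventions

Percentages print at 2 decimals with half-up rounding. Summary classes
partition: per-chromosome totals are recomputed by summation (never
stored), the per-class table reduces each variant to one most-severe
consequence so its total equals the biallelic total, and the 1-Mb density
bins' four display groups (intron / intergenic / up-or-downstream / other)
partition each bin. The "exon region" share reported by the class summary
counts every class except intergenic, intron, upstream and downstream —
i.e. UTR and splice classes included — which is the convention that makes
the printed exonic percentages of published callsets reproducible from
their class tables; the candidate-gene rule uses the narrower exon
definition described above.

## Problem sizes and limitations

The test suite runs estimator-oracle comparisons at ≤ 8 samples × 30 sites
(tolerance 1e-10), diversity oracles at ≤ 10 × 50, parameter recovery at
200 samples × 10⁵ sites for F ∈ {0, 0.1, 0.25} (±0.03), and end-to-end
scans on ~13 k-site simulated cohorts — sizes chosen so the whole suite
completes in well under a minute of estimator time while keeping Monte
Carlo error far inside the asserted bands.

Known limitations: no ROH or haplotype-based inbreeding, no cross-population
statistics (F_ST), no variant calling or re-annotation (annotations are
consumed, not computed), no polyploid genotypes, and multiallelic sites are
excluded from all matrix statistics (they are counted in summaries but not
decomposed). The dual variant-calling pipelines some studies run are out of
scope: the package consumes a single reconciled VCF.
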