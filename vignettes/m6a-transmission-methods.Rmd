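---
title: "Methods: 6mA methylation and DNA-to-RNA genotype transmission"
author: "m6atrans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 6mA methylation and DNA-to-RNA genotype transmission}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes and why the
pieces are designed the way they are. It states no empirical result that the
test suite or `scripts/acceptance.R` does not itself compute.

## The scientific question

DNA N6-methyladenosine (6mA) is called per strand at single-base resolution
from SMRT sequencing kinetics. Two questions drive the analysis:

1. **Stability.** Do genes carrying 6mA accumulate fewer DNA (and RNA)
   variants than unmethylated genes?
2. **Selective transmission.** At a DNA variant site, the RNA genotype can
   reproduce the DNA genotype (0/1 to 0/1, 1/1 to 1/1) or disperse away from
   it (e.g. 0/1 to 0/0). Does methylation bias which of the six possible
   DNA-to-RNA transmit types occurs?

The unit of analysis is the gene. For gene *i*, the design row holds the
methylation indicator, the 6mA density `y_i = n_6mA / n_A` (sites per
coding-strand adenine), and the counts `x_i1..x_i6` of the six transmit
types among the gene's classified variant sites.

## Models

Two regressions, fitted on the per-gene feature table:

* **Logistic** (all genes): `logit P(methylated_i) = b0 + sum_n b_n x_in`,
  maximum likelihood via IRLS, Wald z per term. This asks which transmit
  types are enriched in methylated genes *conditional on the others*.
* **Linear** (methylated genes only, where density is nonzero by
  construction): `y_i = a0 + sum_n a_n x_in + e_i`, ordinary least squares,
  t statistics. This asks how the methylation *level* scales with each
  transmission behaviour.

Inference is Wald rather than likelihood-ratio, matching the conventional
regression summary table, and p-values are reported raw (a
Benjamini–Hochberg adjustment can be applied downstream; the package does
not apply one because each table has at most six terms and the tables are
read term-wise).

Covariate handling is explicit rather than silent:

* all-zero or constant columns are dropped ("all zero"/"constant");
* exactly collinear columns are dropped by QR rank ("collinear");
* a column whose nonzero support lies entirely in one response class has no
  finite ML coefficient. If its presence/absence reproduces the response for
  *every* gene the data are completely separated and the fit is a declared
  failure naming the covariate; otherwise (the typical case: a rare
  homozygous-dispersal type observed in a handful of genes, all of one
  class) the column is dropped with reason "one-class support". This is why
  real studies print four-term tables: the two rare types 1/1_0/0 and
  1/1_0/1 routinely lose finite support.

Group comparisons (variation ratios, imprinting contrasts) use Student's
equal-variance t-test by default — the convention in this literature — with
Welch available via `var_equal = FALSE`. Two identical constant groups
return t = 0, p = 1 by convention rather than erroring.

## Key definitions and rules

* **Depth filter**: a site is *removed* iff coverage is strictly less than
  the cutoff (autosomes and sex chromosomes have separate cutoffs because a
  male genome has half the sex-chromosome depth). Boundary coverage is kept.
  The default `depth_thresholds(30, 15)` is a typical 30x/15x regime;
  studies with other sequencing depths set their own pair. Filtering is
  idempotent.
* **Strand rule**: a gene is methylated iff a site lies in its body *on its
  coding strand*; the density denominator `n_A` counts A in the plus-strand
  sequence for `+` genes and T for `-` genes. The on-gene methyloci summary
  uses the same strand-matched membership so that "sites on genes" and
  "methylated genes" are consistent with each other.
* **Gene-body assignment**: gene-level quantities use the whole body
  (introns included); variation ratios divide by `end - start + 1`. Region
  level analyses partition the body under the precedence UTR > exon >
  intron (UTR records lacking a 5'/3' tag are kept as a single UTR class).
  A site or variant inside two overlapping genes counts in each gene's row
  (per-gene independence keeps the regression rows well defined); the
  region *distribution* instead collapses each position to its single
  highest-precedence label so fractions sum to one.
* **Methylated variation**: a DNA variant coincides with a 6mA site
  positionally *and* its REF base is the adenine of the site's strand (A
  for +, T for −, since VCF REF is plus-strand). Bare positional overlap is
  available with `require_base = FALSE`; discordant overlaps are tallied.
* **RNA 0/0 inference**: variant callers never emit homozygous-reference
  rows, yet the X/X_0/0 transmit types require them. The package infers
  0/0 at a DNA variant site iff an RNA coverage track shows at least
  `min_rna_depth` (default 30, mirroring the >30X RNA variant filter).
  Sites with neither an RNA call nor adequate coverage are excluded and
  tallied — every DNA variant ends up classified, allele-discordant, or
  insufficient-coverage, with counts that sum exactly.
* **Cross-sample consistency**: sites match on (chrom, pos, strand) with
  coverage taken as the pairwise minimum; transmission events match on
  (chrom, pos, ref, alt, transmit type) — the *event*, not just the locus —
  with a position-only key available by flag.
* **Coordinates**: 1-based closed intervals everywhere in memory, the
  native convention of IRanges/GenomicRanges that all interval joins are
  delegated to; conversion happens only at the BED boundary (0-based
  half-open). Using the container library's convention end to end is the
  most reliable way to avoid off-by-one errors in R.

## The synthetic-data generator

`simulate_truth()` / `simulate_study()` produce a complete study with known
ground truth. What it emulates, and the defaults:

* a multi-chromosome genome (3 autosomes + chrX, ~40% GC) with 2,000
  non-overlapping genes, lognormal lengths (median ~3 kb), ~45% on the minus
  strand; short exons (mean 120 bp, up to 5 per gene) with terminal UTRs, so
  gene bodies are intron-dominant as in real genomes;
* per-gene latent methylation (probability 0.5); methylated genes receive
  6mA sites on coding-strand adenines at a Beta(2, 250) per-adenine density,
  plus an intergenic both-strand background (2 per 1,000 adenines) so a
  realistic share of methyloci is not on genes; an AGGYR context is planted
  around 30% of genic sites (the known human 6mA motif shape; the A is the
  methylated base);
* per-site coverages ~ NegBin(mu = 45, size = 8), deliberately straddling
  the 30/15 depth cutoffs so filtering removes a nonzero, known subset;
* DNA variants at 0.10% per base in methylated genes versus 0.21% in
  unmethylated genes — the headline stability contrast — and 0.15%
  intergenic; genotypes 0/1 with probability 0.7; 98% of variants appear in
  the emitted dbSNP list;
* RNA genotypes drawn per variant from a transmission matrix conditioned on
  the gene's methylation: methylated genes favour identity transmission
  (rows (0.05, 0.90, 0.05) for 0/1 and (0.05, 0.05, 0.90) for 1/1 over
  RNA 0/0, 0/1, 1/1), unmethylated genes spread mass
  ((0.25, 0.60, 0.15) and (0.20, 0.15, 0.65)); 90% of genic variant sites
  have adequate RNA coverage, the rest are unassessable;
* an imprinted-gene subset at the realistic fraction 204/58,677; for a
  sample pair, a shared master set of sites (85% retained per sample) and
  variants (90%) over one shared genome, so consistency intersections are
  non-trivial.

Everything is deterministic in the seed (byte-identical bundle reruns), and
the ground-truth tables record both the latent class and the per-sample
observable state (e.g. methylation after depth filtering), which is what
the pipeline can be held to exactly.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: read-level errors and mapping artefacts (variants
are planted, not called), linkage and mutational spectra (variant positions
are uniform within a gene; alt alleles uniform), expression-dependent RNA
coverage (coverage is drawn per site, not per transcript), kinetic
false-positive 6mA calls, overlapping genes, and any correlation between
6mA density and variant count beyond what gene length induces. Recovery of
the planted regression signs on synthetic data validates the machinery, not
the biology.

One consequence worth stating: with identity transmission *and* a lower
variant rate in methylated genes, the per-gene count of identity events is
similar between classes (rate and fidelity offset each other), while
dispersal-type counts are several-fold higher in unmethylated genes. The
logistic fit therefore shows strong negative dispersal terms and a positive
heterozygous-identity term; the homozygous-identity term is attenuated at
the default rates. The direct feature-row generators
(`simulate_feature_rows()`, `simulate_linear_rows()`) plant coefficients
explicitly (logistic −0.5 intercept, +0.12 and +0.13 on the two identity
types; linear 1.3e−4 intercept, 4.7e−4 on 0/1_0/0 with sigma = 2e−3,
echoing the magnitudes such studies report) and are the basis of the
parameter-recovery tests.

## Numerical and degenerate-input choices

* Percentages are rounded to 2 decimals only at report boundaries; full
  precision is kept internally and in feature tables (>= 6 significant
  digits on disk).
* Logistic IRLS runs to epsilon 1e−12 so fits are reproducible against an
  independent implementation to at least 6 significant digits.
* A gene with zero coding-strand adenines reports density 0 with a
  `zero_adenine` flag and a warning (an error only if it also carries
  sites, which contradicts the strand rule).
* A-mutated ratios with an empty denominator (no modified, or no
  unmodified, adenines) are reported as missing, never as 0.
* Zero-variance inputs: density correlation returns NA with a warning;
  a constant linear response returns a flagged degenerate fit (intercept =
  the constant, slopes 0); identical constant t-test groups return p = 1.
* Parsers are total: malformed or out-of-scope records (indels,
  multi-allelic sites, unknown modification types, strand-less genes,
  span records) are rejected with warnings and per-category counts, never
  crashes. Multi-allelic sites are excluded rather than decomposed because
  the genotype classes are defined for biallelic sites only.
* Phased genotypes are normalised to unphased (the transmit classes are
  unphased); `1/0` becomes `0/1`.

## Problem sizes used by the tests

The oracle-equivalence properties run on 20 seeded fixtures of ~25 genes
over ~60 kb, checked base by base against brute-force scans. The
statistical properties use the study scale the models are specified for:
2,000-gene bundles for the end-to-end pipeline and effect-direction checks,
and 5,000-row feature tables across 20 replicates for regression recovery
(each planted coefficient covered by its 95% Wald interval and significant
at p < 0.01 in at least 18 of 20). Imprinting contrasts are calibrated
under a null generator (800 genes, 50 seeds) to a ~5% false-positive rate
at alpha = 0.05.

## Known limitations

* The pipeline consumes *calls* (modification GFFs, VCFs); it does not
  validate upstream alignment or calling quality beyond its declared
  filters.
* RNA 0/0 inference from a coverage track is a stated convention, not a
  re-genotyping; allele-specific coverage is not examined.
* Overlapping same-strand genes double-count shared sites/variants by
  design (logged); densities over a set of overlapping genes are not
  additive.
* The imprinting contrasts inherit the small-cell fragility of the design:
  at a realistic imprinted fraction (~0.35%) the imprinted cells hold only
  a handful of genes and those comparisons are reported as not computable
  when a cell has fewer than two members.
* Student's t on count data is the field's convention, not an exact test;
  for heavily skewed counts a rank-based alternative applied to the
  exported feature table may be preferable.
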