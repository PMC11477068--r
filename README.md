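# m6atrans

DNA N6-methyladenosine (6mA) is a strand-specific base modification called at
single-nucleotide resolution from SMRT sequencing kinetics. `m6atrans` is an R
package for asking how 6mA methylation relates to genetic variation: do
methylated genes mutate less, and does methylation bias how genotypes are
transmitted from DNA into RNA during transcription? It is aimed at
epigenomics/regulatory-genomics analysts who have per-site 6mA calls
(ipdSummary-style modifications GFF), a gene annotation (GFF3/GTF), and paired
DNA/RNA variant calls (VCF) for one or more samples.

## What it computes

**Methylome.** Sites are depth-filtered (a site is removed iff its coverage is
*less than* the autosome or sex-chromosome cutoff). A gene is
*strand-methylated* when at least one 6mA site falls in its body on its coding
strand; its 6mA density is `6mA/A`, the site count over the count of
coding-strand adenines. Genome and per-chromosome densities use both strands'
adenines as the denominator. Cross-sample summaries cover shared methylated
genes, per-chromosome density correlations (Pearson), consistent (shared)
sites, and a strand-normalised flanking-sequence FASTA for motif discovery.

**Variation.** DNA SNVs are screened against dbSNP positions, RNA SNVs by
depth > 30X. The per-gene variation ratio is the variant count over the gene
length; variants are partitioned A/T vs C/G by REF base, overlapped with 6mA
sites ("methylated variations"), assigned to exon/intron/UTR under the
precedence UTR > exon > intron, and compared between methylated and
unmethylated genes by Student's t-test.

**Transmission.** At each DNA variant site the RNA genotype is taken from the
RNA VCF, or inferred as 0/0 where RNA coverage is adequate, giving one of six
transmit types

```
0/1_0/0  0/1_0/1  0/1_1/1  1/1_0/0  1/1_0/1  1/1_1/1
```

(0 = reference allele, 1 = alternate). Events detected identically in two
samples form the high-confidence consistent set.

**Association.** With per-gene transmit-type counts `x_1..x_6` as covariates,
the package fits

- logistic: `logit P(methylated_i) = b0 + sum_n b_n x_in` over all genes, and
- linear: `y_i = a0 + sum_n a_n x_in + e_i` over methylated genes, where
  `y_i` is the gene's 6mA density,

with Wald tests per term and automatic dropping of empty, collinear or
one-class-support covariates. Imprinting-gene contrasts t-test DNA variant
counts across the four cells of methylated/unmethylated x
imprinted/non-imprinted.

**Synthetic studies.** `sim_params()` / `simulate_study()` generate a complete
seeded study — genome, annotation, modification calls, DNA/RNA VCFs, RNA
coverage, dbSNP and imprinting lists — with known ground truth (methylated
genes mutate at 0.10% per base vs 0.21% for unmethylated ones; RNA genotypes
drawn from methylation-dependent transmission matrices), so the whole pipeline
is testable end to end.

## Worked example

```r
library(m6atrans)

dir <- file.path(tempdir(), "study")
sim <- simulate_study(sim_params(seed = 1), dir, n_samples = 2)

cfg <- function(s) run_config(
  annotation    = file.path(dir, "annotation.gff3"),
  genome        = file.path(dir, "genome.fa"),
  modifications = file.path(dir, s, "modifications.gff"),
  dna_vcf       = file.path(dir, s, "dna.vcf"),
  rna_vcf       = file.path(dir, s, "rna.vcf"),
  rna_coverage  = file.path(dir, s, "rna_coverage.tsv"),
  dbsnp         = file.path(dir, "dbsnp.tsv"),
  out_dir       = file.path(dir, "out"))

pair <- run_two_sample(cfg("sample_a"), cfg("sample_b"))

pair$sample_a$methyl_summary$pct_on_gene
#> [1] 68.75
pair$sample_a$ratio_comparison
#> unmethylated (n=1037, mean=0.001795) vs methylated (n=963, mean=0.0008921): t=27.460, df=1998.0, p=4.1e-141
nrow(pair$consistent_transmissions)
#> [1] 3536
pair$fit_logistic
#> logistic fit, 2000 genes
#>          term estimate std_error statistic   p_value
#> 1 (Intercept) -0.12997   0.07266   -1.7889 7.363e-02
#> 2     0/1_0/0 -4.27323   0.71414   -5.9837 2.181e-09
#> 3     0/1_0/1  0.22860   0.04449    5.1378 2.779e-07
#> 4     0/1_1/1 -3.87844   1.01313   -3.8282 1.291e-04
#> 5     1/1_0/0 -3.66631   1.01531   -3.6110 3.050e-04
#> 6     1/1_0/1 -2.64312   0.74218   -3.5613 3.690e-04
#> 7     1/1_1/1 -0.02409   0.07133   -0.3377 7.356e-01
```

Reading the output: 68.75% of the depth-filtered 6mA sites lie on a gene's
coding strand; unmethylated genes carry about twice the per-base variant rate
of methylated genes (0.180% vs 0.089%, t-test p ~ 1e-141), reproducing the
planted rates; 3,536 transmission events are detected identically in both
samples; and in the logistic model identity transmission of heterozygotes
(0/1_0/1) is a significant positive predictor of methylation while the
dispersal types (0/1_0/0, 0/1_1/1, 1/1_0/0, 1/1_0/1) predict unmethylated
genes — the planted selective effect of methylation on transmission.

The `analysis/` directory holds the same workflow as numbered narrative
drivers (`01_simulate.R` ... `06_imprinting.R`); each writes its tables under
`results/analysis/`.

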