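#!/usr/bin/env Rscript
# Generate the synthetic two-sample study: one shared genome and gene
# annotation, and per-sample 6mA calls, DNA/RNA variants and RNA coverage
# with known ground truth. The study conditions encode a methylated-gene
# variant rate of 0.10% per base versus 0.21% for unmethylated genes, and
# methylation-dependent transmission matrices that favour identity
# transmission (0/1->0/1, 1/1->1/1) in methylated genes.

source("analysis/00_common.R")

d <- data_dir()
truth <- utils::read.delim(file.path(d, "truth_genes.tsv"))

message(sprintf("study: %d genes, %d latently methylated (%.0f%%)",
                nrow(truth), sum(truth$meth_latent),
                100 * mean(truth$meth_latent)))
for (s in c("sample_a", "sample_b")) {
  sites <- read_modifications(file.path(d, s, "modifications.gff"))
  vcf <- read_vcf(file.path(d, s, "dna.vcf"), "DNA")
  message(sprintf("%s: %d 6mA calls, %d DNA SNVs, %d methylated genes",
                  s, nrow(sites), nrow(vcf),
                  sum(truth[[paste0("methylated_", s)]])))
}
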