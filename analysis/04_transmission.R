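#!/usr/bin/env Rscript
# DNA-to-RNA genotype transmission: pair each sample's DNA variants with
# RNA genotypes (called, or inferred 0/0 where RNA coverage is adequate),
# classify the six transmit types, and intersect the two samples into the
# high-confidence consistent set.

source("analysis/00_common.R")

d <- data_dir()
dbsnp <- read_dbsnp(file.path(d, "dbsnp.tsv"))

recs <- list(); tallies <- list()
for (s in c("sample_a", "sample_b")) {
  dna <- filter_dna_variants(read_vcf(file.path(d, s, "dna.vcf"), "DNA"),
                             dbsnp)
  rna <- filter_rna_variants(read_vcf(file.path(d, s, "rna.vcf"), "RNA"))
  cov <- read_coverage_track(file.path(d, s, "rna_coverage.tsv"))
  jr <- join_dna_rna(dna, rna, cov)
  recs[[s]] <- jr$records
  tallies[[s]] <- data.frame(
    sample = s, n_dna = jr$log$n_dna, n_classified = jr$log$n_classified,
    n_allele_discordant = jr$log$n_allele_discordant,
    n_insufficient_rna = jr$log$n_insufficient_rna,
    n_rna_only = jr$log$n_rna_only,
    t(as.matrix(table(factor(jr$records$transmit_type,
                             levels = transmit_types())))))
  message(sprintf("%s: %d/%d DNA variants classified into transmit types",
                  s, jr$log$n_classified, jr$log$n_dna))
}
out_tsv(do.call(rbind, tallies), "transmission_tallies.tsv")

cons <- consistent_transmissions(recs$sample_a, recs$sample_b)
out_tsv(cons, "consistent_transmissions.tsv")
message(sprintf("%d consistent transmission events shared by both samples",
                nrow(cons)))
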