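#!/usr/bin/env Rscript
# DNA variation versus methylation, per sample: dbSNP-screened SNVs,
# per-gene variation ratios compared between methylated and unmethylated
# genes, methylated-variation overlap, A-mutated ratios at modified vs
# unmodified adenines, and the exon/intron/UTR breakdown.

source("analysis/00_common.R")

d <- data_dir()
p <- study_params()
genome <- Biostrings::readDNAStringSet(file.path(d, "genome.fa"))
names(genome) <- sub("\\s.*", "", names(genome))
gm <- read_annotation(file.path(d, "annotation.gff3"))
dbsnp <- read_dbsnp(file.path(d, "dbsnp.tsv"))
regions <- gene_regions(gm)

rows <- list(); breakdown <- list()
for (s in c("sample_a", "sample_b")) {
  sites <- filter_by_depth(
    read_modifications(file.path(d, s, "modifications.gff")),
    p$thresholds, p$sex_chroms)
  dna <- filter_dna_variants(read_vcf(file.path(d, s, "dna.vcf"), "DNA"),
                             dbsnp)
  gme <- gene_methylation(gm, sites, genome)
  gv <- gene_variation(gm, dna, sites = sites)
  cmp <- group_ratio_comparison(gv$variation_ratio[!gme$methylated],
                                gv$variation_ratio[gme$methylated],
                                names = c("unmethylated", "methylated"))
  mv <- methylated_variation(dna, sites)
  amr <- a_mutated_ratio(gm, sites, dna, genome)
  rows[[s]] <- data.frame(
    sample = s, n_variants = nrow(dna),
    mean_ratio_unmethylated_pct = 100 * cmp$means[1],
    mean_ratio_methylated_pct = 100 * cmp$means[2],
    t_statistic = cmp$statistic, p_value = cmp$p_value,
    n_methylated_variations = sum(mv$methylated),
    mean_A_mutated_ratio_modified = mean(amr$ratio_modified, na.rm = TRUE),
    mean_A_mutated_ratio_unmodified = mean(amr$ratio_unmodified, na.rm = TRUE))
  breakdown[[s]] <- rbind(
    cbind(sample = s, what = "6mA_sites",
          region_distribution(sites, gm, regions)),
    cbind(sample = s, what = "DNA_variants",
          region_distribution(dna, gm, regions)))
  message(sprintf(paste0("%s: ratio %.3f%% (unmethylated) vs %.3f%% ",
                         "(methylated), t = %.1f, p = %.3g"),
                  s, 100 * cmp$means[1], 100 * cmp$means[2],
                  cmp$statistic, cmp$p_value))
}
out_tsv(do.call(rbind, rows), "variation_vs_methylation.tsv")
out_tsv(do.call(rbind, breakdown), "region_breakdown.tsv")
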