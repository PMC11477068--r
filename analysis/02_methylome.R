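#!/usr/bin/env Rscript
# Methylome summaries per sample: depth-filtered 6mA counts, the share of
# methyloci on genes, strand-methylated gene counts, per-chromosome 6mA
# density, cross-sample density correlation, shared methylated genes, and
# the strand-normalised motif-context FASTA for motif discovery.

source("analysis/00_common.R")

d <- data_dir()
p <- study_params()
genome <- Biostrings::readDNAStringSet(file.path(d, "genome.fa"))
names(genome) <- sub("\\s.*", "", names(genome))
gm <- read_annotation(file.path(d, "annotation.gff3"))

summaries <- list(); dens <- list(); meth_genes <- list()
for (s in c("sample_a", "sample_b")) {
  sites <- filter_by_depth(
    read_modifications(file.path(d, s, "modifications.gff")),
    p$thresholds, p$sex_chroms)
  sm <- methyloci_on_gene_summary(sites, gm)
  summaries[[s]] <- data.frame(
    sample = s, n_methyloci = sm$n_total, n_on_genes = sm$n_on_gene,
    pct_on_genes = sm$pct_on_gene,
    strand_methylated_genes = sm$n_methylated_genes,
    genome_density = genome_density(sites, genome))
  dens[[s]] <- per_chromosome_density(sites, genome)
  gme <- gene_methylation(gm, sites, genome)
  meth_genes[[s]] <- gme$gene_id[gme$methylated]
  if (s == "sample_a") {
    ctx <- export_motif_contexts(sites, genome, flank = 10,
                                 path = file.path(OUT_DIR, "motif_contexts.fa"))
    message(length(ctx), " motif contexts exported for sample_a")
  }
}
out_tsv(do.call(rbind, summaries), "methylome_summary.tsv")
out_tsv(data.frame(chrom = names(dens$sample_a),
                   sample_a = dens$sample_a, sample_b = dens$sample_b),
        "per_chromosome_density.tsv")

r <- density_correlation(dens$sample_a, dens$sample_b)
sh <- shared_gene_summary(meth_genes)
out_tsv(data.frame(density_correlation = r,
                   n_shared_methylated_genes = sh$pairwise$n,
                   pct_of_sample_a = sh$pairwise$pct_of_a,
                   pct_of_sample_b = sh$pairwise$pct_of_b),
        "cross_sample_consistency.tsv")
message(sprintf("per-chromosome density correlation r = %.4f; %d shared methylated genes (%.2f%% of sample_a)",
                r, sh$pairwise$n, sh$pairwise$pct_of_a))
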