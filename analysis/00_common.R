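# Shared paths and configuration for the analysis scripts. Each numbered
# script can be run on its own from the repository root; the simulated
# study is (re)generated on demand by data_dir().

suppressMessages(library(m6atrans))

ANALYSIS_SEED <- 1L
DATA_DIR <- "scratch/analysis-data"
OUT_DIR <- "results/analysis"
dir.create(OUT_DIR, recursive = TRUE, showWarnings = FALSE)

study_params <- function() sim_params(seed = ANALYSIS_SEED, n_genes = 2000)

data_dir <- function() {
  if (!file.exists(file.path(DATA_DIR, "annotation.gff3"))) {
    message("simulating the two-sample study under ", DATA_DIR)
    simulate_study(study_params(), DATA_DIR, n_samples = 2)
  }
  DATA_DIR
}

sample_config <- function(s) {
  d <- data_dir()
  p <- study_params()
  run_config(
    annotation = file.path(d, "annotation.gff3"),
    genome = file.path(d, "genome.fa"),
    modifications = file.path(d, s, "modifications.gff"),
    dna_vcf = file.path(d, s, "dna.vcf"),
    rna_vcf = file.path(d, s, "rna.vcf"),
    rna_coverage = file.path(d, s, "rna_coverage.tsv"),
    dbsnp = file.path(d, "dbsnp.tsv"),
    imprinted = file.path(d, "imprinted_genes.txt"),
    thresholds = p$thresholds, sex_chroms = p$sex_chroms,
    out_dir = file.path(OUT_DIR, s))
}

out_tsv <- function(d, name) {
  dir.create(OUT_DIR, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(d, file.path(OUT_DIR, name), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  message("wrote ", file.path(OUT_DIR, name))
}
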