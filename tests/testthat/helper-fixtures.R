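# Fixture builders shared across test files. Everything is generated in
# code; the default study bundle is created once per session and reused.

tiny_params <- function(seed, ...) {
  args <- list(seed = seed, n_genes = 25,
               gene_length_meanlog = log(900), gene_length_sdlog = 0.3,
               min_gene_length = 300, intergenic_mean = 400,
               chroms = c("chr1", "chr2", "chrX"), sex_chroms = "chrX",
               dna_ratio_meth = 0.004, dna_ratio_unmeth = 0.008,
               dna_ratio_intergenic = 0.004, intergenic_site_density = 0.004,
               density_shape1 = 2, density_shape2 = 60)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_params, args)
}

# hand-built two-gene annotation on one small contig
toy_gm <- function() {
  gene_models(
    genes = data.frame(gene_id = c("gplus", "gminus"),
                       chrom = c("chr1", "chr1"), strand = c("+", "-"),
                       start = c(11L, 201L), end = c(100L, 300L)),
    features = data.frame(
      gene_id = c("gplus", "gplus", "gplus", "gminus", "gminus"),
      type = c("UTR5", "exon", "exon", "exon", "UTR3"),
      start = c(11L, 11L, 71L, 201L, 201L),
      end = c(20L, 40L, 100L, 240L, 210L)))
}

toy_genome <- function(seed = 7, len = 400) {
  set.seed(seed)
  s <- paste(sample(c("A", "C", "G", "T"), len, TRUE, c(.3, .2, .2, .3)),
             collapse = "")
  g <- Biostrings::DNAStringSet(s)
  names(g) <- "chr1"
  g
}

# one shared default-conditions bundle (sample pair) per test session,
# at the study scale the association models are specified for
.bundle_env <- new.env(parent = emptyenv())
shared_bundle <- function() {
  if (is.null(.bundle_env$bundle)) {
    dir <- file.path(tempdir(), "m6atrans-bundle")
    p <- sim_params(seed = 101, n_genes = 2000)
    .bundle_env$bundle <- list(
      dir = dir, params = p,
      sim = simulate_study(p, dir, n_samples = 2))
  }
  .bundle_env$bundle
}

# memoised single-sample and pair analyses of the shared bundle
shared_single <- function() {
  if (is.null(.bundle_env$single)) {
    b <- shared_bundle()
    .bundle_env$single <- suppressMessages(suppressWarnings(
      run_single_sample(bundle_config(b, "sample_a"))))
  }
  .bundle_env$single
}

shared_pair <- function() {
  if (is.null(.bundle_env$pair)) {
    b <- shared_bundle()
    .bundle_env$pair <- suppressMessages(suppressWarnings(
      run_two_sample(bundle_config(b, "sample_a"),
                     bundle_config(b, "sample_b"))))
  }
  .bundle_env$pair
}

bundle_config <- function(b, sample, out_dir = file.path(b$dir, "out", sample)) {
  run_config(
    annotation = file.path(b$dir, "annotation.gff3"),
    genome = file.path(b$dir, "genome.fa"),
    modifications = file.path(b$dir, sample, "modifications.gff"),
    dna_vcf = file.path(b$dir, sample, "dna.vcf"),
    rna_vcf = file.path(b$dir, sample, "rna.vcf"),
    rna_coverage = file.path(b$dir, sample, "rna_coverage.tsv"),
    dbsnp = file.path(b$dir, "dbsnp.tsv"),
    imprinted = file.path(b$dir, "imprinted_genes.txt"),
    thresholds = b$params$thresholds, sex_chroms = b$params$sex_chroms,
    out_dir = out_dir)
}

write_lines_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

vcf_text <- function(records, sample = "S1") {
  c("##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample, sep = "\t"),
    records)
}

vcf_rec <- function(chrom, pos, ref, alt, gt, dp = 40) {
  paste(chrom, pos, ".", ref, alt, "50", "PASS", ".", "GT:DP",
        paste0(gt, ":", dp), sep = "\t")
}
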