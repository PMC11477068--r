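#' Configuration for a single-sample run
#'
#' Bundles the input paths and tuning parameters of one sample's analysis.
#' All referenced paths must exist at construction time.
#'
#' @param annotation GFF3/GTF gene annotation.
#' @param genome FASTA genome.
#' @param modifications Modifications GFF/TSV of 6mA calls.
#' @param dna_vcf Single-sample DNA VCF.
#' @param rna_vcf,rna_coverage Optional RNA VCF and coverage track.
#' @param dbsnp Optional dbSNP position list.
#' @param imprinted Optional imprinted-gene id list.
#' @param thresholds [depth_thresholds] for 6mA site filtering.
#' @param sex_chroms Sex-chromosome names.
#' @param min_rna_depth RNA depth rule: variant filter (strictly greater)
#'   and 0/0 inference (at least).
#' @param out_dir Where reports are written.
#' @return List of class `run_config`.
#' @export
run_config <- function(annotation, genome, modifications, dna_vcf,
                       rna_vcf = NULL, rna_coverage = NULL, dbsnp = NULL,
                       imprinted = NULL,
                       thresholds = depth_thresholds(30, 15),
                       sex_chroms = c("chrX", "chrY"),
                       min_rna_depth = 30, out_dir = ".") {
  paths <- c(annotation = annotation, genome = genome,
             modifications = modifications, dna_vcf = dna_vcf,
             rna_vcf = rna_vcf, rna_coverage = rna_coverage,
             dbsnp = dbsnp, imprinted = imprinted)
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("missing input file(s): ", paste(missing, collapse = ", "))
  structure(list(annotation = annotation, genome = genome,
                 modifications = modifications, dna_vcf = dna_vcf,
                 rna_vcf = rna_vcf, rna_coverage = rna_coverage,
                 dbsnp = dbsnp, imprinted = imprinted,
                 thresholds = thresholds, sex_chroms = sex_chroms,
                 min_rna_depth = min_rna_depth, out_dir = out_dir),
            class = "run_config")
}

#' Run the single-sample analysis
#'
#' Reads every input, depth-filters the 6mA sites, and computes the
#' methylation summary (total/on-gene methyloci, percentage, methylated
#' genes), genome and per-chromosome densities, the per-gene feature
#' table, the methylated-vs-unmethylated variation-ratio comparison, the
#' methylated-variation overlap, and the exon/intron/UTR breakdown of
#' sites and variants. Every reported number is recomputable from the
#' emitted TSVs.
#'
#' @param config A [run_config].
#' @param write Write TSV reports under `config$out_dir` (default TRUE).
#' @return List of class `sample_report`; see Details in the vignette.
#' @export
run_single_sample <- function(config, write = TRUE) {
  stopifnot(inherits(config, "run_config"))
  gm <- read_annotation(config$annotation)
  genome <- Biostrings::readDNAStringSet(config$genome)
  names(genome) <- sub("\\s.*", "", names(genome))
  sites_raw <- read_modifications(config$modifications)
  sites <- filter_by_depth(sites_raw, config$thresholds, config$sex_chroms)

  dna <- read_vcf(config$dna_vcf, source = "DNA")
  dbsnp <- if (!is.null(config$dbsnp)) read_dbsnp(config$dbsnp) else NULL
  dna <- filter_dna_variants(dna, dbsnp)

  summary_tbl <- if (nrow(sites)) methyloci_on_gene_summary(sites, gm) else
    list(n_total = 0L, n_on_gene = 0L, pct_on_gene = NA_real_,
         n_methylated_genes = 0L)
  gmeth <- gene_methylation(gm, sites, genome)
  dens <- per_chromosome_density(sites, genome)
  gvar <- gene_variation(gm, dna, sites = sites)

  ratio_cmp <- {
    um <- gvar$variation_ratio[!gmeth$methylated]
    me <- gvar$variation_ratio[gmeth$methylated]
    if (length(um) >= 2 && length(me) >= 2)
      group_ratio_comparison(um, me, names = c("unmethylated", "methylated"))
    else NULL
  }
  mvar <- methylated_variation(dna, sites)
  regions <- gene_regions(gm)
  region_sites <- region_distribution(sites, gm, regions)
  region_vars <- region_distribution(dna, gm, regions)

  rna <- NULL; transmit <- NULL; tcounts <- NULL
  if (!is.null(config$rna_vcf)) {
    rna <- filter_rna_variants(read_vcf(config$rna_vcf, source = "RNA"),
                               config$min_rna_depth)
    cov <- if (!is.null(config$rna_coverage))
      read_coverage_track(config$rna_coverage) else NULL
    transmit <- join_dna_rna(dna, rna, cov, config$min_rna_depth)
    tcounts <- gene_transmit_counts(transmit$records, gm)
  } else {
    tcounts <- gene_transmit_counts(
      data.frame(chrom = character(), pos = integer(),
                 transmit_type = character()), gm)
  }
  imprinted <- if (!is.null(config$imprinted))
    read_gene_list(config$imprinted) else character()
  rows <- feature_rows(gmeth, tcounts, gvar, imprinted)

  report <- structure(
    list(methyl_summary = summary_tbl,
         genome_density = if (nrow(sites)) genome_density(sites, genome) else 0,
         per_chrom_density = dens, gene_methylation = gmeth,
         gene_variation = gvar, ratio_comparison = ratio_cmp,
         n_methylated_variation = sum(mvar$methylated),
         region_sites = region_sites, region_variants = region_vars,
         feature_rows = rows, sites = sites, dna_variants = dna,
         rna_variants = rna, transmission = transmit,
         log = list(sites_in = nrow(sites_raw), sites_kept = nrow(sites),
                    dna_in = attr(dna, "log"))),
    class = "sample_report")

  if (write) {
    od <- config$out_dir
    dir.create(od, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(
      data.frame(n_methyloci = summary_tbl$n_total,
                 n_methyloci_on_genes = summary_tbl$n_on_gene,
                 pct_methyloci_on_genes = summary_tbl$pct_on_gene,
                 n_methylated_genes = summary_tbl$n_methylated_genes),
      file.path(od, "methylation_summary.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(chrom = names(dens), density = dens),
      file.path(od, "per_chromosome_density.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    write_feature_table(rows, file.path(od, "gene_features.tsv"))
    utils::write.table(rbind(cbind(what = "6mA_sites", region_sites),
                             cbind(what = "DNA_variants", region_vars)),
                       file.path(od, "region_breakdown.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    sites_to_bed(sites, file.path(od, "filtered_sites.bed"))
  }
  report
}

#' Run the two-sample consistency and association analysis
#'
#' Runs both samples, intersects their 6mA sites and transmission events
#' into high-confidence sets, recomputes per-gene 6mA density on the
#' consistent sites and per-gene transmit-type counts on the consistent
#' transmissions, and fits the two association models: logistic
#' (methylated vs transmit counts, all genes) and linear (density vs
#' transmit counts, methylated genes). Imprinting contrasts are added
#' when a gene list is supplied.
#'
#' @param config_a,config_b [run_config]s sharing one annotation/genome.
#' @param write Write TSV reports under `config_a$out_dir`.
#' @return List of class `pair_report`: per-sample reports, consistent
#'   sites/transmissions, pooled `feature_rows`, `fit_logistic`,
#'   `fit_linear`, `imprinting`.
#' @export
run_two_sample <- function(config_a, config_b, write = TRUE) {
  rep_a <- run_single_sample(config_a, write = FALSE)
  rep_b <- run_single_sample(config_b, write = FALSE)
  chr_a <- unique(rep_a$sites$chrom); chr_b <- unique(rep_b$sites$chrom)
  off <- union(setdiff(chr_a, chr_b), setdiff(chr_b, chr_a))
  if (length(off) && (!length(chr_a) || !length(chr_b)))
    off <- character()                       # one sample empty: not a clash
  if (length(off))
    stop("chromosome namespaces differ between samples: ",
         paste(off, collapse = ", "))

  gm <- read_annotation(config_a$annotation)
  genome <- Biostrings::readDNAStringSet(config_a$genome)
  names(genome) <- sub("\\s.*", "", names(genome))

  cons_sites <- consistent_sites(rep_a$sites, rep_b$sites)
  if (is.null(rep_a$transmission) || is.null(rep_b$transmission))
    stop("both samples need RNA inputs for the transmission analysis")
  cons_trans <- consistent_transmissions(rep_a$transmission$records,
                                         rep_b$transmission$records)
  if (!nrow(cons_trans))
    stop("no consistent transmissions between the samples; ",
         "association models not identifiable")

  gmeth <- gene_methylation(gm, cons_sites, genome)
  tcounts <- gene_transmit_counts(cons_trans, gm)
  gvar <- gene_variation(gm, rep_a$dna_variants, sites = cons_sites)
  imprinted <- if (!is.null(config_a$imprinted))
    read_gene_list(config_a$imprinted) else character()
  rows <- feature_rows(gmeth, tcounts, gvar, imprinted)

  logit_fit <- fit_logistic(rows)
  lin_fit <- fit_linear(rows[rows$methylated, , drop = FALSE])
  imp <- if (length(imprinted)) imprinting_contrasts(rows) else NULL

  report <- structure(
    list(sample_a = rep_a, sample_b = rep_b,
         consistent_sites = cons_sites, consistent_transmissions = cons_trans,
         feature_rows = rows, fit_logistic = logit_fit, fit_linear = lin_fit,
         imprinting = imp,
         density_correlation = density_correlation(rep_a$per_chrom_density,
                                                   rep_b$per_chrom_density)),
    class = "pair_report")

  if (write) {
    od <- config_a$out_dir
    dir.create(od, recursive = TRUE, showWarnings = FALSE)
    write_feature_table(rows, file.path(od, "pair_gene_features.tsv"))
    utils::write.table(logit_fit$terms,
                       file.path(od, "regression_logistic.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(lin_fit$terms, file.path(od, "regression_linear.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(imp))
      utils::write.table(imp, file.path(od, "imprinting_contrasts.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(cons_trans, file.path(od, "consistent_transmissions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  report
}
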