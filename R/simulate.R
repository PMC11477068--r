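#' Parameters for the synthetic study generator
#'
#' Defines the simulated study conditions: a small multi-chromosome genome
#' with stranded multi-exon genes, per-gene 6mA methylation with planted
#' AGGYR-like motif contexts, DNA variants at a per-base rate that depends
#' on methylation status (defaults 0.21% for unmethylated vs 0.10% for
#' methylated genes), RNA genotypes drawn from a methylation-dependent
#' transmission matrix over the six transmit types, per-site coverages
#' straddling the depth-filter thresholds, and an imprinted-gene subset.
#'
#' Defaults for a sample pair share the genome, annotation, latent gene
#' methylation and a core of sites/variants, so cross-sample consistency
#' operations have non-trivial intersections.
#'
#' @param seed Integer seed; the whole bundle is deterministic in it.
#' @param n_genes Number of genes.
#' @param chroms Named integer-free chromosome layout: character vector of
#'   names, sex chromosomes listed in `sex_chroms`.
#' @param sex_chroms Which `chroms` are sex chromosomes.
#' @param gene_length_meanlog,gene_length_sdlog,min_gene_length Lognormal
#'   gene-length model (bases).
#' @param intergenic_mean Mean intergenic gap (bases).
#' @param p_minus_strand Fraction of genes on the minus strand.
#' @param max_exons Maximum exons per gene.
#' @param exon_length_mean Mean exon length (bases); introns absorb the
#'   rest of the gene body, making genes intron-dominant as in real
#'   genomes.
#' @param p_gene_methylated Probability a gene is (latently) methylated.
#' @param density_shape1,density_shape2 Beta model for the per-gene target
#'   6mA density (6mA/A) of methylated genes.
#' @param intergenic_site_density Per-adenine 6mA rate outside gene
#'   bodies (both strands), so a realistic share of methyloci is not on
#'   genes.
#' @param motif Context planted around a fraction of sites; IUPAC, must
#'   start with A (the methylated base).
#' @param p_motif Fraction of sites with a planted motif context.
#' @param coverage_mu,coverage_size Negative-binomial per-site coverage.
#' @param thresholds [depth_thresholds] the study will be filtered with
#'   (coverages are drawn to straddle them).
#' @param dna_ratio_meth,dna_ratio_unmeth Per-base DNA variant rates in
#'   methylated / unmethylated genes.
#' @param dna_ratio_intergenic Per-base DNA variant rate outside genes.
#' @param p_het P(genotype 0/1) for a DNA variant (else 1/1).
#' @param t_meth,t_unmeth 2x3 transmission matrices (rows `0/1`, `1/1`;
#'   columns `0/0`, `0/1`, `1/1`), each row summing to 1. Methylated genes
#'   favour identity transmission; unmethylated genes spread mass.
#' @param p_rna_covered Probability a genic DNA variant site has adequate
#'   RNA coverage (else it is RNA-unassessable).
#' @param rna_only_rate Expected RNA-only variants per gene.
#' @param p_dbsnp Probability a simulated DNA variant is in the dbSNP list.
#' @param p_imprinted Probability a gene is imprinted.
#' @param p_site_shared,p_var_shared For a sample pair: probability a
#'   master site / variant is present in each sample.
#' @return List of class `sim_params`.
#' @export
sim_params <- function(seed = 1,
                       n_genes = 2000,
                       chroms = c("chr1", "chr2", "chr3", "chrX"),
                       sex_chroms = "chrX",
                       gene_length_meanlog = log(3000),
                       gene_length_sdlog = 0.35,
                       min_gene_length = 400,
                       intergenic_mean = 1500,
                       p_minus_strand = 0.45,
                       max_exons = 5,
                       exon_length_mean = 120,
                       p_gene_methylated = 0.5,
                       density_shape1 = 2,
                       density_shape2 = 250,
                       intergenic_site_density = 0.002,
                       motif = "AGGYR",
                       p_motif = 0.3,
                       coverage_mu = 45,
                       coverage_size = 8,
                       thresholds = depth_thresholds(30, 15),
                       dna_ratio_meth = 0.0010,
                       dna_ratio_unmeth = 0.0021,
                       dna_ratio_intergenic = 0.0015,
                       p_het = 0.7,
                       t_meth = matrix(c(0.05, 0.90, 0.05,
                                         0.05, 0.05, 0.90),
                                       2, 3, byrow = TRUE,
                                       dimnames = list(c("0/1", "1/1"),
                                                       c("0/0", "0/1", "1/1"))),
                       t_unmeth = matrix(c(0.25, 0.60, 0.15,
                                           0.20, 0.15, 0.65),
                                         2, 3, byrow = TRUE,
                                         dimnames = list(c("0/1", "1/1"),
                                                         c("0/0", "0/1", "1/1"))),
                       p_rna_covered = 0.9,
                       rna_only_rate = 0.05,
                       p_dbsnp = 0.98,
                       p_imprinted = 204 / 58677,
                       p_site_shared = 0.85,
                       p_var_shared = 0.9) {
  p <- as.list(environment())
  probs <- c(p$p_gene_methylated, p$p_motif, p$p_het, p$p_rna_covered,
             p$p_dbsnp, p$p_imprinted, p$p_site_shared, p$p_var_shared,
             p$p_minus_strand)
  stopifnot(all(probs >= 0 & probs <= 1),
            all(abs(rowSums(p$t_meth) - 1) < 1e-9),
            all(abs(rowSums(p$t_unmeth) - 1) < 1e-9),
            p$dna_ratio_meth < 1, p$dna_ratio_unmeth < 1,
            p$dna_ratio_intergenic < 1,
            substr(p$motif, 1, 1) == "A",
            p$sex_chroms %in% p$chroms)
  structure(p, class = "sim_params")
}

# sample concrete bases for an IUPAC motif (first base fixed); internal
.motif_instance <- function(motif) {
  iupac <- list(A = "A", C = "C", G = "G", T = "T",
                R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                N = c("A", "C", "G", "T"))
  vapply(strsplit(motif, "")[[1]],
         function(ch) { v <- iupac[[ch]]; if (length(v) == 1) v else sample(v, 1) },
         character(1), USE.NAMES = FALSE)
}

.revcomp_chars <- function(x) rev(c(A = "T", C = "G", G = "C", T = "A")[x])

#' Simulate a synthetic methylation/variation study in memory
#'
#' Generates the complete ground truth for `n_samples` samples over one
#' shared genome and annotation: per-gene methylation, 6mA sites with
#' coverages, DNA/RNA variants, RNA coverage at variant sites, and the
#' true transmit type of every assessable variant. Deterministic in
#' `params$seed`.
#'
#' @param params A [sim_params] object.
#' @param n_samples 1 or 2.
#' @return List of class `sim_truth`: `genome` (DNAStringSet),
#'   `gene_models`, `imprinted`, `dbsnp`, `genes` (per-gene, per-sample
#'   truth), and `samples` — a named list where each sample holds `sites`,
#'   `dna_variants`, `rna_variants`, `rna_coverage` and `transmissions`
#'   (with `assessable` flags).
#' @export
simulate_truth <- function(params = sim_params(), n_samples = 1) {
  stopifnot(inherits(params, "sim_params"), n_samples %in% 1:2)
  p <- params
  set.seed(p$seed)
  bases <- c("A", "C", "G", "T")
  sample_names <- c("sample_a", "sample_b")[seq_len(n_samples)]

  ## ---- genome + annotation -------------------------------------------------
  glen <- pmax(p$min_gene_length,
               round(stats::rlnorm(p$n_genes, p$gene_length_meanlog,
                                   p$gene_length_sdlog)))
  gchrom <- sort(sample(p$chroms, p$n_genes, replace = TRUE))
  gaps <- pmax(50L, stats::rpois(p$n_genes, p$intergenic_mean))
  strand <- ifelse(stats::runif(p$n_genes) < p$p_minus_strand, "-", "+")

  gstart <- integer(p$n_genes); gend <- integer(p$n_genes)
  chrom_len <- integer(length(p$chroms)); names(chrom_len) <- p$chroms
  for (chr in p$chroms) {
    idx <- which(gchrom == chr)
    cursor <- 1L
    for (i in idx) {
      gstart[i] <- cursor + gaps[i]
      gend[i] <- gstart[i] + glen[i] - 1L
      cursor <- gend[i]
    }
    chrom_len[chr] <- cursor + 200L
  }
  seqs <- lapply(chrom_len, function(L)
    sample(bases, L, replace = TRUE, prob = c(0.3, 0.2, 0.2, 0.3)))

  gene_ids <- sprintf("g%04d", seq_len(p$n_genes))
  genes_df <- data.frame(gene_id = gene_ids, chrom = gchrom, strand = strand,
                         start = gstart, end = gend)

  feats <- vector("list", p$n_genes)
  for (i in seq_len(p$n_genes)) {
    L <- glen[i]
    # short exons separated by long introns; terminal exons at the gene ends
    n_ex <- if (L < 1000L) 1L else sample(2:p$max_exons, 1)
    ex_len <- pmax(40L, round(stats::rexp(n_ex, 1 / p$exon_length_mean)))
    if (sum(ex_len) + 50L * (n_ex - 1L) > L)
      ex_len <- pmax(40L, floor(ex_len * (L - 50L * (n_ex - 1L)) /
                                  sum(ex_len)))
    if (n_ex == 1L) {
      ex_start <- gstart[i]; ex_end <- gend[i]
    } else {
      gap_total <- L - sum(ex_len)
      w <- stats::rexp(n_ex - 1L) + 0.1
      gaps_i <- pmax(50L, floor(gap_total * w / sum(w)))
      while (sum(gaps_i) > gap_total)         # rounding guard
        gaps_i[which.max(gaps_i)] <- gaps_i[which.max(gaps_i)] - 1L
      ex_start <- gstart[i] + cumsum(c(0L, ex_len[-n_ex] + gaps_i))
      ex_end <- ex_start + ex_len - 1L
      ex_end[n_ex] <- gend[i]                 # last exon reaches gene end
      ex_start[n_ex] <- max(ex_start[n_ex], ex_end[n_ex - 1L] + 2L)
    }
    f <- data.frame(gene_id = gene_ids[i], type = "exon",
                    start = ex_start, end = ex_end)
    # UTRs at the ends of the terminal exons; 5' end depends on strand
    u1_len <- max(10L, round((ex_end[1] - ex_start[1] + 1L) * 0.15))
    u2_len <- max(10L, round((ex_end[length(ex_end)] -
                                ex_start[length(ex_start)] + 1L) * 0.15))
    low_tag <- if (strand[i] == "+") "UTR5" else "UTR3"
    high_tag <- if (strand[i] == "+") "UTR3" else "UTR5"
    f <- rbind(f,
               data.frame(gene_id = gene_ids[i], type = low_tag,
                          start = ex_start[1],
                          end = min(ex_start[1] + u1_len - 1L, ex_end[1])),
               data.frame(gene_id = gene_ids[i], type = high_tag,
                          start = max(ex_end[length(ex_end)] - u2_len + 1L,
                                      ex_start[length(ex_start)]),
                          end = ex_end[length(ex_end)]))
    feats[[i]] <- f
  }
  gm <- gene_models(genes_df, do.call(rbind, feats))
  genes_df <- gm$genes                      # canonical order
  gi_of <- stats::setNames(seq_len(nrow(genes_df)), genes_df$gene_id)

  ## ---- latent methylation + master 6mA sites -------------------------------
  meth_latent <- stats::runif(nrow(genes_df)) < p$p_gene_methylated
  master_sites <- vector("list", nrow(genes_df))
  for (i in which(meth_latent)) {
    chr <- genes_df$chrom[i]
    body <- seqs[[chr]][genes_df$start[i]:genes_df$end[i]]
    cod_base <- if (genes_df$strand[i] == "+") "A" else "T"
    apos <- genes_df$start[i] - 1L + which(body == cod_base)
    if (!length(apos)) next
    d <- stats::rbeta(1, p$density_shape1, p$density_shape2)
    n_s <- max(1L, stats::rbinom(1, length(apos), d))
    pos <- sort(sample(apos, min(n_s, length(apos))))
    master_sites[[i]] <- data.frame(chrom = chr, pos = pos,
                                    strand = genes_df$strand[i],
                                    gene_id = genes_df$gene_id[i])
  }
  master_sites <- do.call(rbind, master_sites)
  if (is.null(master_sites))
    master_sites <- data.frame(chrom = character(), pos = integer(),
                               strand = character(), gene_id = character())

  ## ---- plant motif contexts ------------------------------------------------
  mlen <- nchar(p$motif)
  motif_planted <- rep(NA_character_, nrow(master_sites))
  if (nrow(master_sites)) {
    want <- stats::runif(nrow(master_sites)) < p$p_motif
    for (k in which(want)) {
      chr <- master_sites$chrom[k]; pos <- master_sites$pos[k]
      str <- master_sites$strand[k]
      win <- if (str == "+") pos:(pos + mlen - 1L) else (pos - mlen + 1L):pos
      if (min(win) < 1L || max(win) > chrom_len[chr]) next
      # do not overwrite another site's adenine
      others <- master_sites$chrom == chr & master_sites$pos %in% win &
        seq_len(nrow(master_sites)) != k
      if (any(others)) next
      inst <- .motif_instance(p$motif)
      seqs[[chr]][win] <- if (str == "+") inst else .revcomp_chars(inst)
      motif_planted[k] <- paste(inst, collapse = "")
    }
    # drop any site whose adenine got disturbed (opposite-strand planting)
    cod <- ifelse(master_sites$strand == "+", "A", "T")
    at <- mapply(function(chr, pos) seqs[[chr]][pos],
                 master_sites$chrom, master_sites$pos)
    ok <- at == cod
    master_sites <- master_sites[ok, , drop = FALSE]
    motif_planted <- motif_planted[ok]
  }
  master_sites$motif <- motif_planted

  ## ---- intergenic background 6mA (both strands, outside gene bodies) -------
  free_pos <- lapply(p$chroms, function(chr) {
    idx <- which(genes_df$chrom == chr)
    covered <- IRanges::reduce(IRanges::IRanges(genes_df$start[idx],
                                                genes_df$end[idx]))
    free <- IRanges::setdiff(IRanges::IRanges(1L, chrom_len[chr]), covered)
    unlist(lapply(seq_along(free), function(q)
      IRanges::start(free)[q]:IRanges::end(free)[q]))
  })
  names(free_pos) <- p$chroms
  bg <- lapply(p$chroms, function(chr) {
    base <- seqs[[chr]][free_pos[[chr]]]
    cand <- free_pos[[chr]][base %in% c("A", "T")]
    n_bg <- stats::rbinom(1, length(cand), p$intergenic_site_density)
    if (!n_bg) return(NULL)
    pos <- sort(sample(cand, n_bg))
    data.frame(chrom = chr, pos = pos,
               strand = ifelse(seqs[[chr]][pos] == "A", "+", "-"),
               gene_id = NA_character_, motif = NA_character_)
  })
  master_sites <- rbind(master_sites, do.call(rbind, bg))

  genome <- Biostrings::DNAStringSet(vapply(seqs, paste, "", collapse = ""))
  names(genome) <- p$chroms

  ## ---- master DNA variants -------------------------------------------------
  alt_of <- function(ref) {               # uniform over the 3 non-ref bases
    ri <- match(ref, bases)
    bases[((ri - 1L + sample.int(3, length(ref), replace = TRUE)) %% 4L) + 1L]
  }
  ratio <- ifelse(meth_latent, p$dna_ratio_meth, p$dna_ratio_unmeth)
  mv <- vector("list", nrow(genes_df) + length(p$chroms))
  for (i in seq_len(nrow(genes_df))) {
    L <- genes_df$end[i] - genes_df$start[i] + 1L
    n_v <- stats::rbinom(1, L, ratio[i])
    if (!n_v) next
    pos <- sort(sample(genes_df$start[i]:genes_df$end[i], n_v))
    chr <- genes_df$chrom[i]
    ref <- seqs[[chr]][pos]
    mv[[i]] <- data.frame(chrom = chr, pos = pos, ref = ref,
                          alt = alt_of(ref),
                          gene_id = genes_df$gene_id[i], genic = TRUE)
  }
  for (j in seq_along(p$chroms)) {       # intergenic background
    chr <- p$chroms[j]
    n_v <- stats::rbinom(1, length(free_pos[[chr]]), p$dna_ratio_intergenic)
    if (!n_v) next
    pos <- sort(sample(free_pos[[chr]], n_v))
    ref <- seqs[[chr]][pos]
    mv[[nrow(genes_df) + j]] <- data.frame(chrom = chr, pos = pos, ref = ref,
                                           alt = alt_of(ref),
                                           gene_id = NA_character_,
                                           genic = FALSE)
  }
  master_var <- do.call(rbind, mv)
  if (is.null(master_var))
    master_var <- data.frame(chrom = character(), pos = integer(),
                             ref = character(), alt = character(),
                             gene_id = character(), genic = logical())
  rownames(master_var) <- NULL
  master_var$genotype <- ifelse(stats::runif(nrow(master_var)) < p$p_het,
                                "0/1", "1/1")
  master_var$in_dbsnp <- stats::runif(nrow(master_var)) < p$p_dbsnp

  dbsnp <- master_var[master_var$in_dbsnp, c("chrom", "pos")]
  # decoy positions so the list is a superset of the observed variants
  n_decoy <- max(10L, nrow(dbsnp) %/% 5L)
  decoy_chr <- sample(p$chroms, n_decoy, replace = TRUE)
  decoy_pos <- vapply(decoy_chr, function(chr)
    sample.int(chrom_len[chr], 1), 1L)
  dbsnp <- unique(rbind(dbsnp, data.frame(chrom = decoy_chr, pos = decoy_pos)))
  dbsnp <- dbsnp[order(dbsnp$chrom, dbsnp$pos), ]
  rownames(dbsnp) <- NULL

  imprinted <- genes_df$gene_id[stats::runif(nrow(genes_df)) < p$p_imprinted]

  ## ---- per-sample draws ----------------------------------------------------
  sex_min <- p$thresholds$sex_min; auto_min <- p$thresholds$autosome_min
  samples <- list()
  for (s in sample_names) {
    keep_s <- if (n_samples == 1) rep(TRUE, nrow(master_sites)) else
      stats::runif(nrow(master_sites)) < p$p_site_shared
    sites <- master_sites[keep_s, , drop = FALSE]
    sites$coverage <- stats::rnbinom(nrow(sites), mu = p$coverage_mu,
                                     size = p$coverage_size)
    min_cov <- ifelse(sites$chrom %in% p$sex_chroms, sex_min, auto_min)
    sites$passes_depth <- sites$coverage >= min_cov

    keep_v <- if (n_samples == 1) rep(TRUE, nrow(master_var)) else
      stats::runif(nrow(master_var)) < p$p_var_shared
    dvar <- master_var[keep_v, , drop = FALSE]
    dvar$depth <- 10L + stats::rpois(nrow(dvar), 40)

    # per-gene methylation as observable after depth filtering
    meth_gene_ids <- unique(sites$gene_id[sites$passes_depth])
    gene_meth <- genes_df$gene_id %in% meth_gene_ids

    # transmissions for genic, dbSNP-consistent DNA variants
    tv <- dvar[dvar$genic & dvar$in_dbsnp, , drop = FALSE]
    cls_meth <- gene_meth[gi_of[tv$gene_id]]
    rna_gt <- character(nrow(tv))
    for (m in c(TRUE, FALSE)) for (gt in c("0/1", "1/1")) {
      idx <- which(cls_meth == m & tv$genotype == gt)
      if (!length(idx)) next
      tm <- if (m) p$t_meth else p$t_unmeth
      rna_gt[idx] <- sample(colnames(tm), length(idx), replace = TRUE,
                            prob = tm[gt, ])
    }
    tv$rna_gt <- rna_gt
    tv$assessable <- stats::runif(nrow(tv)) < p$p_rna_covered
    tv$transmit_type <- classify_transmit(tv$genotype, tv$rna_gt)

    # RNA variant records (non-reference, assessable), depth always > 30
    rv <- tv[tv$assessable & tv$rna_gt != "0/0", , drop = FALSE]
    rna_var <- data.frame(chrom = rv$chrom, pos = rv$pos, ref = rv$ref,
                          alt = rv$alt, genotype = rv$rna_gt,
                          depth = 31L + stats::rpois(nrow(rv), 30),
                          source = "RNA")
    # RNA-only variants on gene bodies away from DNA variant positions
    n_ro <- stats::rpois(1, p$rna_only_rate * nrow(genes_df))
    if (n_ro) {
      gi <- sample(nrow(genes_df), n_ro, replace = TRUE)
      ro_pos <- vapply(gi, function(i)
        sample(genes_df$start[i]:genes_df$end[i], 1), 1L)
      ro_chr <- genes_df$chrom[gi]
      clash <- paste(ro_chr, ro_pos) %in% paste(dvar$chrom, dvar$pos)
      ro_ref <- mapply(function(chr, pos) seqs[[chr]][pos], ro_chr, ro_pos)
      ro <- data.frame(chrom = ro_chr[!clash], pos = ro_pos[!clash],
                       ref = ro_ref[!clash],
                       alt = vapply(ro_ref[!clash],
                                    function(r) sample(setdiff(bases, r), 1), ""),
                       genotype = sample(c("0/1", "1/1"), sum(!clash),
                                         replace = TRUE),
                       depth = 31L + stats::rpois(sum(!clash), 30),
                       source = "RNA")
      ro <- ro[!duplicated(paste(ro$chrom, ro$pos)), , drop = FALSE]
      rna_var <- rbind(rna_var, ro)
    }
    rna_var <- rna_var[order(rna_var$chrom, rna_var$pos), , drop = FALSE]
    rownames(rna_var) <- NULL

    # coverage track: assessable sites high, unassessable low
    cov_depth <- ifelse(tv$assessable, 31L + stats::rpois(nrow(tv), 30),
                        sample.int(30L, nrow(tv), replace = TRUE) - 1L)
    rna_cov <- data.frame(chrom = tv$chrom, start = tv$pos, end = tv$pos,
                          depth = cov_depth)
    rna_cov <- rna_cov[order(rna_cov$chrom, rna_cov$start), , drop = FALSE]
    rownames(rna_cov) <- NULL

    rownames(sites) <- rownames(dvar) <- rownames(tv) <- NULL
    samples[[s]] <- list(sites = sites, dna_variants = dvar,
                         rna_variants = rna_var, rna_coverage = rna_cov,
                         transmissions = tv, gene_methylated = gene_meth)
  }

  ## ---- per-gene truth table ------------------------------------------------
  genes_truth <- data.frame(gene_id = genes_df$gene_id,
                            chrom = genes_df$chrom, strand = genes_df$strand,
                            start = genes_df$start, end = genes_df$end,
                            meth_latent = meth_latent,
                            imprinted = genes_df$gene_id %in% imprinted)
  for (s in sample_names) {
    ss <- samples[[s]]
    fs <- ss$sites[ss$sites$passes_depth, , drop = FALSE]
    genes_truth[[paste0("n_6mA_", s)]] <-
      as.integer(table(factor(fs$gene_id, levels = genes_df$gene_id)))
    genes_truth[[paste0("methylated_", s)]] <- ss$gene_methylated
    gv <- ss$dna_variants[ss$dna_variants$genic, , drop = FALSE]
    genes_truth[[paste0("n_var_", s)]] <-
      as.integer(table(factor(gv$gene_id, levels = genes_df$gene_id)))
  }

  structure(list(params = p, genome = genome, gene_models = gm,
                 imprinted = imprinted, dbsnp = dbsnp, genes = genes_truth,
                 samples = samples),
            class = "sim_truth")
}

#' Write a simulated study to disk
#'
#' Emits, under `dir`: `genome.fa`, `annotation.gff3`, `dbsnp.tsv`,
#' `imprinted_genes.txt`, per-sample subdirectories with
#' `modifications.gff`, `dna.vcf`, `rna.vcf`, `rna_coverage.tsv`, and the
#' ground-truth tables of [truth_report]. Byte-identical across reruns
#' with the same parameters.
#'
#' @param params A [sim_params] object.
#' @param dir Output directory (created if needed).
#' @param n_samples 1 or 2.
#' @return Invisibly, a list with `truth` (the [simulate_truth] object)
#'   and `paths` (named file paths; per-sample paths nested under the
#'   sample name).
#' @export
simulate_study <- function(params = sim_params(), dir, n_samples = 1) {
  truth <- simulate_truth(params, n_samples = n_samples)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(dir, ...)
  Biostrings::writeXStringSet(truth$genome, fp("genome.fa"), width = 80)
  write_annotation(truth$gene_models, fp("annotation.gff3"))
  utils::write.table(truth$dbsnp, fp("dbsnp.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(sort(truth$imprinted), fp("imprinted_genes.txt"))
  paths <- list(genome = fp("genome.fa"), annotation = fp("annotation.gff3"),
                dbsnp = fp("dbsnp.tsv"), imprinted = fp("imprinted_genes.txt"))
  contigs <- stats::setNames(Biostrings::width(truth$genome),
                             names(truth$genome))
  for (s in names(truth$samples)) {
    sdir <- fp(s)
    dir.create(sdir, showWarnings = FALSE)
    ss <- truth$samples[[s]]
    write_modifications(
      methyl_sites(ss$sites$chrom, ss$sites$pos, ss$sites$strand,
                   ss$sites$coverage),
      file.path(sdir, "modifications.gff"))
    dv <- ss$dna_variants
    write_vcf(data.frame(chrom = dv$chrom, pos = dv$pos, ref = dv$ref,
                         alt = dv$alt, genotype = dv$genotype,
                         depth = dv$depth),
              file.path(sdir, "dna.vcf"), sample = s, contigs = contigs)
    write_vcf(ss$rna_variants, file.path(sdir, "rna.vcf"), sample = s,
              contigs = contigs)
    write_coverage_track(ss$rna_coverage, file.path(sdir, "rna_coverage.tsv"))
    paths[[s]] <- list(modifications = file.path(sdir, "modifications.gff"),
                       dna_vcf = file.path(sdir, "dna.vcf"),
                       rna_vcf = file.path(sdir, "rna.vcf"),
                       rna_coverage = file.path(sdir, "rna_coverage.tsv"))
  }
  truth_report(truth, dir)
  invisible(list(truth = truth, paths = paths))
}

#' Write flat ground-truth tables for a simulated study
#'
#' `truth_genes.tsv` (one row per gene: latent and per-sample methylation,
#' variant counts), plus per-sample `truth_sites.tsv`,
#' `truth_variants.tsv` and `truth_transmissions.tsv`.
#'
#' @param truth A `sim_truth` object.
#' @param dir Output directory.
#' @return Invisibly, the named vector of written paths.
#' @export
truth_report <- function(truth, dir) {
  stopifnot(inherits(truth, "sim_truth"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(d, path) {
    utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  paths <- c(genes = w(truth$genes, file.path(dir, "truth_genes.tsv")))
  for (s in names(truth$samples)) {
    ss <- truth$samples[[s]]
    sdir <- file.path(dir, s)
    dir.create(sdir, showWarnings = FALSE)
    paths[paste0(s, "_sites")] <- w(ss$sites,
                                    file.path(sdir, "truth_sites.tsv"))
    paths[paste0(s, "_variants")] <- w(ss$dna_variants,
                                       file.path(sdir, "truth_variants.tsv"))
    paths[paste0(s, "_transmissions")] <-
      w(ss$transmissions, file.path(sdir, "truth_transmissions.tsv"))
  }
  invisible(paths)
}

#' Simulate per-gene feature rows from known regression coefficients
#'
#' Direct generator for the association models: transmit-type counts are
#' drawn per gene from Poisson distributions and the methylation indicator
#' from the logistic model with the given coefficients, so fitted
#' coefficients can be compared with planted truth. Effect sizes default
#' to the magnitudes typical of the identity transmit types (het-to-het
#' and hom-to-hom) driving methylation.
#'
#' @param n Number of genes.
#' @param beta Named coefficients: `intercept` plus any of the transmit
#'   count columns `x01_00` ... `x11_11` (absent = 0).
#' @param x_mu Named Poisson means for the six count columns.
#' @param seed Optional seed.
#' @return Feature-row data.frame with `gene_id`, `methylated`,
#'   `y_density`, the six count columns, `n_var_dna`, `imprinted`;
#'   attribute `"beta"` carries the full planted coefficient vector.
#' @export
simulate_feature_rows <- function(n = 5000,
                                  beta = c(intercept = -0.5,
                                           x01_01 = 0.12, x11_11 = 0.13),
                                  x_mu = c(x01_00 = 0.3, x01_01 = 2,
                                           x01_11 = 0.3, x11_00 = 0.1,
                                           x11_01 = 0.1, x11_11 = 2),
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cols <- .transmit_cols()
  X <- vapply(cols, function(cn) stats::rpois(n, x_mu[[cn]]),
              numeric(n))
  b <- stats::setNames(rep(0, 6), cols)
  b[intersect(names(beta), cols)] <- beta[intersect(names(beta), cols)]
  eta <- beta[["intercept"]] + as.vector(X %*% b)
  y <- stats::runif(n) < stats::plogis(eta)
  rows <- data.frame(gene_id = sprintf("g%05d", seq_len(n)),
                     y_density = ifelse(y, stats::rbeta(n, 2, 250), 0),
                     methylated = y)
  rows <- cbind(rows, as.data.frame(X))
  rows$n_var_dna <- as.integer(rowSums(X))
  rows$imprinted <- FALSE
  attr(rows, "beta") <- c(intercept = unname(beta[["intercept"]]), b)
  rows
}

#' Simulate methylated-gene rows from a known linear density model
#'
#' Counts as in [simulate_feature_rows]; the response is
#' `y = a0 + sum_j a_j x_j + N(0, sigma^2)`, the linear model of 6mA
#' density on transmit-type counts.
#'
#' @param n Number of genes.
#' @param a Named coefficients (`intercept` plus count columns).
#' @param sigma Residual standard deviation.
#' @param x_mu Named Poisson means for the counts.
#' @param seed Optional seed.
#' @return Feature-row data.frame (all rows `methylated = TRUE`);
#'   attribute `"a"` carries the planted coefficients.
#' @export
simulate_linear_rows <- function(n = 5000,
                                 a = c(intercept = 1.3e-4, x01_00 = 4.7e-4),
                                 sigma = 2e-3,
                                 x_mu = c(x01_00 = 0.3, x01_01 = 2,
                                          x01_11 = 0.3, x11_00 = 0.1,
                                          x11_01 = 0.1, x11_11 = 2),
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cols <- .transmit_cols()
  X <- vapply(cols, function(cn) stats::rpois(n, x_mu[[cn]]), numeric(n))
  av <- stats::setNames(rep(0, 6), cols)
  av[intersect(names(a), cols)] <- a[intersect(names(a), cols)]
  y <- a[["intercept"]] + as.vector(X %*% av) + stats::rnorm(n, 0, sigma)
  rows <- data.frame(gene_id = sprintf("g%05d", seq_len(n)),
                     y_density = y, methylated = TRUE)
  rows <- cbind(rows, as.data.frame(X))
  rows$n_var_dna <- as.integer(rowSums(X))
  rows$imprinted <- FALSE
  attr(rows, "a") <- c(intercept = unname(a[["intercept"]]), av)
  rows
}
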