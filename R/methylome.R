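#' Depth thresholds for 6mA site filtering
#'
#' SMRT 6mA calls below a per-chromosome-class coverage cutoff are
#' unreliable; sites with coverage strictly below the cutoff are removed
#' (the boundary value is kept). Cutoffs differ between autosomes and sex
#' chromosomes because a male genome carries sex chromosomes at half depth.
#'
#' @param autosome_min Minimum coverage on autosomes.
#' @param sex_min Minimum coverage on sex chromosomes.
#' @return List of class `depth_thresholds`.
#' @export
depth_thresholds <- function(autosome_min, sex_min) {
  stopifnot(autosome_min >= 0, sex_min >= 0)
  structure(list(autosome_min = as.integer(autosome_min),
                 sex_min = as.integer(sex_min)),
            class = "depth_thresholds")
}

#' Filter 6mA sites by coverage depth
#'
#' Keeps a site on an autosome iff `coverage >= autosome_min`, on a sex
#' chromosome iff `coverage >= sex_min`. Output is sorted by
#' (chrom, pos, strand); the operation is idempotent.
#'
#' @param sites A [methyl_sites] data.frame.
#' @param thresholds A [depth_thresholds] object.
#' @param sex_chroms Character vector of sex-chromosome names.
#' @return Filtered, sorted [methyl_sites].
#' @export
filter_by_depth <- function(sites, thresholds, sex_chroms = c("chrX", "chrY")) {
  stopifnot(inherits(thresholds, "depth_thresholds"))
  min_cov <- ifelse(sites$chrom %in% sex_chroms,
                    thresholds$sex_min, thresholds$autosome_min)
  out <- sites[sites$coverage >= min_cov, , drop = FALSE]
  out <- out[order(out$chrom, out$pos, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# adenine positions callable for 6mA: A on the plus strand (+ sites) and
# T on the plus strand (- sites); internal
.adenine_count <- function(seqs, both_strands = TRUE) {
  lf <- Biostrings::letterFrequency(seqs, c("A", "T"))
  if (both_strands) sum(lf) else sum(lf[, "A"])
}

#' Genome-wide 6mA density
#'
#' Number of called sites divided by the number of adenines callable for
#' 6mA. With `both_strands = TRUE` (default) the denominator counts
#' adenines on both strands, i.e. plus-strand A plus plus-strand T,
#' matching strand-specific site calls.
#'
#' @param sites A [methyl_sites] data.frame (already depth-filtered).
#' @param genome A `Biostrings::DNAStringSet`, one entry per chromosome.
#' @param both_strands Count adenines on both strands in the denominator.
#' @return Fraction in `[0, 1]`.
#' @export
genome_density <- function(sites, genome, both_strands = TRUE) {
  nA <- .adenine_count(genome, both_strands)
  if (nA == 0) stop("genome contains no adenines")
  nrow(sites) / nA
}

#' Per-chromosome 6mA density
#'
#' @inheritParams genome_density
#' @return Named numeric vector, one density per chromosome in `genome`;
#'   chromosomes without sites report 0.
#' @export
per_chromosome_density <- function(sites, genome, both_strands = TRUE) {
  lf <- Biostrings::letterFrequency(genome, c("A", "T"))
  nA <- if (both_strands) rowSums(lf) else lf[, "A"]
  n <- table(factor(sites$chrom, levels = names(genome)))
  dens <- as.numeric(n) / nA
  dens[nA == 0] <- 0
  stats::setNames(dens, names(genome))
}

#' Per-gene 6mA counts, density and methylation status
#'
#' A site is assigned to a gene iff its position lies in the gene body and
#' its strand equals the gene's strand ("strand-methylated" genes). The
#' denominator counts coding-strand adenines: `A` in the plus-strand
#' sequence for `+` genes, `T` for `-` genes. A site inside two overlapping
#' same-strand genes counts in both. A gene with zero body adenines gets
#' density 0 and is flagged.
#'
#' @param gm A [gene_models] object.
#' @param sites Depth-filtered [methyl_sites].
#' @param genome `DNAStringSet` with every gene's chromosome present.
#' @return data.frame: `gene_id`, `chrom`, `strand`, `n_A`, `n_6mA`,
#'   `density`, `methylated`, `zero_adenine`.
#' @export
gene_methylation <- function(gm, sites, genome) {
  g <- gm$genes
  missing_chr <- setdiff(g$chrom, names(genome))
  if (length(missing_chr))
    stop("no sequence for chromosome(s): ", paste(missing_chr, collapse = ", "))

  n_A <- integer(nrow(g))
  for (chr in unique(g$chrom)) {
    idx <- which(g$chrom == chr)
    v <- Biostrings::Views(genome[[chr]], start = g$start[idx], end = g$end[idx])
    lf <- Biostrings::letterFrequency(v, c("A", "T"))
    n_A[idx] <- ifelse(g$strand[idx] == "+", lf[, "A"], lf[, "T"])
  }

  ggr <- .genes_gr(gm)
  sgr <- GenomicRanges::GRanges(sites$chrom,
                                IRanges::IRanges(sites$pos, width = 1),
                                strand = sites$strand)
  n_6mA <- GenomicRanges::countOverlaps(ggr, sgr, ignore.strand = FALSE)

  zero <- n_A == 0
  if (any(zero & n_6mA > 0))
    stop("gene(s) with 6mA sites but zero coding-strand adenines: ",
         paste(g$gene_id[zero & n_6mA > 0], collapse = ", "))
  if (any(zero))
    warning(sum(zero), " gene(s) with zero coding-strand adenines; density 0")
  density <- ifelse(zero, 0, n_6mA / n_A)
  data.frame(gene_id = g$gene_id, chrom = g$chrom, strand = g$strand,
             n_A = n_A, n_6mA = as.integer(n_6mA), density = density,
             methylated = n_6mA > 0, zero_adenine = zero)
}

#' Summary of 6mA sites relative to genes
#'
#' Counts how many sites fall on a gene (same-strand gene-body membership;
#' a site inside several genes counts once) and how many genes carry at
#' least one same-strand site.
#'
#' @param sites Depth-filtered [methyl_sites].
#' @param gm A [gene_models] object.
#' @return List: `n_total`, `n_on_gene`, `pct_on_gene` (2-decimal percent),
#'   `n_methylated_genes`.
#' @export
methyloci_on_gene_summary <- function(sites, gm) {
  if (!nrow(sites)) stop("no 6mA sites")
  ggr <- .genes_gr(gm)
  sgr <- GenomicRanges::GRanges(sites$chrom,
                                IRanges::IRanges(sites$pos, width = 1),
                                strand = sites$strand)
  hit <- GenomicRanges::countOverlaps(sgr, ggr, ignore.strand = FALSE) > 0
  per_gene <- GenomicRanges::countOverlaps(ggr, sgr, ignore.strand = FALSE)
  list(n_total = nrow(sites), n_on_gene = sum(hit),
       pct_on_gene = pct(sum(hit), nrow(sites)),
       n_methylated_genes = sum(per_gene > 0))
}

#' Percentage, rounded at the reporting boundary
#'
#' @param num,den Numerator count and denominator count.
#' @param digits Decimal places (default 2, the reporting convention).
#' @return `100 * num / den` rounded to `digits`.
#' @export
pct <- function(num, den, digits = 2) round(100 * num / den, digits)

#' Methylated-gene overlap between samples
#'
#' For two or more samples' methylated-gene sets, reports every
#' intersection cell and, per sample, the percentage of its genes found in
#' the all-sample intersection and in each pairwise intersection.
#'
#' @param gene_sets Named list (>= 2) of character vectors of gene ids.
#' @return List of class `shared_gene_summary`: `sizes`, `n_all` and
#'   `pct_all` (all-sample intersection and per-sample percentages),
#'   `pairwise` (data.frame with `n`, `pct_of_a`, `pct_of_b`). Percentages
#'   for an empty sample set are `NA`.
#' @export
shared_gene_summary <- function(gene_sets) {
  stopifnot(is.list(gene_sets), length(gene_sets) >= 2,
            !is.null(names(gene_sets)))
  gene_sets <- lapply(gene_sets, unique)
  sizes <- vapply(gene_sets, length, 0L)
  all_int <- Reduce(intersect, gene_sets)
  pct_all <- ifelse(sizes > 0, pct(length(all_int), sizes), NA_real_)
  prs <- utils::combn(names(gene_sets), 2)
  pairwise <- do.call(rbind, lapply(seq_len(ncol(prs)), function(k) {
    a <- prs[1, k]; b <- prs[2, k]
    n <- length(intersect(gene_sets[[a]], gene_sets[[b]]))
    data.frame(sample_a = a, sample_b = b, n = n,
               pct_of_a = if (sizes[a] > 0) pct(n, sizes[a]) else NA_real_,
               pct_of_b = if (sizes[b] > 0) pct(n, sizes[b]) else NA_real_)
  }))
  structure(list(sizes = sizes, n_all = length(all_int),
                 pct_all = stats::setNames(pct_all, names(gene_sets)),
                 pairwise = pairwise),
            class = "shared_gene_summary")
}

#' High-confidence 6mA sites shared by two samples
#'
#' Sites present in both inputs at the same (chrom, pos, strand); the
#' reported coverage is the minimum of the two calls.
#'
#' @param sites_a,sites_b Depth-filtered [methyl_sites].
#' @return [methyl_sites] of the intersection, sorted.
#' @export
consistent_sites <- function(sites_a, sites_b) {
  ka <- paste(sites_a$chrom, sites_a$pos, sites_a$strand)
  kb <- paste(sites_b$chrom, sites_b$pos, sites_b$strand)
  ia <- which(ka %in% kb)
  ib <- match(ka[ia], kb)
  out <- sites_a[ia, , drop = FALSE]
  out$coverage <- pmin(sites_a$coverage[ia], sites_b$coverage[ib])
  out <- out[order(out$chrom, out$pos, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pearson correlation of per-chromosome densities between samples
#'
#' @param dens_a,dens_b Named numeric vectors (chromosome -> density).
#' @return Pearson r over the shared chromosomes (>= 3 required); `NA`
#'   with a warning when either vector has zero variance.
#' @export
density_correlation <- function(dens_a, dens_b) {
  shared <- intersect(names(dens_a), names(dens_b))
  if (length(shared) < 3) stop("need >= 3 shared chromosomes")
  a <- dens_a[shared]; b <- dens_b[shared]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("zero variance; correlation undefined")
    return(NA_real_)
  }
  stats::cor(a, b, method = "pearson")
}

#' Export strand-normalised sequence contexts around 6mA sites
#'
#' One FASTA record per site: the reference window of length
#' `2 * flank + 1` centred on the site, reverse-complemented for minus
#' strand sites so the methylated adenine is always the central base.
#' Sites too close to a contig end are skipped with a warning.
#'
#' @param sites [methyl_sites].
#' @param genome `DNAStringSet`.
#' @param flank Bases on each side of the adenine (>= 1).
#' @param path Optional FASTA output file.
#' @return `DNAStringSet` of contexts, names `chrom:pos(strand)`;
#'   attribute `"n_skipped"` counts edge-skipped sites.
#' @export
export_motif_contexts <- function(sites, genome, flank = 10, path = NULL) {
  stopifnot(flank >= 1)
  len <- stats::setNames(Biostrings::width(genome), names(genome))
  ok <- sites$pos - flank >= 1 & sites$pos + flank <= len[sites$chrom]
  if (any(!ok))
    warning(sum(!ok), " site(s) within ", flank, " bases of a contig end skipped")
  s <- sites[ok, , drop = FALSE]
  seqs <- Biostrings::DNAStringSet(vapply(seq_len(nrow(s)), function(i) {
    w <- Biostrings::subseq(genome[[s$chrom[i]]],
                            s$pos[i] - flank, s$pos[i] + flank)
    if (s$strand[i] == "-") w <- Biostrings::reverseComplement(w)
    as.character(w)
  }, character(1)))
  names(seqs) <- if (nrow(s))
    paste0(s$chrom, ":", s$pos, "(", s$strand, ")") else character()
  if (!is.null(path)) Biostrings::writeXStringSet(seqs, path, width = 80)
  attr(seqs, "n_skipped") <- sum(!ok)
  seqs
}
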