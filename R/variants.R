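#' Screen DNA variants against known dbSNP positions
#'
#' Keeps variants whose (chrom, pos) appears in the position list; with no
#' list supplied the input passes through with a notice.
#'
#' @param vars Variant data.frame (see [read_vcf]).
#' @param dbsnp data.frame with columns `chrom`, `pos`, or `NULL`.
#' @return Filtered variants.
#' @export
filter_dna_variants <- function(vars, dbsnp = NULL) {
  if (is.null(dbsnp)) {
    message("no dbSNP positions supplied; DNA variants passed through")
    return(vars)
  }
  keep <- paste(vars$chrom, vars$pos) %in% paste(dbsnp$chrom, dbsnp$pos)
  out <- vars[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Screen RNA variants by sequencing depth
#'
#' Keeps variants with depth strictly greater than `min_depth` (the
#' ">30X" rule). Variants with missing depth are dropped with a warning.
#'
#' @param vars Variant data.frame.
#' @param min_depth Strict lower bound on depth (default 30).
#' @return Filtered variants.
#' @export
filter_rna_variants <- function(vars, min_depth = 30) {
  nodp <- is.na(vars$depth)
  if (any(nodp))
    warning(sum(nodp), " RNA variant(s) without depth dropped")
  out <- vars[!nodp & vars$depth > min_depth, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign positions to genes and exon/intron/UTR regions
#'
#' For every row of `x` (any table with `chrom` and `pos`), returns one row
#' per overlapping gene with the region label at that base under the
#' precedence UTR > exon > intron; positions outside every gene body are
#' labelled `intergenic` (with `gene_id` NA). Gene-body membership is
#' positional (strand-blind): variants are unstranded observations.
#'
#' @param x data.frame with columns `chrom`, `pos`.
#' @param gm A [gene_models] object.
#' @param regions Optional precomputed [gene_regions] table (saves
#'   recomputation across calls).
#' @return data.frame: `row` (index into `x`), `chrom`, `pos`, `gene_id`,
#'   `region`.
#' @export
annotate_regions <- function(x, gm, regions = NULL) {
  reg <- if (is.null(regions)) gene_regions(gm) else regions
  rgr <- GenomicRanges::GRanges(reg$chrom, IRanges::IRanges(reg$start, reg$end))
  pgr <- GenomicRanges::GRanges(x$chrom, IRanges::IRanges(x$pos, width = 1))
  ov <- GenomicRanges::findOverlaps(pgr, rgr, ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
  hit <- data.frame(row = qi, chrom = x$chrom[qi], pos = x$pos[qi],
                    gene_id = reg$gene_id[si], region = reg$region[si])
  outside <- setdiff(seq_len(nrow(x)), qi)
  if (length(outside))
    hit <- rbind(hit, data.frame(row = outside, chrom = x$chrom[outside],
                                 pos = x$pos[outside], gene_id = NA_character_,
                                 region = "intergenic"))
  hit <- hit[order(hit$row, hit$gene_id), , drop = FALSE]
  rownames(hit) <- NULL
  hit
}

#' Collapse region labels to one per position
#'
#' Each position gets its single highest-precedence label across all
#' overlapping genes (UTR > exon > intron > intergenic), so label
#' fractions over positions sum to 1.
#'
#' @inheritParams annotate_regions
#' @return data.frame: `region`, `n`, `fraction`.
#' @export
region_distribution <- function(x, gm, regions = NULL) {
  ann <- annotate_regions(x, gm, regions)
  prec <- c(UTR = 1, exon = 2, intron = 3, intergenic = 4)
  best <- tapply(prec[ann$region], ann$row, min)
  lab <- names(prec)[best]
  tab <- table(factor(lab, levels = names(prec)))
  data.frame(region = names(tab), n = as.integer(tab),
             fraction = if (nrow(x)) as.integer(tab) / nrow(x) else NA_real_)
}

#' Per-gene variant counts and variation ratio
#'
#' The variation ratio of a gene is its variant count divided by the gene
#' length (`end - start + 1`, introns included). Variants are assigned to
#' genes positionally; a variant in overlapping genes counts in each. A/T
#' versus C/G classification uses the REF base (plus strand). When 6mA
#' sites are supplied, variants coinciding with a site (see
#' [methylated_variation]) are counted per gene as `n_methylated_var`.
#'
#' @param gm A [gene_models] object.
#' @param vars Filtered variant data.frame.
#' @param sites Optional depth-filtered [methyl_sites].
#' @return data.frame: `gene_id`, `gene_length`, `n_var`,
#'   `variation_ratio`, `n_AT`, `n_CG`, `n_methylated_var`.
#' @export
gene_variation <- function(gm, vars, sites = NULL) {
  g <- gm$genes
  ggr <- .genes_gr(gm)
  vgr <- GenomicRanges::GRanges(vars$chrom, IRanges::IRanges(vars$pos, width = 1))
  ov <- GenomicRanges::findOverlaps(vgr, ggr, ignore.strand = TRUE)
  vi <- S4Vectors::queryHits(ov); gi <- S4Vectors::subjectHits(ov)
  is_at <- vars$ref %in% c("A", "T")
  meth <- if (is.null(sites)) rep(FALSE, nrow(vars)) else
    methylated_variation(vars, sites)$methylated
  cnt <- function(w) tabulate(gi[w], nbins = nrow(g))
  n_var <- cnt(TRUE)
  out <- data.frame(gene_id = g$gene_id,
                    gene_length = g$end - g$start + 1L,
                    n_var = n_var,
                    variation_ratio = n_var / (g$end - g$start + 1L),
                    n_AT = cnt(is_at[vi]),
                    n_CG = cnt(!is_at[vi]),
                    n_methylated_var = cnt(meth[vi]))
  stopifnot(all(out$n_AT + out$n_CG == out$n_var))
  out
}

#' Flag DNA variants that are also 6mA sites
#'
#' A variant is a "methylated variation" iff a 6mA site shares its
#' (chrom, pos) and the variant's REF base is the adenine of that site's
#' strand: `A` for a plus-strand site, `T` for a minus-strand site (the
#' VCF REF is the plus-strand base). With `require_base = FALSE` bare
#' positional overlap suffices. Positional overlaps whose REF base is
#' inconsistent with the site strand are tallied in the log.
#'
#' @param vars Variant data.frame.
#' @param sites Depth-filtered [methyl_sites].
#' @param require_base Require REF/strand concordance (default TRUE).
#' @return `vars` with a logical `methylated` column; attribute `"log"`
#'   counts inconsistent positional overlaps.
#' @export
methylated_variation <- function(vars, sites, require_base = TRUE) {
  key <- paste(vars$chrom, vars$pos)
  plus <- key %in% paste(sites$chrom, sites$pos)[sites$strand == "+"]
  minus <- key %in% paste(sites$chrom, sites$pos)[sites$strand == "-"]
  positional <- plus | minus
  concordant <- (plus & vars$ref == "A") | (minus & vars$ref == "T")
  vars$methylated <- if (require_base) concordant else positional
  n_inconsistent <- sum(positional & !concordant)
  if (n_inconsistent)
    message(n_inconsistent,
            " variant(s) overlap a 6mA site with a non-adenine REF base")
  attr(vars, "log") <- list(n_positional = sum(positional),
                            n_inconsistent = n_inconsistent)
  vars
}

#' A-mutated ratios at modified versus unmodified adenines
#'
#' Per gene, classifies every coding-strand adenine as 6mA-modified or not
#' and computes the fraction mutated in each class: `ratio_modified` =
#' methylated-variation variants / 6mA sites in the gene;
#' `ratio_unmodified` = variants at unmodified coding-strand adenines /
#' unmodified coding-strand adenines. A zero denominator yields `NA`
#' (undefined), not 0.
#'
#' @param gm A [gene_models] object.
#' @param sites Depth-filtered [methyl_sites].
#' @param vars Filtered variant data.frame.
#' @param genome `DNAStringSet`.
#' @return data.frame: `gene_id`, `n_modified_A`, `n_modified_mut`,
#'   `n_unmodified_A`, `n_unmodified_mut`, `ratio_modified`,
#'   `ratio_unmodified`.
#' @export
a_mutated_ratio <- function(gm, sites, vars, genome) {
  gmeth <- gene_methylation(gm, sites, genome)
  g <- gm$genes
  ggr <- .genes_gr(gm)

  vars <- methylated_variation(vars, sites)
  # variant at a coding-strand adenine of a gene: REF A for + genes, T for -
  vgr <- GenomicRanges::GRanges(vars$chrom, IRanges::IRanges(vars$pos, width = 1))
  ov <- GenomicRanges::findOverlaps(vgr, ggr, ignore.strand = TRUE)
  vi <- S4Vectors::queryHits(ov); gi <- S4Vectors::subjectHits(ov)
  on_coding_A <- (g$strand[gi] == "+" & vars$ref[vi] == "A") |
    (g$strand[gi] == "-" & vars$ref[vi] == "T")
  # modified-mut must also match the gene's strand (site strand == ref base)
  mod_mut <- tabulate(gi[on_coding_A & vars$methylated[vi]], nbins = nrow(g))
  any_A_mut <- tabulate(gi[on_coding_A], nbins = nrow(g))

  n_mod <- gmeth$n_6mA
  n_unmod <- gmeth$n_A - n_mod
  unmod_mut <- any_A_mut - mod_mut
  data.frame(gene_id = g$gene_id,
             n_modified_A = n_mod, n_modified_mut = mod_mut,
             n_unmodified_A = n_unmod, n_unmodified_mut = unmod_mut,
             ratio_modified = ifelse(n_mod > 0, mod_mut / n_mod, NA_real_),
             ratio_unmodified = ifelse(n_unmod > 0, unmod_mut / n_unmod,
                                       NA_real_))
}

#' Two-group comparison of per-gene ratios
#'
#' Student's two-sample t-test by default (equal variances, matching the
#' conventional reporting for these comparisons); Welch via
#' `var_equal = FALSE`. Two identical constant groups return t = 0, p = 1
#' by convention.
#'
#' @param ratios_a,ratios_b Numeric vectors (n >= 2 each); NAs dropped.
#' @param names Length-2 character vector of group labels.
#' @param var_equal Assume equal variances (default TRUE).
#' @return List of class `comparison_result`: group names, sizes, means,
#'   `statistic`, `df`, `p_value`, `method`.
#' @export
group_ratio_comparison <- function(ratios_a, ratios_b,
                                   names = c("a", "b"), var_equal = TRUE) {
  a <- ratios_a[!is.na(ratios_a)]; b <- ratios_b[!is.na(ratios_b)]
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (stats::sd(a) == 0 && stats::sd(b) == 0 && mean(a) == mean(b)) {
    res <- list(statistic = 0, parameter = length(a) + length(b) - 2,
                p.value = 1, method = "degenerate (no variance)")
  } else {
    res <- stats::t.test(a, b, var.equal = var_equal)
  }
  structure(list(groups = names, n = c(length(a), length(b)),
                 means = c(mean(a), mean(b)),
                 statistic = unname(res$statistic),
                 df = unname(res$parameter),
                 p_value = res$p.value,
                 method = res$method),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s (n=%d, mean=%.4g) vs %s (n=%d, mean=%.4g): t=%.3f, df=%.1f, p=%.3g\n",
              x$groups[1], x$n[1], x$means[1], x$groups[2], x$n[2], x$means[2],
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Per-gene region-level variation ratios
#'
#' Region analogue of [gene_variation]: per gene and region class
#' (UTR/exon/intron), the variant count over the total region length in
#' that gene.
#'
#' @param gm A [gene_models] object.
#' @param vars Filtered variant data.frame.
#' @param regions Optional precomputed [gene_regions] table.
#' @return data.frame: `gene_id`, `region`, `region_length`, `n_var`,
#'   `variation_ratio`; genes with no bases of a region class are omitted
#'   for that class.
#' @export
region_gene_variation <- function(gm, vars, regions = NULL) {
  reg <- if (is.null(regions)) gene_regions(gm) else regions
  reg_len <- stats::aggregate(cbind(region_length = reg$end - reg$start + 1),
                              by = list(gene_id = reg$gene_id,
                                        region = reg$region), FUN = sum)
  ann <- annotate_regions(vars, gm, reg)
  ann <- ann[ann$region != "intergenic", , drop = FALSE]
  if (nrow(ann)) {
    cnt <- stats::aggregate(cbind(n_var = ann$pos * 0 + 1),
                            by = list(gene_id = ann$gene_id,
                                      region = ann$region), FUN = sum)
    out <- merge(reg_len, cnt, by = c("gene_id", "region"), all.x = TRUE)
  } else {
    out <- reg_len; out$n_var <- 0L
  }
  out$n_var[is.na(out$n_var)] <- 0L
  out$variation_ratio <- out$n_var / out$region_length
  out <- out[order(out$gene_id, out$region), , drop = FALSE]
  rownames(out) <- NULL
  out
}
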