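#' The six DNA-to-RNA transmit types
#'
#' A variant site with DNA genotype 0/1 or 1/1 and RNA genotype 0/0, 0/1
#' or 1/1 falls into exactly one of six ordered pairs (0 = reference
#' allele, 1 = alternate allele).
#'
#' @return Character vector of the six type labels in canonical order.
#' @export
transmit_types <- function() {
  c("0/1_0/0", "0/1_0/1", "0/1_1/1", "1/1_0/0", "1/1_0/1", "1/1_1/1")
}

# syntactic column names for the six types, used in feature tables
.transmit_cols <- function() c("x01_00", "x01_01", "x01_11",
                               "x11_00", "x11_01", "x11_11")

#' Map transmit-type labels to feature-table column names and back
#' @param x Character vector of type labels or column names.
#' @return The corresponding column names (`transmit_col`) or type labels
#'   (`transmit_label`).
#' @export
transmit_col <- function(x) {
  stats::setNames(.transmit_cols(), transmit_types())[x]
}

#' @rdname transmit_col
#' @export
transmit_label <- function(x) {
  stats::setNames(transmit_types(), .transmit_cols())[x]
}

#' Classify a DNA/RNA genotype pair into a transmit type
#'
#' @param dna_gt DNA genotype(s), `"0/1"` or `"1/1"` (a 0/0 DNA genotype is
#'   an error: sites without a DNA variant are outside the six types).
#' @param rna_gt RNA genotype(s), `"0/0"`, `"0/1"` or `"1/1"`.
#' @return Character vector of transmit-type labels.
#' @export
classify_transmit <- function(dna_gt, rna_gt) {
  if (!all(dna_gt %in% c("0/1", "1/1")))
    stop("DNA genotype must be 0/1 or 1/1 (got: ",
         paste(unique(setdiff(dna_gt, c("0/1", "1/1"))), collapse = ", "), ")")
  if (!all(rna_gt %in% c("0/0", "0/1", "1/1")))
    stop("RNA genotype must be 0/0, 0/1 or 1/1")
  paste0(dna_gt, "_", rna_gt)
}

#' Pair DNA variants with RNA genotypes at the same sites
#'
#' For each DNA variant: (a) an RNA variant at the same (chrom, pos) with
#' the same ref/alt supplies the RNA genotype; (b) otherwise, RNA coverage
#' at the site of at least `min_rna_depth` supports an inferred reference
#' genotype 0/0 (GATK-style VCFs never emit 0/0 rows, so some evidence
#' threshold is required); (c) otherwise the site is excluded as
#' RNA-unassessable. An RNA variant at the position with a different
#' allele is excluded and logged as allele-discordant. RNA variants with
#' no DNA variant at their position are returned separately, unclassified.
#'
#' @param dna,rna Filtered variant data.frames (see [filter_dna_variants],
#'   [filter_rna_variants]).
#' @param rna_cov Coverage track data.frame (`chrom`, `start`, `end`,
#'   `depth`), or `NULL` (then rule (b) never applies).
#' @param min_rna_depth Minimum RNA coverage to infer 0/0 (default 30).
#' @return List: `records` (data.frame `chrom`, `pos`, `ref`, `alt`,
#'   `dna_gt`, `rna_gt`, `transmit_type`), `rna_only` (unmatched RNA
#'   variants), `log` (tallies; classified + discordant + insufficient =
#'   number of DNA variants).
#' @export
join_dna_rna <- function(dna, rna, rna_cov = NULL, min_rna_depth = 30) {
  kd <- paste(dna$chrom, dna$pos)
  kr <- paste(rna$chrom, rna$pos)
  m <- match(kd, kr)
  has_rna <- !is.na(m)
  allele_ok <- has_rna & dna$ref == rna$ref[m] & dna$alt == rna$alt[m]
  discordant <- has_rna & !allele_ok

  covered <- rep(FALSE, nrow(dna))
  if (!is.null(rna_cov) && nrow(rna_cov)) {
    cgr <- GenomicRanges::GRanges(rna_cov$chrom,
                                  IRanges::IRanges(rna_cov$start, rna_cov$end),
                                  depth = rna_cov$depth)
    dgr <- GenomicRanges::GRanges(dna$chrom, IRanges::IRanges(dna$pos, width = 1))
    ov <- GenomicRanges::findOverlaps(dgr, cgr)
    dmax <- tapply(rna_cov$depth[S4Vectors::subjectHits(ov)],
                   S4Vectors::queryHits(ov), max)
    covered[as.integer(names(dmax))] <- dmax >= min_rna_depth
  }
  infer_ref <- !has_rna & covered
  classified <- allele_ok | infer_ref

  rna_gt <- rep(NA_character_, nrow(dna))
  rna_gt[allele_ok] <- rna$genotype[m[allele_ok]]
  rna_gt[infer_ref] <- "0/0"

  rec <- data.frame(chrom = dna$chrom[classified], pos = dna$pos[classified],
                    ref = dna$ref[classified], alt = dna$alt[classified],
                    dna_gt = dna$genotype[classified],
                    rna_gt = rna_gt[classified])
  rec$transmit_type <- classify_transmit(rec$dna_gt, rec$rna_gt)
  rec <- rec[order(rec$chrom, rec$pos), , drop = FALSE]
  rownames(rec) <- NULL

  rna_only <- rna[!(kr %in% kd), , drop = FALSE]
  rownames(rna_only) <- NULL
  log <- list(n_dna = nrow(dna), n_classified = sum(classified),
              n_allele_discordant = sum(discordant),
              n_insufficient_rna = sum(!has_rna & !covered),
              n_rna_only = nrow(rna_only))
  stopifnot(log$n_classified + log$n_allele_discordant +
              log$n_insufficient_rna == log$n_dna)
  list(records = rec, rna_only = rna_only, log = log)
}

#' High-confidence transmissions shared by two samples
#'
#' Records present in both samples with identical
#' (chrom, pos, ref, alt, transmit_type) — the transmission event itself,
#' not just the locus. `key = "position"` relaxes the match to
#' (chrom, pos).
#'
#' @param recs_a,recs_b Transmission record data.frames (see
#'   [join_dna_rna]).
#' @param key `"full"` (default) or `"position"`.
#' @return The matching records of `recs_a`, sorted.
#' @export
consistent_transmissions <- function(recs_a, recs_b,
                                     key = c("full", "position")) {
  key <- match.arg(key)
  mk <- function(r) if (key == "full")
    paste(r$chrom, r$pos, r$ref, r$alt, r$transmit_type)
  else paste(r$chrom, r$pos)
  out <- recs_a[mk(recs_a) %in% mk(recs_b), , drop = FALSE]
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-gene counts of the six transmit types
#'
#' Counts, for every gene, the classified transmission records whose
#' position lies in the gene body (positional; a record in overlapping
#' genes counts in each). Genes with no records emit all-zero rows — the
#' logistic model needs them as negatives.
#'
#' @param recs Transmission records (see [join_dna_rna]).
#' @param gm A [gene_models] object.
#' @return data.frame: `gene_id` plus the six count columns `x01_00` ...
#'   `x11_11` (ordered as [transmit_types]).
#' @export
gene_transmit_counts <- function(recs, gm) {
  g <- gm$genes
  ggr <- .genes_gr(gm)
  out <- data.frame(gene_id = g$gene_id)
  types <- transmit_types()
  cols <- .transmit_cols()
  counts <- matrix(0L, nrow(g), 6, dimnames = list(NULL, cols))
  if (nrow(recs)) {
    rgr <- GenomicRanges::GRanges(recs$chrom,
                                  IRanges::IRanges(recs$pos, width = 1))
    ov <- GenomicRanges::findOverlaps(rgr, ggr, ignore.strand = TRUE)
    ri <- S4Vectors::queryHits(ov); gi <- S4Vectors::subjectHits(ov)
    for (k in seq_along(types))
      counts[, k] <- tabulate(gi[recs$transmit_type[ri] == types[k]],
                              nbins = nrow(g))
  }
  cbind(out, as.data.frame(counts))
}
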