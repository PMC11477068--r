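#' Gene model collection
#'
#' Container for gene annotations: one row per gene plus a table of
#' sub-gene features (exons and UTRs). Coordinates are 1-based inclusive
#' throughout, the GFF/VCF convention.
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `strand`
#'   (`"+"`/`"-"`), `start`, `end` (1-based inclusive gene body).
#' @param features data.frame with columns `gene_id`, `type` (one of
#'   `"exon"`, `"UTR5"`, `"UTR3"`, `"UTR"`), `start`, `end`. May have zero
#'   rows. Exon intervals are merged per gene on construction.
#'
#' @details Invariants enforced: `start <= end` for every interval; every
#'   feature lies within its gene body (a violating exon is a hard error
#'   naming the gene); exons are non-overlapping after merging.
#'
#' @return An object of class `gene_models`: a list with elements `genes`
#'   and `features` (both data.frames).
#' @export
gene_models <- function(genes, features = NULL) {
  req <- c("gene_id", "chrom", "strand", "start", "end")
  stopifnot(is.data.frame(genes), all(req %in% names(genes)))
  genes <- genes[, req]
  genes$gene_id <- as.character(genes$gene_id)
  genes$chrom <- as.character(genes$chrom)
  genes$strand <- as.character(genes$strand)
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene_id: ",
         paste(unique(genes$gene_id[duplicated(genes$gene_id)]), collapse = ", "))
  if (!all(genes$strand %in% c("+", "-")))
    stop("gene strand must be '+' or '-'")
  if (any(genes$start < 1L) || any(genes$end < genes$start))
    stop("invalid gene coordinates (need 1 <= start <= end)")
  genes <- genes[order(genes$chrom, genes$start, genes$gene_id), , drop = FALSE]
  rownames(genes) <- NULL

  if (is.null(features))
    features <- data.frame(gene_id = character(), type = character(),
                           start = integer(), end = integer())
  stopifnot(all(c("gene_id", "type", "start", "end") %in% names(features)))
  features <- features[, c("gene_id", "type", "start", "end")]
  features$gene_id <- as.character(features$gene_id)
  features$type <- as.character(features$type)
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  if (!all(features$type %in% c("exon", "UTR5", "UTR3", "UTR")))
    stop("feature type must be exon/UTR5/UTR3/UTR")
  unknown <- setdiff(features$gene_id, genes$gene_id)
  if (length(unknown))
    stop("features reference unknown genes: ", paste(unknown, collapse = ", "))
  if (nrow(features)) {
    idx <- match(features$gene_id, genes$gene_id)
    bad <- features$start < genes$start[idx] | features$end > genes$end[idx] |
      features$start > features$end
    if (any(bad))
      stop("feature outside gene body in gene(s): ",
           paste(unique(features$gene_id[bad]), collapse = ", "))
    # merge exon intervals per gene; UTRs kept verbatim
    ex <- features[features$type == "exon", , drop = FALSE]
    ut <- features[features$type != "exon", , drop = FALSE]
    if (nrow(ex)) {
      merged <- lapply(split(ex, ex$gene_id), function(d) {
        r <- IRanges::reduce(IRanges::IRanges(d$start, d$end))
        data.frame(gene_id = d$gene_id[1], type = "exon",
                   start = IRanges::start(r), end = IRanges::end(r))
      })
      ex <- do.call(rbind, merged)
    }
    features <- rbind(ex, ut)
  }
  gi <- match(features$gene_id, genes$gene_id)
  features <- features[order(gi, features$start, features$end, features$type), ,
                       drop = FALSE]
  rownames(features) <- NULL
  structure(list(genes = genes, features = features), class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat("gene_models:", nrow(x$genes), "genes,",
      sum(x$features$type == "exon"), "exons,",
      sum(x$features$type != "exon"), "UTR records\n")
  invisible(x)
}

#' Read a GFF3 or GTF gene annotation
#'
#' Parses gene, exon and UTR records into a [gene_models] collection. The
#' dialect (GFF3 vs GTF) is auto-detected by `rtracklayer::readGFF()`, and
#' both are normalised to the same in-memory representation: exons are
#' merged, UTR records lacking a 5'/3' tag keep the generic tag `"UTR"`.
#'
#' Records of type `gene` without a strand are rejected with a warning;
#' an exon falling outside its gene body is a hard error naming the gene.
#'
#' @param path GFF3 or GTF file.
#' @return A [gene_models] object. The attribute `"log"` carries counts of
#'   rejected records.
#' @export
read_annotation <- function(path) {
  stopifnot(file.exists(path))
  df <- as.data.frame(rtracklayer::readGFF(path))
  df$type <- as.character(df$type)
  df$strand <- as.character(df$strand)
  is_gtf <- "gene_id" %in% names(df) && !("ID" %in% names(df))

  gid_of <- function(d) {
    if (is_gtf) return(as.character(d$gene_id))
    # GFF3: gene rows carry ID, children carry Parent (a CharacterList)
    out <- rep(NA_character_, nrow(d))
    if ("Parent" %in% names(d)) {
      par <- d$Parent
      has <- lengths(par) > 0
      out[has] <- vapply(par[has], function(p) p[[1]], character(1))
    }
    if ("ID" %in% names(d)) out[is.na(out)] <- as.character(d$ID[is.na(out)])
    out
  }

  grec <- df[df$type == "gene", , drop = FALSE]
  if (!nrow(grec)) stop("no 'gene' records found in ", path)
  grec$gene_id <- gid_of(grec)
  no_strand <- !(grec$strand %in% c("+", "-"))
  n_rejected_strand <- sum(no_strand)
  if (n_rejected_strand) {
    warning(n_rejected_strand, " gene record(s) without strand rejected")
    grec <- grec[!no_strand, , drop = FALSE]
  }
  genes <- data.frame(gene_id = grec$gene_id, chrom = as.character(grec$seqid),
                      strand = grec$strand, start = grec$start, end = grec$end)

  type_map <- c(exon = "exon", five_prime_UTR = "UTR5",
                three_prime_UTR = "UTR3", UTR = "UTR",
                five_prime_utr = "UTR5", three_prime_utr = "UTR3")
  frec <- df[df$type %in% names(type_map), , drop = FALSE]
  n_skipped_types <- nrow(df) - nrow(grec) - n_rejected_strand - nrow(frec)
  features <- data.frame(gene_id = gid_of(frec),
                         type = unname(type_map[frec$type]),
                         start = frec$start, end = frec$end)
  features <- features[features$gene_id %in% genes$gene_id, , drop = FALSE]
  gm <- gene_models(genes, features)
  attr(gm, "log") <- list(n_genes = nrow(genes),
                          n_rejected_no_strand = n_rejected_strand,
                          n_other_types_skipped = n_skipped_types)
  gm
}

#' Write a gene annotation as canonical GFF3
#'
#' Emits a deterministic, sorted GFF3 (genes by chromosome/start/id, then
#' each gene's features by start). Writing and re-reading a collection
#' produced by [gene_models] reproduces it exactly, and a second write is
#' byte-identical.
#'
#' @param gm A [gene_models] object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(gm, path) {
  stopifnot(inherits(gm, "gene_models"))
  type_out <- c(exon = "exon", UTR5 = "five_prime_UTR",
                UTR3 = "three_prime_UTR", UTR = "UTR")
  g <- gm$genes
  f <- gm$features
  gi <- match(f$gene_id, g$gene_id)
  gene_lines <- paste(g$chrom, "m6atrans", "gene", g$start, g$end, ".",
                      g$strand, ".", paste0("ID=", g$gene_id), sep = "\t")
  feat_lines <- if (nrow(f))
    paste(g$chrom[gi], "m6atrans", type_out[f$type], f$start,
          f$end, ".", g$strand[gi], ".",
          paste0("Parent=", f$gene_id), sep = "\t")
  else character()
  # interleave: each gene line, then its features (already in feature order)
  key_gene <- order(c(seq_len(nrow(g)), gi),
                    c(rep(0L, nrow(g)), seq_len(nrow(f))))
  writeLines(c("##gff-version 3", c(gene_lines, feat_lines)[key_gene]), path)
  invisible(path)
}

#' Derive disjoint exon/intron/UTR regions for every gene
#'
#' Partitions each gene body into regions under the precedence
#' UTR > exon > intron: UTR intervals (5', 3' and untagged pooled as one
#' class), exon bases not in a UTR, and intron = everything else in the
#' body. The three region sets tile the gene body exactly.
#'
#' @param gm A [gene_models] object.
#' @return data.frame with columns `gene_id`, `chrom`, `strand`, `region`
#'   (`"UTR"`, `"exon"`, `"intron"`), `start`, `end`.
#' @export
gene_regions <- function(gm) {
  stopifnot(inherits(gm, "gene_models"))
  g <- gm$genes
  f <- gm$features
  # vectorised per-gene interval algebra: encode the gene id as the
  # seqname, so reduce/setdiff act within genes but in one C pass
  lev <- g$gene_id
  gr <- function(ids, start, end)
    GenomicRanges::GRanges(factor(ids, levels = lev),
                           IRanges::IRanges(start, end))
  body <- gr(g$gene_id, g$start, g$end)
  is_ex <- f$type == "exon"
  utr <- GenomicRanges::reduce(gr(f$gene_id[!is_ex], f$start[!is_ex],
                                  f$end[!is_ex]))
  exon <- GenomicRanges::setdiff(
    GenomicRanges::reduce(gr(f$gene_id[is_ex], f$start[is_ex], f$end[is_ex])),
    utr)
  intron <- GenomicRanges::setdiff(GenomicRanges::setdiff(body, exon), utr)
  mk <- function(x, lab) {
    if (!length(x)) return(NULL)
    gid <- as.character(GenomicRanges::seqnames(x))
    i <- match(gid, g$gene_id)
    data.frame(gene_id = gid, chrom = g$chrom[i], strand = g$strand[i],
               region = lab, start = GenomicRanges::start(x),
               end = GenomicRanges::end(x))
  }
  res <- rbind(mk(utr, "UTR"), mk(exon, "exon"), mk(intron, "intron"))
  res <- res[order(match(res$gene_id, g$gene_id), res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# GRanges of gene bodies (strand-aware); internal
.genes_gr <- function(gm) {
  g <- gm$genes
  GenomicRanges::GRanges(g$chrom, IRanges::IRanges(g$start, g$end),
                         strand = g$strand, gene_id = g$gene_id)
}
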