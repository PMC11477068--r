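#' Read biallelic SNVs from a single-sample VCF
#'
#' Returns only biallelic single-nucleotide records with genotype 0/1 or
#' 1/1. Multi-allelic records, indels, 0/0 and missing genotypes are
#' excluded and counted in the log; a malformed genotype rejects the record
#' with a warning rather than crashing. Phased genotypes are normalised to
#' unphased (`0|1` and `1|0` both become `0/1`).
#'
#' @param path VCF v4.x file with a single sample column.
#' @param source `"DNA"` or `"RNA"`; recorded on every variant.
#' @return data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `genotype` (`"0/1"`/`"1/1"`), `depth` (NA when the VCF carries no DP)
#'   and `source`; attribute `"log"` tallies exclusions.
#' @export
read_vcf <- function(path, source = c("DNA", "RNA")) {
  source <- match.arg(source)
  stopifnot(file.exists(path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  n_in <- nrow(fix)
  log <- list(n_records = n_in, n_multiallelic = 0L, n_indel = 0L,
              n_homref_or_missing = 0L, n_malformed_gt = 0L, n_kept = 0L)
  empty <- data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), genotype = character(),
                      depth = integer(), source = character())
  if (n_in == 0) { attr(empty, "log") <- log; return(empty) }
  if (ncol(v@gt) > 2) stop("expected a single-sample VCF: ", path)
  gt <- as.character(vcfR::extract.gt(v, element = "GT"))
  dp <- suppressWarnings(
    as.integer(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)))
  if (is.null(dp) || !length(dp)) dp <- rep(NA_integer_, n_in)

  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  multi <- grepl(",", alt, fixed = TRUE)
  snv <- !multi & nchar(ref) == 1 & nchar(alt) == 1 &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  log$n_multiallelic <- sum(multi)
  log$n_indel <- sum(!multi & !snv)

  gt_norm <- gsub("|", "/", gt, fixed = TRUE)
  gt_norm[gt_norm == "1/0"] <- "0/1"
  wellformed <- !is.na(gt_norm) & gt_norm %in% c("0/0", "0/1", "1/1")
  malformed <- !is.na(gt) & !wellformed
  log$n_malformed_gt <- sum(malformed & snv)
  if (log$n_malformed_gt)
    warning(log$n_malformed_gt, " record(s) with malformed genotype rejected")
  log$n_homref_or_missing <- sum(snv & !malformed &
                                   (is.na(gt) | gt_norm == "0/0"))
  keep <- snv & wellformed & gt_norm %in% c("0/1", "1/1")
  log$n_kept <- sum(keep)

  out <- data.frame(chrom = fix[keep, "CHROM"],
                    pos = as.integer(fix[keep, "POS"]),
                    ref = ref[keep], alt = alt[keep],
                    genotype = gt_norm[keep], depth = dp[keep],
                    source = source)
  rownames(out) <- NULL
  attr(out, "log") <- log
  out
}

#' Write variants as a minimal single-sample VCF
#'
#' Deterministic order (chrom, pos); FORMAT is `GT:DP`. Contig lengths, if
#' supplied, are written as `##contig` header lines.
#'
#' @param variants data.frame with `chrom`, `pos`, `ref`, `alt`, `genotype`,
#'   `depth`.
#' @param path Output file.
#' @param sample Sample name for the genotype column.
#' @param contigs Optional named integer vector of contig lengths.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, path, sample = "SAMPLE", contigs = NULL) {
  v <- variants[order(variants$chrom, variants$pos), , drop = FALSE]
  hdr <- c("##fileformat=VCFv4.2",
           if (!is.null(contigs))
             paste0("##contig=<ID=", names(contigs), ",length=", contigs, ">"),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", sample, sep = "\t"))
  dp <- ifelse(is.na(v$depth), ".", as.character(v$depth))
  recs <- if (nrow(v))
    paste(v$chrom, v$pos, ".", v$ref, v$alt, ".", "PASS", ".", "GT:DP",
          paste0(v$genotype, ":", dp), sep = "\t")
  else character()
  writeLines(c(hdr, recs), path)
  invisible(path)
}

#' Read a dbSNP position list
#'
#' Accepts either a VCF (positions from columns 1-2) or a TSV with columns
#' `chrom` and `pos` (header optional).
#'
#' @param path File of known-variant positions.
#' @return data.frame with columns `chrom`, `pos`.
#' @export
read_dbsnp <- function(path) {
  stopifnot(file.exists(path))
  first <- readLines(path, n = 1)
  if (startsWith(first, "##fileformat=VCF")) {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "#")]
    f <- strsplit(lines, "\t", fixed = TRUE)
    return(data.frame(chrom = vapply(f, `[`, "", 1),
                      pos = as.integer(vapply(f, `[`, "", 2))))
  }
  header <- grepl("chrom", first)
  d <- utils::read.delim(path, header = header)
  if (!header) names(d)[1:2] <- c("chrom", "pos")
  data.frame(chrom = as.character(d$chrom), pos = as.integer(d$pos))
}

#' Read / write a per-base RNA coverage track
#'
#' TSV with header `chrom start end depth`; intervals are 1-based inclusive,
#' non-overlapping. Used to establish reference (0/0) RNA genotypes at DNA
#' variant sites with adequate RNA evidence.
#'
#' @param path TSV file.
#' @return data.frame with columns `chrom`, `start`, `end`, `depth`.
#' @export
read_coverage_track <- function(path) {
  d <- utils::read.delim(path, header = TRUE)
  stopifnot(all(c("chrom", "start", "end", "depth") %in% names(d)))
  d <- d[order(d$chrom, d$start), c("chrom", "start", "end", "depth")]
  stopifnot(all(d$depth >= 0), all(d$start <= d$end))
  rownames(d) <- NULL
  d
}

#' @rdname read_coverage_track
#' @param track data.frame with `chrom`, `start`, `end`, `depth`.
#' @return `path`, invisibly (for the writer).
#' @export
write_coverage_track <- function(track, path) {
  t <- track[order(track$chrom, track$start), , drop = FALSE]
  utils::write.table(t, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
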