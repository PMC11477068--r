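#' Construct a table of 6mA sites
#'
#' @param chrom,pos,strand,coverage,score Vectors of equal length (score
#'   optional). `pos` is the 1-based position of the methylated adenine on
#'   `strand`; `coverage` the read depth of the call.
#' @return data.frame of class `methyl_sites` with those five columns.
#' @export
methyl_sites <- function(chrom, pos, strand, coverage, score = NA_real_) {
  score <- rep_len(as.numeric(score), length(chrom))
  s <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                  strand = as.character(strand),
                  coverage = as.integer(coverage),
                  score = score)
  if (nrow(s)) {
    stopifnot(all(s$pos >= 1L), all(s$strand %in% c("+", "-")),
              all(s$coverage >= 0L, na.rm = TRUE))
  }
  class(s) <- c("methyl_sites", "data.frame")
  s
}

#' Read 6mA base-modification calls
#'
#' Accepts either an ipdSummary-style modifications GFF (feature type `m6A`,
#' or `modified_base` with an m6A attribute; `coverage=` in column 9) or a
#' plain TSV with header `chrom pos strand coverage [score]`. Only m6A
#' records are returned; other modification types are skipped silently with
#' a count in the log; a GFF record with `start != end` is rejected with a
#' warning.
#'
#' @param path Modifications GFF or TSV file.
#' @return A [methyl_sites] data.frame; attribute `"log"` holds counts of
#'   skipped/rejected records.
#' @export
read_modifications <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(body)) {
    out <- methyl_sites(character(), integer(), character(), integer())
    attr(out, "log") <- list(n_m6A = 0L, n_other_type = 0L, n_bad_span = 0L)
    return(out)
  }
  nf <- length(strsplit(body[1], "\t", fixed = TRUE)[[1]])
  if (nf >= 8) {                               # GFF dialect
    f <- strsplit(body, "\t", fixed = TRUE)
    f <- f[lengths(f) >= 8]
    m <- matrix(unlist(lapply(f, `[`, 1:9)), ncol = 9, byrow = TRUE)
    type <- m[, 3]
    attrs <- m[, 9]
    is_m6a <- type == "m6A" |
      (type == "modified_base" & grepl("m6A", attrs, fixed = TRUE))
    n_other <- sum(!is_m6a)
    m <- m[is_m6a, , drop = FALSE]
    start <- as.integer(m[, 4]); end <- as.integer(m[, 5])
    bad <- start != end
    if (any(bad)) warning(sum(bad), " m6A record(s) with start != end rejected")
    m <- m[!bad, , drop = FALSE]
    cov <- suppressWarnings(
      as.integer(sub(".*coverage=([0-9]+).*", "\\1", m[, 9])))
    cov[is.na(cov)] <- 0L
    score <- suppressWarnings(as.numeric(m[, 6]))
    out <- methyl_sites(m[, 1], as.integer(m[, 4]), m[, 7], cov, score)
    attr(out, "log") <- list(n_m6A = nrow(out), n_other_type = n_other,
                             n_bad_span = sum(bad))
    if (n_other) message(n_other, " non-m6A modification record(s) skipped")
  } else {                                     # TSV dialect
    d <- utils::read.delim(path, header = TRUE, comment.char = "#")
    stopifnot(all(c("chrom", "pos", "strand", "coverage") %in% names(d)))
    if (!"score" %in% names(d)) d$score <- NA_real_
    out <- methyl_sites(d$chrom, d$pos, d$strand, d$coverage, d$score)
    attr(out, "log") <- list(n_m6A = nrow(out), n_other_type = 0L,
                             n_bad_span = 0L)
  }
  out
}

#' Write 6mA sites as a modifications GFF
#'
#' Deterministic output, sorted by (chrom, pos, strand); one single-base
#' `m6A` record per site with a `coverage=` attribute.
#'
#' @param sites A [methyl_sites] data.frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_modifications <- function(sites, path) {
  s <- sites[order(sites$chrom, sites$pos, sites$strand), , drop = FALSE]
  score <- ifelse(is.na(s$score), ".", format(s$score, trim = TRUE))
  lines <- c("##gff-version 3",
             if (nrow(s)) paste(s$chrom, "m6atrans", "m6A", s$pos, s$pos,
                                score, s$strand, ".",
                                paste0("coverage=", s$coverage), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Export 6mA sites as BED
#'
#' BED uses 0-based half-open coordinates; a site at 1-based position p
#' becomes the interval `[p-1, p)`. Column 5 carries the coverage.
#'
#' @param sites A [methyl_sites] data.frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
sites_to_bed <- function(sites, path) {
  s <- sites[order(sites$chrom, sites$pos, sites$strand), , drop = FALSE]
  lines <- if (nrow(s))
    paste(s$chrom, s$pos - 1L, s$pos, ".", s$coverage, s$strand, sep = "\t")
  else character()
  writeLines(lines, path)
  invisible(path)
}
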