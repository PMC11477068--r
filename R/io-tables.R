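#' Write the per-gene feature table
#'
#' One header line plus one row per gene, tab-separated, sorted by
#' `gene_id`; numeric columns keep full precision (>= 6 significant
#' digits). Duplicate gene ids or an empty table are hard errors.
#'
#' @param rows data.frame of per-gene features (see [feature_rows]).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(rows, path) {
  if (!nrow(rows)) stop("empty feature table")
  if (anyDuplicated(rows$gene_id))
    stop("duplicate gene_id in feature table: ",
         paste(unique(rows$gene_id[duplicated(rows$gene_id)]), collapse = ", "))
  rows <- rows[order(rows$gene_id), , drop = FALSE]
  num <- vapply(rows, is.numeric, TRUE) & !vapply(rows, is.integer, TRUE)
  rows[num] <- lapply(rows[num], function(x) format(x, digits = 15, trim = TRUE))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @return The feature table as a data.frame (for the reader).
#' @export
read_feature_table <- function(path) {
  d <- utils::read.delim(path, header = TRUE,
                         colClasses = c(gene_id = "character"))
  d$gene_id <- as.character(d$gene_id)
  d
}

#' Read a plain-text gene id list (e.g. imprinted genes)
#'
#' One id per line; blank lines and `#` comments are ignored.
#'
#' @param path Text file.
#' @return Character vector of gene ids.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}
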