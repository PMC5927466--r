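# Plain-text readers/writers: TSV matrices (features x samples with a
# header of sample ids), design/annotation tables, BED6 intervals.

#' Write a feature-by-sample matrix as TSV
#'
#' First column `feature_id`, one column per sample, tab-separated.
#'
#' @param x Numeric matrix with row and column names.
#' @param path Output file.
#' @export
write_matrix_tsv <- function(x, path) {
  df <- data.frame(feature_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature-by-sample TSV matrix
#'
#' @param path File written by [write_matrix_tsv()].
#' @return Numeric matrix with feature row names.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write / read a design or annotation table as TSV
#'
#' @param df Data frame.
#' @param path File path.
#' @export
write_table_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table_tsv
#' @export
read_table_tsv <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Write gene annotation as BED6
#'
#' 0-based half-open intervals: chrom, start, end, name, score (0),
#' strand; no header, tab-separated.
#'
#' @param annot A `gene_annotation` data frame.
#' @param path Output file.
#' @export
write_bed6 <- function(annot, path) {
  bed <- data.frame(annot$chrom, annot$start, annot$end, annot$gene_id,
                    0L, annot$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene annotation from BED6
#'
#' @param path BED file written by [write_bed6()].
#' @return A `gene_annotation` data frame.
#' @export
read_bed6 <- function(path) {
  bed <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  annot <- data.frame(gene_id = bed[[4]], chrom = bed[[1]],
                      start = as.integer(bed[[2]]), end = as.integer(bed[[3]]),
                      strand = bed[[6]], stringsAsFactors = FALSE)
  class(annot) <- c("gene_annotation", "data.frame")
  annot
}
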