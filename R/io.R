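# TSV dialects for the expression matrix and the sample-to-group mapping.

#' Write an expression matrix as TSV
#'
#' First column `transcript_id`, remaining columns one per sample (header
#' row = sample ids).
#' @param mat numeric matrix with row and column names.
#' @param path output path.
#' @export
write_expression_tsv <- function(mat, path) {
  out <- data.frame(transcript_id = rownames(mat), mat, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression matrix from TSV
#' @param path TSV written by [write_expression_tsv()].
#' @return numeric matrix, transcripts x samples.
#' @export
read_expression_tsv <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(d[, -1, drop = FALSE])
  rownames(mat) <- d[[1]]
  storage.mode(mat) <- "double"
  if (anyNA(mat)) stop("data error: missing values in expression matrix",
                       call. = FALSE)
  mat
}

#' Write the sample-to-group mapping as a two-column TSV
#' @param groups named vector sample_id -> treatment/control.
#' @param path output path.
#' @export
write_groups_tsv <- function(groups, path) {
  utils::write.table(data.frame(sample_id = names(groups),
                                group = unname(groups)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample-to-group mapping TSV
#' @param path two-column TSV (sample_id, group).
#' @return named character vector.
#' @export
read_groups_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(d$group, d$sample_id)
}
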