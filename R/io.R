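#' Read a numeric matrix from TSV (first column = row ids, header = column
#' ids)
#'
#' @param path tab-separated file.
#' @return numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  m
}

#' Write a numeric matrix to TSV (row ids in a leading `id` column)
#'
#' @param m matrix with dimnames.
#' @param path output file.
#' @param id_col name of the leading id column.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path, id_col = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-column sample label file (`sample_id<TAB>label`)
#'
#' @param path TSV with header; labels must be 0/1.
#' @return named integer vector.
#' @export
read_labels_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(ncol(df) >= 2L)
  lab <- as.integer(df[[2]])
  if (any(!lab %in% c(0L, 1L))) stop("labels must be 0 or 1")
  stats::setNames(lab, as.character(df[[1]]))
}
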