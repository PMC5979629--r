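#' Write a labelled square matrix as CSV
#'
#' Row labels in the first column, column labels in the header; an optional
#' comment line records the row/column semantics (e.g. rows = source).
#'
#' @param M labelled matrix.
#' @param path output path.
#' @param comment optional `# `-prefixed header comment.
#' @export
write_matrix_csv <- function(M, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  df <- data.frame(label = rownames(M), unclass(M), check.names = FALSE)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a labelled square matrix written by [write_matrix_csv()]
#' @param path input path.
#' @return labelled matrix.
#' @export
read_matrix_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  M <- as.matrix(df[, -1, drop = FALSE])
  rownames(M) <- df[[1]]
  M
}
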