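#' Read / write the expression-DE table
#'
#' Plain TSV with header: `gene_id`, `tpm_control`, `log2fc`, `padj`.
#' `log2fc` is knockdown vs control (positive = up in knockdown); this
#' package never fits a differential-expression model, it consumes one.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_expression_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "tpm_control", "log2fc", "padj")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_("expression table %s lacks column(s): %s", path,
          paste(miss, collapse = ", "))
  if (any(df$tpm_control < 0, na.rm = TRUE))
    stop_("expression table %s: negative TPM", path)
  df
}

#' @rdname read_expression_table
#' @param expr expression data.frame.
#' @export
write_expression_table <- function(expr, path) {
  utils::write.table(expr, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname read_splicing_table
#' @param events splicing event data.frame.
#' @param path TSV path.
#' @export
write_splicing_table <- function(events, path) {
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
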