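# Plain-text serialization for the pipeline's stage outputs.

#' Read / write beta matrices as TSV
#'
#' Rows are CpGs (first column `cpg_id`), remaining columns are samples.
#'
#' @param beta CpG x sample matrix.
#' @param path File path.
#' @return `write_beta_tsv()` returns `path` invisibly; `read_beta_tsv()` a
#'   numeric matrix with dimnames.
#' @export
write_beta_tsv <- function(beta, path) {
  df <- tibble::as_tibble(beta, rownames = "cpg_id")
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_beta_tsv
#' @export
read_beta_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Read a probe blocklist (one CpG id per line)
#' @param path File path.
#' @return Character vector of CpG ids.
#' @export
read_blocklist <- function(path) {
  ids <- readr::read_lines(path)
  ids[nzchar(trimws(ids))]
}
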