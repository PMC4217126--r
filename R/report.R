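#' Write a result table as deterministic tab-delimited text
#'
#' All package reports go through this writer: columns in their given order,
#' tab separated, no quoting, numeric columns rendered with
#' `sprintf("%.10g")` so that a written table re-reads to the formatted
#' precision and two identical tables produce byte-identical files.
#'
#' @param table a data frame with named columns (zero rows allowed).
#' @param path output path.
#' @export
write_report <- function(table, path) {
  if (!is.data.frame(table)) stop("'table' must be a data frame")
  if (is.null(names(table)) || any(!nzchar(names(table))))
    stop("'table' must have named columns")
  out <- table
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.10g", out[[j]])
    else out[[j]] <- as.character(out[[j]])
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(out), collapse = "\t"), con)
  if (nrow(out))
    writeLines(do.call(paste, c(unname(as.list(out)), sep = "\t")), con)
  invisible(NULL)
}

#' Read a table written by [write_report()]
#'
#' @param path file path.
#' @return a data frame with `check.names = FALSE`.
#' @export
read_report <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}
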