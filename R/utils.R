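# small shared helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

#' Read a tab-separated table
#'
#' Thin wrapper over [utils::read.delim()] with the conventions used by all
#' panprobio file formats: tab separator, no quoting, strings kept as
#' character, `#`-comment lines ignored.
#'
#' @param path file path.
#' @param ... passed on to [utils::read.delim()].
#' @return a `data.frame`.
#' @export
read_tsv_file <- function(path, ...) {
  utils::read.delim(path, sep = "\t", quote = "", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}

#' Write a tab-separated table
#'
#' @param x data.frame or matrix.
#' @param path output path.
#' @param row_names write row names as a first column? Default `FALSE`.
#' @return `path`, invisibly.
#' @export
write_tsv_file <- function(x, path, row_names = FALSE) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = row_names, col.names = TRUE)
  invisible(path)
}
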