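#' @keywords internal
"_PACKAGE"

#' @importFrom stats dhyper pbinom pchisq rnorm runif rnbinom rpois chisq.test
#'   fisher.test setNames quantile
#' @importFrom utils read.table write.table packageVersion
NULL

# Stop unless `cond` holds; `...` is a sprintf-style message.
.assert <- function(cond, ...) {
  if (!isTRUE(cond)) stop(sprintf(...), call. = FALSE)
  invisible(TRUE)
}

.is_count <- function(x) is.numeric(x) && all(is.finite(x)) && all(x >= 0) &&
  all(x == floor(x))

# Tab-separated writer used for all on-disk tables.
.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

.read_tsv <- function(path, ...) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE, ...)
}
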