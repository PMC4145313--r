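#' @keywords internal
"_PACKAGE"

#' @importFrom stats median ks.test wilcox.test cor p.adjust phyper dhyper
#'   rbinom rpois runif rlnorm rmultinom rnorm quantile sd hclust cutree dist
#'   setNames cor.test
#' @importFrom utils read.delim write.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a child seed from a master seed
#'
#' Deterministic seed chaining used everywhere randomness is split across
#' replicates or samples; keeps derived seeds inside the 32-bit integer
#' range R requires.
#'
#' @param seed master seed (single integer).
#' @param index non-negative offset (replicate or sample index).
#' @return a single integer seed.
#' @export
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index)) %% 2147483647L)
}

#' Median with the even-count rule stated throughout the package
#'
#' For an even number of values the arithmetic mean of the two central
#' values is returned (the convention of [stats::median()]).
#' @param x numeric vector.
#' @return median value.
#' @export
median_rule <- function(x) {
  if (length(x) == 0L) stop("median of an empty vector is undefined")
  stats::median(x)
}

## TSV writers: deterministic column order, no quoting, unix newlines --
## results must be byte-identical across runs with the same seed.
write_tsv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(colnames(df), collapse = "\t"), con)
  if (nrow(df)) {
    cells <- vapply(df, function(col) {
      if (is.numeric(col)) format(col, digits = 15, trim = TRUE, scientific = FALSE)
      else as.character(col)
    }, character(nrow(df)))
    if (nrow(df) == 1L) cells <- matrix(cells, nrow = 1L)
    writeLines(apply(cells, 1L, paste, collapse = "\t"), con)
  }
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}
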