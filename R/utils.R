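#' @importFrom methods new validObject is
#' @importFrom stats rnorm runif p.adjust aov TukeyHSD wilcox.test
#'   kruskal.test setNames ks.test
#' @importFrom utils read.table write.table
NULL

# run `expr` under a temporary RNG state seeded with `seed`
.withSeed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

.assertCount <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x))
    stop(sprintf("'%s' must be a single integer >= %d", name, min), call. = FALSE)
  as.integer(x)
}

.assertFraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("'%s' must be a single value in [0, 1]", name), call. = FALSE)
  as.numeric(x)
}

#' Write a data frame as tab-separated text
#'
#' Thin wrapper around [utils::write.table()] with the conventions used for
#' all tabular outputs of this package: tab separator, no quoting, no row
#' names, `NA` written as `NA`.
#'
#' @param x A data frame.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
writeTsv <- function(x, path) {
  stopifnot(is.data.frame(x))
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tab-separated table
#'
#' @param path File path.
#' @return A data frame with character columns left as-is.
#' @export
readTsv <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             check.names = FALSE)
}
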