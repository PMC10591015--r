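#' @importFrom stats approx cor lm median nls coef p.adjust pnorm pt quantile
#'   rbinom rlnorm rnbinom rnorm rpois runif sd setNames var wilcox.test
#' @importFrom utils read.table write.table packageVersion
NULL

# Counter-based seed expansion: a stable stream per (seed, index) so that
# adding genes/samples never reshuffles draws for existing ones.
# Keeps derived seeds strictly inside the 32-bit signed range.
derive_seed <- function(seed, index) {
  s <- (as.double(seed) %% 2147483647) * 48271 + as.double(index) * 1664525 + 1013904223
  as.integer(s %% 2147483646) + 1L
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Deterministic TSV writers: fixed column order, no quoting surprises,
# so repeated runs are byte-identical.
write_tsv_det <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv_det <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE, check.names = FALSE)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
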