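# internal helpers

# Derive a child seed from a master seed; keeps results < 2^31 and distinct
# per stage/offset so one pipeline seed fans out reproducibly.
deriveSeed <- function(seed, offset = 0L) {
  # all arithmetic in double space (exact below 2^53), reduced before the
  # integer cast so chained derivations cannot overflow
  as.integer(((as.double(seed) %% 2147483647) * 48271 +
                1000003 * (as.double(offset) + 1)) %% 2147483647)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Column-wise Z-score; zero-variance columns become all-zero.
zscoreColumns <- function(m) {
  m <- as.matrix(m)
  mu <- colMeans(m)
  sdv <- apply(m, 2, stats::sd)
  sdv[sdv == 0] <- 1
  sweep(sweep(m, 2, mu, "-"), 2, sdv, "/")
}

writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

readTsv <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
}
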