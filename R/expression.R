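# RNA-seq counts -> filtered, replicate-averaged FPKM (the regression Y),
# plus the unit-norm cross-condition normalization used before clustering.

#' Filter genes by a minimum read count in every sample
#'
#' Keeps genes detected with at least \code{minReads} reads in all samples
#' across all conditions and replicates (default 1: one zero anywhere drops
#' the gene). \code{minReads = 0} is the identity filter.
#'
#' @param et An \linkS4class{ExpressionTable}.
#' @param minReads Minimum count required in every sample.
#' @return The filtered \linkS4class{ExpressionTable} (FPKM slot reset).
#' @export
filterMinCount <- function(et, minReads = 1) {
  keep <- rowSums(et@counts >= minReads) == ncol(et@counts)
  new("ExpressionTable",
      counts = et@counts[keep, , drop = FALSE],
      geneLengths = et@geneLengths[keep],
      conditions = et@conditions, replicates = et@replicates)
}

#' Compute per-condition FPKM from counts
#'
#' FPKM of gene g in sample s is count_gs * 1e9 / (libsize_s * length_g),
#' where libsize_s is the column sum of the (already filtered) counts.
#' Per-condition FPKM is the mean over that condition's replicates.
#'
#' @param et A filtered \linkS4class{ExpressionTable}.
#' @return The table with the genes x conditions \code{fpkm} slot filled.
#' @export
computeFpkm <- function(et) {
  lib <- colSums(et@counts)
  if (any(lib == 0)) stopf("zero library size in sample(s): %s",
                           paste(which(lib == 0), collapse = ", "))
  perSample <- sweep(et@counts, 2, lib, "/") * 1e9 / et@geneLengths
  conds <- unique(et@conditions)
  f <- vapply(conds, function(cn)
    rowMeans(perSample[, et@conditions == cn, drop = FALSE]),
    numeric(nrow(et@counts)))
  f <- matrix(f, nrow = nrow(et@counts),
              dimnames = list(rownames(et@counts), conds))
  initialize(et, fpkm = f)
}

#' Scale each gene's cross-condition profile to unit sum of squares
#'
#' Divides every row by its Euclidean norm, so rows differ only in the
#' *shape* of their expression change across conditions, not its magnitude.
#' All-zero rows cannot be normalized and are dropped with a warning.
#'
#' @param m Genes x conditions matrix (e.g. the FPKM slot).
#' @return Matrix with unit-sum-of-squares rows.
#' @export
sumOfSquaresNormalize <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) < 2L) stopf("need at least 2 conditions to normalize across")
  norms <- sqrt(rowSums(m^2))
  zero <- norms == 0
  if (any(zero)) {
    warnf("dropping %d all-zero gene row(s) before normalization", sum(zero))
    m <- m[!zero, , drop = FALSE]
    norms <- norms[!zero]
  }
  m / norms
}
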