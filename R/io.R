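# Plain-text readers/writers: TSS tables, signal matrices, count tables,
# GEM-like peak lists, GMT-like gene-set collections. All tab-separated,
# UTF-8, one header line.

#' Read a BED-like TSS annotation table
#'
#' Expects tab-separated columns chrom, tss, gene_id, strand (header line).
#'
#' @param path File path.
#' @return data.frame(chrom, tss, gene_id, strand).
#' @export
readTss <- function(path) {
  df <- readTsv(path)
  need <- c("chrom", "tss", "gene_id", "strand")
  if (!all(need %in% names(df)))
    stopf("TSS table %s must have columns %s", path, paste(need, collapse = ", "))
  df <- df[need]
  df$tss <- as.integer(df$tss)
  if (any(df$tss < 1)) stopf("TSS coordinates must be >= 1 (1-based)")
  if (!all(df$strand %in% c("+", "-"))) stopf("strand must be '+' or '-'")
  if (anyDuplicated(df$gene_id)) stopf("duplicate gene ids in TSS table")
  df
}

#' @rdname readTss
#' @param tss data.frame(chrom, tss, gene_id, strand).
#' @export
writeTss <- function(tss, path) writeTsv(tss[c("chrom", "tss", "gene_id", "strand")], path)

#' Read/write a PromoterSignalMatrix as TSV
#'
#' Layout: header \code{gene_id} then one column per TF; one row per gene.
#'
#' @param path File path.
#' @param condition,window,representation Metadata recorded on read.
#' @return A \linkS4class{PromoterSignalMatrix}.
#' @export
readSignalMatrix <- function(path, condition = "unknown", window = c(500, 500),
                             representation = "promoter_sum") {
  df <- readTsv(path)
  if (names(df)[1] != "gene_id") stopf("first column of %s must be gene_id", path)
  m <- as.matrix(df[-1])
  rownames(m) <- df$gene_id
  new("PromoterSignalMatrix", signal = m, condition = condition,
      window = window, representation = representation)
}

#' @rdname readSignalMatrix
#' @param psm A \linkS4class{PromoterSignalMatrix}.
#' @export
writeSignalMatrix <- function(psm, path) {
  m <- signalMatrix(psm)
  writeTsv(data.frame(gene_id = rownames(m), m, check.names = FALSE), path)
}

#' Read an RNA-seq counts table into an ExpressionTable
#'
#' Layout: columns \code{gene_id}, \code{length_bp}, then one column per
#' sample named \code{condition.replicate} (e.g. \code{glucose.1}).
#'
#' @param path File path.
#' @return An \linkS4class{ExpressionTable}.
#' @export
readCountsTable <- function(path) {
  df <- readTsv(path)
  if (!all(c("gene_id", "length_bp") %in% names(df)[1:2]))
    stopf("counts table %s must start with gene_id, length_bp", path)
  samples <- names(df)[-(1:2)]
  if (length(samples) == 0L) stopf("counts table %s has no sample columns", path)
  parts <- regmatches(samples, regexpr("\\.[^.]*$", samples))
  conds <- sub("\\.[^.]*$", "", samples)
  reps <- sub("^\\.", "", parts)
  if (any(!nzchar(conds)) || any(!nzchar(reps)))
    stopf("sample columns must be named condition.replicate")
  m <- as.matrix(df[-(1:2)])
  rownames(m) <- df$gene_id
  new("ExpressionTable", counts = m, geneLengths = as.numeric(df$length_bp),
      conditions = conds, replicates = reps)
}

#' @rdname readCountsTable
#' @param et An \linkS4class{ExpressionTable}.
#' @export
writeCountsTable <- function(et, path) {
  m <- countsMatrix(et)
  colnames(m) <- paste(et@conditions, et@replicates, sep = ".")
  writeTsv(data.frame(gene_id = rownames(m), length_bp = et@geneLengths, m,
                      check.names = FALSE), path)
}

#' Read a GEM-like peak list (chrom, position, signal TSV)
#'
#' @param path File path.
#' @return data.frame(chrom, position, signal, local_noise, snr, gene_id);
#'   missing noise columns are filled so downstream thresholds still apply
#'   (snr defaults to Inf: a pre-filtered external peak list passes through).
#' @export
readPeaks <- function(path) {
  df <- readTsv(path)
  if (!all(c("chrom", "position", "signal") %in% names(df)))
    stopf("peak list %s needs columns chrom, position, signal", path)
  if (is.null(df$local_noise)) df$local_noise <- NA_real_
  if (is.null(df$snr))
    df$snr <- ifelse(!is.na(df$local_noise) & df$local_noise > 0,
                     df$signal / df$local_noise, Inf)
  if (is.null(df$gene_id)) df$gene_id <- NA_character_
  df[c("chrom", "position", "signal", "local_noise", "snr", "gene_id")]
}

#' Read a GMT-like gene-set collection
#'
#' Each line: set name, description, then tab-separated member gene ids.
#'
#' @param path File path.
#' @return Named list of character vectors (the description is dropped).
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t"), function(f) {
    if (length(f) < 3L) stopf("GMT line needs name, description, >=1 member")
    unique(f[-(1:2)])
  })
  names(sets) <- vapply(strsplit(lines, "\t"), `[[`, "", 1L)
  if (anyDuplicated(names(sets))) stopf("duplicate set names in %s", path)
  sets
}
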