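#' Read a WIG coverage file into a CoverageTrack
#'
#' Supports the fixedStep and variableStep dialects (span >= 1). Positions
#' never declared by the file are filled with 0; a position declared twice
#' (overlapping blocks) is an error. Chromosome vectors extend to the last
#' covered base unless longer lengths are supplied.
#'
#' @param path Path to a .wig file.
#' @param chromLengths Optional named vector of chromosome lengths to pad to.
#' @return A \linkS4class{CoverageTrack}.
#' @export
readWig <- function(path, chromLengths = NULL) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines) & !grepl("^(track|browser)\\b", lines)
  lineNo <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stopf("empty WIG file: %s", path)

  isHeader <- grepl("^(fixedStep|variableStep)\\b", lines)
  if (!isHeader[1])
    stopf("WIG parse error at line %d: data before any step declaration", lineNo[1])

  parseAttrs <- function(header, i) {
    kv <- regmatches(header, gregexpr("[A-Za-z]+=[^ \t]+", header))[[1]]
    a <- sub("=.*", "", kv)
    v <- sub("^[^=]+=", "", kv)
    out <- as.list(v); names(out) <- a
    if (is.null(out$chrom)) stopf("WIG parse error at line %d: missing chrom=", i)
    out
  }

  # per chromosome: positions and values accumulated, duplicates checked at end
  pos <- list(); val <- list()
  starts <- which(isHeader)
  ends <- c(starts[-1] - 1L, length(lines))
  for (b in seq_along(starts)) {
    hi <- starts[b]
    header <- lines[hi]
    at <- parseAttrs(header, lineNo[hi])
    chrom <- at$chrom
    span <- if (is.null(at$span)) 1L else as.integer(at$span)
    if (is.na(span) || span < 1) stopf("WIG parse error at line %d: bad span", lineNo[hi])
    body <- if (ends[b] >= hi + 1L) lines[(hi + 1L):ends[b]] else character(0)
    if (startsWith(header, "fixedStep")) {
      if (is.null(at$start) || is.null(at$step))
        stopf("WIG parse error at line %d: fixedStep needs start= and step=", lineNo[hi])
      start <- as.integer(at$start); step <- as.integer(at$step)
      if (is.na(start) || start < 1 || is.na(step) || step < 1)
        stopf("WIG parse error at line %d: bad start/step", lineNo[hi])
      v <- suppressWarnings(as.numeric(body))
      if (anyNA(v))
        stopf("WIG parse error at line %d: non-numeric value",
              lineNo[hi + which(is.na(v))[1]])
      p0 <- start + step * (seq_along(v) - 1L)
    } else {
      flds <- strsplit(body, "[ \t]+")
      ok <- lengths(flds) == 2L
      if (any(!ok))
        stopf("WIG parse error at line %d: variableStep lines need 'pos value'",
              lineNo[hi + which(!ok)[1]])
      m <- matrix(suppressWarnings(as.numeric(unlist(flds))), ncol = 2, byrow = TRUE)
      if (anyNA(m))
        stopf("WIG parse error at line %d: non-numeric field",
              lineNo[hi + which(apply(is.na(m), 1, any))[1]])
      p0 <- as.integer(m[, 1]); v <- m[, 2]
      if (any(p0 < 1)) stopf("WIG parse error at line %d: position < 1", lineNo[hi])
    }
    if (span > 1L) {
      p0 <- rep(p0, each = span) + rep(0:(span - 1L), times = length(p0))
      v <- rep(v, each = span)
    }
    pos[[chrom]] <- c(pos[[chrom]], list(p0))
    val[[chrom]] <- c(val[[chrom]], list(v))
  }

  cov <- lapply(names(pos), function(chrom) {
    p <- unlist(pos[[chrom]]); v <- unlist(val[[chrom]])
    if (anyDuplicated(p))
      stopf("overlapping WIG declarations on %s (position %d covered twice)",
            chrom, p[duplicated(p)][1])
    len <- max(p)
    if (!is.null(chromLengths) && chrom %in% names(chromLengths))
      len <- max(len, chromLengths[[chrom]])
    out <- numeric(len)
    out[p] <- v
    out
  })
  names(cov) <- names(pos)
  new("CoverageTrack", coverage = cov, meta = list(source = path))
}

#' Write a CoverageTrack as fixedStep (step=1) WIG
#'
#' Lossless round-trip partner of \code{readWig} for dense step-1 tracks.
#'
#' @param track A \linkS4class{CoverageTrack}.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeWig <- function(track, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (chrom in names(track@coverage)) {
    writeLines(sprintf("fixedStep chrom=%s start=1 step=1", chrom), con)
    writeLines(format(track@coverage[[chrom]], trim = TRUE, scientific = FALSE,
                      digits = 15), con)
  }
  invisible(path)
}

#' Average replicate coverage tracks base-by-base
#'
#' Biological replicates are averaged at the track level (before any
#' promoter quantification), giving the per-base arithmetic mean.
#'
#' @param tracks List of \linkS4class{CoverageTrack}s over identical
#'   chromosome sets and lengths.
#' @return A single averaged \linkS4class{CoverageTrack}.
#' @export
averageReplicates <- function(tracks) {
  if (length(tracks) == 0L) stopf("no tracks to average")
  ref <- tracks[[1]]
  refLen <- chromLengths(ref)
  for (t in tracks[-1]) {
    len <- chromLengths(t)
    if (!identical(sort(names(len)), sort(names(refLen))))
      stopf("replicate tracks cover different chromosome sets")
    if (!identical(len[names(refLen)], refLen))
      stopf("replicate tracks have mismatched chromosome lengths")
  }
  cov <- lapply(names(ref@coverage), function(chrom) {
    Reduce(`+`, lapply(tracks, function(t) t@coverage[[chrom]])) / length(tracks)
  })
  names(cov) <- names(ref@coverage)
  new("CoverageTrack", coverage = cov,
      meta = c(ref@meta[setdiff(names(ref@meta), "replicate")],
               list(nReplicates = length(tracks))))
}
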