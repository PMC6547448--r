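# Promoter-window quantification of coverage, the naive peak caller used as
# a stand-in for an event-calling algorithm, peak-to-gene annotation, and
# per-condition target-set overlaps.

# Sum coverage over [tss+startRel, tss+endRel] per gene (+ strand); for -
# strand genes the window is mirrored (position tss-x plays the role of
# tss+x) unless mirror=FALSE. Bases outside the chromosome contribute 0;
# unknown chromosomes give NA with one warning.
windowSumRel <- function(track, tss, startRel, endRel, mirror = TRUE) {
  stopifnot(endRel >= startRel)
  cov <- track@coverage
  out <- rep(NA_real_, nrow(tss))
  names(out) <- tss$gene_id
  unknown <- !(tss$chrom %in% names(cov))
  if (any(unknown))
    warnf("%d gene(s) on chromosomes absent from the track; returning NA",
          sum(unknown))
  for (i in which(!unknown)) {
    v <- cov[[tss$chrom[i]]]
    minus <- mirror && tss$strand[i] == "-"
    lo <- if (minus) tss$tss[i] - endRel else tss$tss[i] + startRel
    hi <- if (minus) tss$tss[i] - startRel else tss$tss[i] + endRel
    lo <- max(1L, lo); hi <- min(length(v), hi)
    out[i] <- if (lo > hi) 0 else sum(v[lo:hi])
  }
  out
}

#' Total promoter read count per gene
#'
#' Sums per-base coverage over the promoter window around each TSS (default
#' TSS -500 to TSS +500, inclusive: 1001 bases). For minus-strand genes the
#' window is mirrored so that "upstream" is biologically 5' of the gene;
#' set \code{mirror = FALSE} for strand-agnostic windows.
#'
#' @param track A \linkS4class{CoverageTrack} (replicate-averaged).
#' @param tss data.frame with columns chrom, tss, gene_id, strand.
#' @param window Length-2 numeric (upstream_bp, downstream_bp), both >= 0.
#' @param mirror Mirror windows on minus-strand genes (default TRUE).
#' @return Named numeric vector of per-gene promoter sums (NA for genes on
#'   chromosomes the track does not cover).
#' @export
promoterSum <- function(track, tss, window = c(500, 500), mirror = TRUE) {
  if (length(window) != 2L || any(window < 0))
    stopf("window must be two non-negative lengths (upstream, downstream)")
  windowSumRel(track, tss, -window[1], window[2], mirror = mirror)
}

movingAverage <- function(v, k) {
  if (k <= 1L) return(v)
  csum <- cumsum(c(0, v))
  n <- length(v)
  half <- (k - 1L) %/% 2L
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (csum[hi + 1L] - csum[lo]) / (hi - lo + 1L)
}

#' Naive SNR-thresholded peak detection (event-caller stand-in)
#'
#' Finds local maxima of lightly smoothed coverage, estimates the local
#' genomic noise as the median raw coverage in the flanking windows around
#' the peak span, and keeps peaks whose signal-to-noise ratio strictly
#' exceeds \code{minSnr} (the ">2-fold over local noise" convention).
#'
#' @param track A \linkS4class{CoverageTrack}.
#' @param minSnr Peaks kept when snr > minSnr (strict; default 2).
#' @param noiseWindowBp Total flanking span used for the noise median
#'   (default 2000; half on each side of the peak).
#' @param smoothBp Moving-average width before maxima detection (default 5).
#' @param minSignal Candidate floor on smoothed summit height (default 0);
#'   raise on noisy tracks so single-read background maxima are not scored.
#' @return data.frame(chrom, position, signal, local_noise, snr, gene_id)
#'   with gene_id all NA (see \code{annotatePeaks}); zero rows for flat or
#'   all-zero tracks.
#' @export
detectPeaks <- function(track, minSnr = 2, noiseWindowBp = 2000,
                        smoothBp = 5, minSignal = 0) {
  if (noiseWindowBp <= 0) stopf("noiseWindowBp must be > 0")
  res <- list()
  for (chrom in names(track@coverage)) {
    raw <- track@coverage[[chrom]]
    if (all(raw == 0)) next
    sm <- movingAverage(raw, smoothBp)
    r <- rle(sm)
    nr <- length(r$values)
    if (nr < 2L) next  # flat chromosome: no local maxima
    endsIdx <- cumsum(r$lengths)
    startsIdx <- endsIdx - r$lengths + 1L
    prev <- c(-Inf, r$values[-nr])
    nxt <- c(r$values[-1], -Inf)
    isMax <- r$values > prev & r$values > nxt & r$values > 0 &
      r$values >= minSignal
    for (j in which(isMax)) {
      summit <- (startsIdx[j] + endsIdx[j]) %/% 2L
      h <- r$values[j]
      # peak span: contiguous region with smoothed coverage >= half height
      lo <- startsIdx[j]; hi <- endsIdx[j]
      while (lo > 1L && sm[lo - 1L] >= h / 2) lo <- lo - 1L
      while (hi < length(sm) && sm[hi + 1L] >= h / 2) hi <- hi + 1L
      half <- noiseWindowBp %/% 2L
      flank <- c(seq.int(max(1L, lo - half), lo - 1L),
                 seq.int(hi + 1L, min(length(raw), hi + half)))
      flank <- flank[flank >= 1L & flank <= length(raw)]
      noise <- if (length(flank)) stats::median(raw[flank]) else 0
      signal <- max(raw[lo:hi])
      snr <- if (noise > 0) signal / noise else Inf
      if (snr > minSnr)
        res[[length(res) + 1L]] <- data.frame(
          chrom = chrom, position = summit, signal = signal,
          local_noise = noise, snr = snr, stringsAsFactors = FALSE)
    }
  }
  if (length(res) == 0L)
    return(data.frame(chrom = character(0), position = integer(0),
                      signal = numeric(0), local_noise = numeric(0),
                      snr = numeric(0), gene_id = character(0)))
  out <- do.call(rbind, res)
  out$gene_id <- NA_character_
  out
}

#' Annotate peaks to the nearest TSS within a radius
#'
#' A peak is assigned to a gene when its summit lies within \code{radiusBp}
#' of that gene's TSS (inclusive). When several TSSs qualify the nearest
#' wins; exact distance ties break to the lexicographically smaller gene id.
#' Unassigned peaks keep gene_id NA.
#'
#' @param peaks data.frame from \code{detectPeaks} (or GEM-like TSV).
#' @param tss data.frame(chrom, tss, gene_id, strand).
#' @param radiusBp Annotation radius (default 500).
#' @return The peaks data.frame with gene_id filled in.
#' @export
annotatePeaks <- function(peaks, tss, radiusBp = 500) {
  if (radiusBp < 0) stopf("radiusBp must be >= 0")
  if (nrow(peaks) == 0L) return(peaks)
  peaks$gene_id <- NA_character_
  for (chrom in unique(peaks$chrom)) {
    tc <- tss[tss$chrom == chrom, , drop = FALSE]
    if (nrow(tc) == 0L) next
    pIdx <- which(peaks$chrom == chrom)
    for (i in pIdx) {
      d <- abs(tc$tss - peaks$position[i])
      ok <- d <= radiusBp
      if (!any(ok)) next
      cand <- tc$gene_id[ok][order(d[ok], tc$gene_id[ok])]
      peaks$gene_id[i] <- cand[1]
    }
  }
  peaks
}

#' Per-gene coverage sum in windows around annotated peaks
#'
#' Sums coverage over [summit - halfwidthBp, summit + halfwidthBp] for every
#' annotated peak of a gene; where windows of the same gene overlap, each
#' base is counted once. Genes without annotated peaks get 0.
#'
#' @param track A \linkS4class{CoverageTrack}.
#' @param peaks Annotated peaks data.frame (gene_id filled in).
#' @param genes Character vector of gene ids defining the output universe.
#' @param halfwidthBp Half-width of the peak window (default 50).
#' @return Named numeric vector over \code{genes}.
#' @export
peakWindowSum <- function(track, peaks, genes, halfwidthBp = 50) {
  out <- stats::setNames(numeric(length(genes)), genes)
  pk <- peaks[!is.na(peaks$gene_id) & peaks$gene_id %in% genes, , drop = FALSE]
  if (nrow(pk) == 0L) return(out)
  for (g in unique(pk$gene_id)) {
    rows <- pk[pk$gene_id == g, , drop = FALSE]
    total <- 0
    for (chrom in unique(rows$chrom)) {
      v <- track@coverage[[chrom]]
      if (is.null(v)) next
      posIdx <- unique(unlist(lapply(rows$position[rows$chrom == chrom],
                                     function(p) seq.int(max(1L, p - halfwidthBp),
                                                         min(length(v), p + halfwidthBp)))))
      total <- total + sum(v[posIdx])
    }
    out[g] <- total
  }
  out
}

#' Per-gene summed peak signal (SNR-thresholded representation)
#'
#' The sparsest binding representation: the sum of summit signals of a
#' gene's annotated peaks that pass the SNR threshold.
#'
#' @param peaks Annotated peaks data.frame.
#' @param genes Gene universe for the output vector.
#' @param minSnr Strict SNR threshold applied before summing (default 2).
#' @return Named numeric vector over \code{genes}.
#' @export
peakSignalSum <- function(peaks, genes, minSnr = 2) {
  out <- stats::setNames(numeric(length(genes)), genes)
  pk <- peaks[!is.na(peaks$gene_id) & peaks$snr > minSnr &
                peaks$gene_id %in% genes, , drop = FALSE]
  if (nrow(pk) == 0L) return(out)
  agg <- tapply(pk$signal, pk$gene_id, sum)
  out[names(agg)] <- as.numeric(agg)
  out
}

#' Per-condition target sets and their exact overlap counts
#'
#' The target set of a condition is the set of genes with at least one
#' annotated peak passing the SNR threshold. Overlaps are exclusive
#' (Euler-style) region counts: for every non-empty combination of
#' conditions, the number of genes targeted in exactly those conditions.
#'
#' @param x Named list per condition: either a character vector of target
#'   genes, or an annotated peaks data.frame (filtered with \code{minSnr}).
#' @param minSnr SNR threshold when peak data.frames are supplied.
#' @return list(targets = per-condition gene sets,
#'   overlaps = named integer vector keyed "condA&condB&...").
#' @export
conditionTargets <- function(x, minSnr = 2) {
  if (length(x) < 1L) stopf("need at least one condition")
  targets <- lapply(x, function(el) {
    if (is.data.frame(el))
      unique(el$gene_id[!is.na(el$gene_id) & el$snr > minSnr])
    else unique(as.character(el))
  })
  conds <- names(targets)
  allGenes <- unique(unlist(targets))
  member <- vapply(targets, function(s) allGenes %in% s,
                   logical(length(allGenes)))
  if (length(allGenes) == 1L) member <- matrix(member, nrow = 1)
  overlaps <- integer(0)
  for (mask in seq_len(2^length(conds) - 1L)) {
    inSet <- as.logical(bitwAnd(mask, 2^(seq_along(conds) - 1L)))
    key <- paste(conds[inSet], collapse = "&")
    if (length(allGenes) == 0L) { overlaps[key] <- 0L; next }
    hit <- rowSums(member[, inSet, drop = FALSE]) == sum(inSet) &
      rowSums(member[, !inSet, drop = FALSE]) == 0L
    overlaps[key] <- sum(hit)
  }
  list(targets = targets, overlaps = overlaps)
}
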