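# Synthetic data with known ground truth: log-normal promoter binding with
# copula-induced collinear pairs, expression from linear/hinge/saturating
# TF effects plus an optional multiplicative interaction, pseudo-counts that
# invert the FPKM formula exactly, and coverage tracks with rectangular
# read pileups over Poisson background.

# Latent Gaussian correlation that yields Pearson correlation rho between
# two log-normal margins with common sdlog s: inverts
# corr(e^{sZ1}, e^{sZ2}) = (e^{s^2 rho_l} - 1)/(e^{s^2} - 1).
latentRho <- function(rho, sdlog) {
  s2 <- sdlog^2
  rl <- log(1 + rho * (exp(s2) - 1)) / s2
  if (is.nan(rl) || rl < -1 || rl > 1)
    stopf("target correlation %.3g is not achievable for log-normal margins with sdlog %.3g",
          rho, sdlog)
  rl
}

geneIds <- function(n) sprintf("g%04d", seq_len(n))
tfIds <- function(p) sprintf("TF%02d", seq_len(p))

#' Generate a promoter binding matrix under a synthetic truth
#'
#' Binding signals are log-normal (heavy-tailed, like promoter read-count
#' sums); designated collinear pairs are induced through a Gaussian copula
#' on the log scale with the latent correlation calibrated analytically so
#' the empirical Pearson correlation of the binding values hits the target.
#'
#' @param truth A \linkS4class{SyntheticTruth}.
#' @param condition Condition label (must be one of truth's conditions);
#'   each condition gets an independent seeded draw.
#' @return A \linkS4class{PromoterSignalMatrix}.
#' @export
generateBindingMatrix <- function(truth, condition = truth@conditions[1]) {
  validObject(truth)
  ci <- match(condition, truth@conditions)
  if (is.na(ci)) stopf("unknown condition '%s'", condition)
  n <- truth@nGenes; p <- truth@nTfs
  set.seed(deriveSeed(truth@seed, 10L + ci))
  Z <- matrix(stats::rnorm(n * p), n, p)
  cp <- truth@collinearPairs
  for (i in seq_len(nrow(cp))) {
    rl <- latentRho(cp$rho[i], truth@bindingSdlog)
    Z[, cp$b[i]] <- rl * Z[, cp$a[i]] + sqrt(1 - rl^2) * Z[, cp$b[i]]
  }
  X <- exp(truth@bindingMeanlog + truth@bindingSdlog * Z)
  dimnames(X) <- list(geneIds(n), tfIds(p))
  new("PromoterSignalMatrix", signal = X, condition = condition,
      window = c(500, 500), representation = "promoter_sum")
}

# Deterministic part of the generative model: intercept + per-TF shape
# contributions + optional multiplicative interaction.
generativeMean <- function(truth, X) {
  mu <- rep(truth@intercept, nrow(X))
  for (i in seq_along(truth@activeTfs)) {
    tf <- truth@activeTfs[i]
    x <- X[, tf]
    t1 <- truth@knots[i]
    si <- match(tf, truth@saturationTfs)
    contrib <- if (!is.na(si)) {
      t2 <- truth@saturationKnots[si]
      lo <- if (is.na(t1)) 0 else t1
      pmin(pmax(x - lo, 0), t2 - lo)
    } else if (is.na(t1)) x else pmax(x - t1, 0)
    mu <- mu + truth@coefficients[i] * contrib
  }
  ip <- truth@interactionPair
  if (length(ip) > 0) mu <- mu + ip$gamma * X[, ip$a] * X[, ip$b]
  mu
}

#' Generate expression (FPKM-scale response) from a binding matrix
#'
#' Y_i = b0 + sum_k f_k(X_ki) + gamma * X_ai * X_bi + eps_i, where f_k is
#' linear, hinge (max(0, x - t)) or saturating (a hinge that flattens above
#' a second knot) per the truth, and eps ~ Normal(0, noiseSd). Negative
#' values are clipped to 0 (they become undetected pseudo-counts downstream).
#'
#' @param truth The \linkS4class{SyntheticTruth} the binding was drawn under.
#' @param binding The matching \linkS4class{PromoterSignalMatrix}.
#' @return Named numeric vector: the condition's response on the FPKM scale.
#' @export
generateExpression <- function(truth, binding) {
  X <- signalMatrix(binding)
  if (nrow(X) != truth@nGenes || ncol(X) != truth@nTfs)
    stopf("dimension mismatch between truth (%d x %d) and binding (%d x %d)",
          truth@nGenes, truth@nTfs, nrow(X), ncol(X))
  ci <- match(binding@condition, truth@conditions)
  if (is.na(ci)) stopf("binding condition '%s' not in truth", binding@condition)
  mu <- generativeMean(truth, X)
  set.seed(deriveSeed(truth@seed, 100L + ci))
  eps <- stats::rnorm(length(mu), 0, truth@noiseSd)
  stats::setNames(pmax(mu + eps, 0), rownames(X))
}

#' Build a coverage track from rectangular read pileups plus background
#'
#' Each peak is a rectangular pileup of the stated height covering
#' \code{width} bases starting at (TSS + offset - width %/% 2); background
#' is independent per-base Poisson noise. The promoter-window sum of a
#' noise-free track is therefore the analytic sum of the pileups
#' overlapping the window.
#'
#' @param tss TSS table (chrom, tss, gene_id, strand).
#' @param offsets Named list (gene_id -> numeric offsets relative to the
#'   TSS, genomic orientation) or a single numeric vector parallel to tss.
#' @param heights Same shape as offsets: read-count height per pileup.
#' @param width Pileup width in bp (default 10).
#' @param backgroundRate Poisson reads/bp (default 0).
#' @param chromLengths Optional named lengths; default pads 2500 bp past
#'   the last TSS.
#' @param seed Seed for the background noise.
#' @return A \linkS4class{CoverageTrack} with the pileup table in its meta.
#' @export
generateCoverageTrack <- function(tss, offsets, heights, width = 10,
                                  backgroundRate = 0, chromLengths = NULL,
                                  seed = 1) {
  if (backgroundRate < 0) stopf("backgroundRate must be >= 0")
  if (!is.list(offsets)) offsets <- as.list(stats::setNames(offsets, tss$gene_id))
  if (!is.list(heights)) heights <- as.list(stats::setNames(heights, tss$gene_id))
  if (any(unlist(heights) < 0)) stopf("peak heights must be >= 0")
  if (any(abs(unlist(offsets)) > 2000)) stopf("peak offsets must lie within 2000 bp of the TSS")
  if (is.null(chromLengths)) {
    chromLengths <- tapply(tss$tss, tss$chrom, function(p) max(p) + 2500L)
    chromLengths <- stats::setNames(as.integer(chromLengths), names(chromLengths))
  }
  set.seed(seed)
  cov <- lapply(names(chromLengths), function(ch) {
    L <- chromLengths[[ch]]
    if (backgroundRate > 0) as.numeric(stats::rpois(L, backgroundRate)) else numeric(L)
  })
  names(cov) <- names(chromLengths)
  pileups <- list()
  for (i in seq_len(nrow(tss))) {
    g <- tss$gene_id[i]; ch <- tss$chrom[i]
    off <- offsets[[g]]; h <- heights[[g]]
    if (is.null(off) || length(off) == 0L) next
    if (length(h) != length(off)) stopf("offsets/heights mismatch for gene %s", g)
    for (j in seq_along(off)) {
      center <- tss$tss[i] + off[j]
      lo <- max(1L, as.integer(center) - width %/% 2L)
      hi <- min(length(cov[[ch]]), lo + width - 1L)
      if (lo <= hi) cov[[ch]][lo:hi] <- cov[[ch]][lo:hi] + h[j]
      pileups[[length(pileups) + 1L]] <- data.frame(
        gene_id = g, chrom = ch, center = as.integer(center),
        height = h[j], width = width, stringsAsFactors = FALSE)
    }
  }
  new("CoverageTrack", coverage = cov,
      meta = list(pileups = if (length(pileups)) do.call(rbind, pileups)
                  else NULL,
                  backgroundRate = backgroundRate))
}

# Convert one condition's response into pseudo-counts that invert the FPKM
# formula at a fixed library size: counts = y * L * len / 1e9, with the
# response rescaled so the counts of detected (>= minReads) genes sum
# exactly to L. Returns the scaled response and the counts.
pseudoCounts <- function(y, lengths, libSize = 1e7, minReads = 1,
                         maxIter = 10L) {
  detected <- y > 0
  scale <- 1
  for (it in seq_len(maxIter)) {
    denom <- sum(y[detected] * lengths[detected])
    if (denom == 0) stopf("no detected genes; response is all zero")
    scale <- 1e9 / denom
    counts <- y * scale * libSize * lengths / 1e9
    newDetected <- counts >= minReads
    if (identical(newDetected, detected)) break
    detected <- newDetected
  }
  list(yScaled = y * scale, counts = counts, scale = scale, detected = detected)
}

#' Assemble a complete synthetic bundle under one truth
#'
#' Generates, for every condition: a binding matrix, the matching response,
#' exact-FPKM pseudo-counts (identical RNA replicates; all noise lives in
#' the response), and optionally replicate coverage tracks whose promoter
#' sums recover the binding matrix (one rectangular pileup per gene x TF at
#' a fixed per-gene-per-TF offset, plus Poisson background per replicate).
#'
#' @param truth A \linkS4class{SyntheticTruth}.
#' @param geneSpacing Distance between TSSs along the synthetic genome (bp).
#' @param peakWidth Pileup width for tracks (bp).
#' @param heightScale Track pileup height = binding * heightScale.
#' @param backgroundRate Poisson background (reads/bp) for tracks.
#' @param withTracks Build coverage tracks (memory-heavy at full scale).
#' @param trackReplicates Replicate tracks per TF x condition.
#' @param rnaReplicates RNA-seq replicates per condition.
#' @param libSize Fixed library size for the pseudo-counts.
#' @return A \linkS4class{SyntheticBundle}.
#' @export
makeSyntheticBundle <- function(truth, geneSpacing = 4000, peakWidth = 10,
                                heightScale = 1, backgroundRate = 0.2,
                                withTracks = FALSE, trackReplicates = 2,
                                rnaReplicates = 3, libSize = 1e7) {
  validObject(truth)
  n <- truth@nGenes
  genes <- geneIds(n)
  set.seed(deriveSeed(truth@seed, 1L))
  lengths <- round(stats::runif(n, 500, 5000))
  half <- ceiling(n / 2)
  chrom <- rep(c("chrI", "chrII"), times = c(half, n - half))
  posIdx <- c(seq_len(half), seq_len(n - half))
  tss <- data.frame(chrom = chrom,
                    tss = as.integer(2500 + (posIdx - 1) * geneSpacing),
                    gene_id = genes,
                    strand = rep_len(c("+", "-"), n),
                    stringsAsFactors = FALSE)
  # one fixed upstream offset per gene x TF, shared across conditions
  offsets <- matrix(round(stats::runif(n * truth@nTfs, -300, -50)),
                    n, truth@nTfs, dimnames = list(genes, tfIds(truth@nTfs)))

  binding <- list(); yList <- list(); countsList <- list(); scales <- numeric(0)
  tracks <- list()
  for (cond in truth@conditions) {
    b <- generateBindingMatrix(truth, cond)
    y <- generateExpression(truth, b)
    pc <- pseudoCounts(y, lengths, libSize = libSize)
    binding[[cond]] <- b
    yList[[cond]] <- pc$yScaled
    countsList[[cond]] <- matrix(pc$counts, n, rnaReplicates,
                                 dimnames = list(genes, NULL))
    scales[cond] <- pc$scale
    if (withTracks) {
      X <- signalMatrix(b)
      ci <- match(cond, truth@conditions)
      tracks[[cond]] <- lapply(stats::setNames(nm = colnames(X)), function(tf) {
        ti <- match(tf, colnames(X))
        lapply(seq_len(trackReplicates), function(rep) {
          generateCoverageTrack(
            tss,
            offsets = as.list(stats::setNames(offsets[, tf], genes)),
            heights = as.list(stats::setNames(X[, tf] * heightScale, genes)),
            width = peakWidth, backgroundRate = backgroundRate,
            seed = deriveSeed(truth@seed, 1000L + 97L * ci + 13L * ti + rep))
        })
      })
    }
  }
  counts <- do.call(cbind, countsList)
  conds <- rep(truth@conditions, each = rnaReplicates)
  reps <- rep(as.character(seq_len(rnaReplicates)), times = length(truth@conditions))
  colnames(counts) <- paste(conds, reps, sep = ".")
  et <- new("ExpressionTable", counts = counts, geneLengths = lengths,
            conditions = conds, replicates = reps)
  new("SyntheticBundle", binding = binding, expression = et,
      tracks = tracks, tss = tss, truth = truth,
      meta = list(response = yList, responseScale = scales,
                  geneLengths = stats::setNames(lengths, genes),
                  peakOffsets = offsets, peakWidth = peakWidth,
                  heightScale = heightScale, backgroundRate = backgroundRate,
                  libSize = libSize))
}

#' Serialize / parse a SyntheticTruth as JSON
#'
#' @param truth A \linkS4class{SyntheticTruth}.
#' @param path Output (input) path.
#' @return \code{writeTruth}: the path, invisibly. \code{readTruth}: the
#'   reconstructed \linkS4class{SyntheticTruth}.
#' @export
writeTruth <- function(truth, path) {
  obj <- list(nGenes = truth@nGenes, nTfs = truth@nTfs,
              conditions = truth@conditions,
              activeTfs = truth@activeTfs, coefficients = truth@coefficients,
              knots = truth@knots, saturationTfs = truth@saturationTfs,
              saturationKnots = truth@saturationKnots,
              collinearPairs = truth@collinearPairs,
              interactionPair = truth@interactionPair,
              intercept = truth@intercept, noiseSd = truth@noiseSd,
              bindingMeanlog = truth@bindingMeanlog,
              bindingSdlog = truth@bindingSdlog, seed = truth@seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  invisible(path)
}

#' @rdname writeTruth
#' @export
readTruth <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  cp <- if (is.null(o$collinearPairs) || length(o$collinearPairs) == 0) NULL
        else as.data.frame(o$collinearPairs)
  ip <- if (is.null(o$interactionPair) || length(o$interactionPair) == 0) NULL
        else o$interactionPair
  SyntheticTruth(nGenes = o$nGenes, nTfs = o$nTfs, conditions = o$conditions,
                 activeTfs = o$activeTfs %||% integer(0),
                 coefficients = o$coefficients %||% numeric(0),
                 knots = if (is.null(o$knots)) rep(NA_real_, length(o$activeTfs))
                         else as.numeric(o$knots),
                 saturationTfs = o$saturationTfs %||% integer(0),
                 saturationKnots = o$saturationKnots %||% numeric(0),
                 collinearPairs = cp, interactionPair = ip,
                 intercept = o$intercept, noiseSd = o$noiseSd,
                 bindingMeanlog = o$bindingMeanlog,
                 bindingSdlog = o$bindingSdlog, seed = o$seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a synthetic bundle to disk in the package's plain-text formats
#'
#' Writes tss.tsv, counts.tsv, one binding_<condition>.tsv per condition,
#' truth.json, and (when tracks exist) tracks/<TF>_<condition>_rep<i>.wig.
#'
#' @param bundle A \linkS4class{SyntheticBundle}.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
writeBundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeTss(bundle@tss, file.path(dir, "tss.tsv"))
  writeCountsTable(bundle@expression, file.path(dir, "counts.tsv"))
  for (cond in names(bundle@binding))
    writeSignalMatrix(bundle@binding[[cond]],
                      file.path(dir, sprintf("binding_%s.tsv", cond)))
  writeTruth(bundle@truth, file.path(dir, "truth.json"))
  if (length(bundle@tracks)) {
    tdir <- file.path(dir, "tracks")
    dir.create(tdir, showWarnings = FALSE)
    for (cond in names(bundle@tracks))
      for (tf in names(bundle@tracks[[cond]])) {
        reps <- bundle@tracks[[cond]][[tf]]
        for (i in seq_along(reps))
          writeWig(reps[[i]],
                   file.path(tdir, sprintf("%s_%s_rep%d.wig", tf, cond, i)))
      }
  }
  invisible(dir)
}
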