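# Regulatory diagnostics on top of fitted models: representation comparison,
# TF-importance scores, binding collinearity with substitution testing,
# additive-vs-multiplicative interaction scans, promoter-segment and
# region-extension regressions, and coordinated-trio detection.

#' Signed TF importance scores
#'
#' Importance of a TF = model R2 x relative importance (0..1) x sign of its
#' net effect (+1 activation, -1 repression). The sign comes from the sum
#' over the TF's terms of coefficient x average basis slope, where the
#' average slope of a hinge is the fraction of observations on its active
#' side (signed); a zero net slope falls back to the largest-|coefficient|
#' term with a warning.
#'
#' @param model A fitted \linkS4class{MarsModel}.
#' @param X,y The data the model was fitted on.
#' @param condition,cluster Labels echoed into the result (default "all").
#' @return data.frame(tf, condition, cluster, relative_importance, sign,
#'   score) with |score| <= R2 and signs in {-1, +1}.
#' @export
tfImportance <- function(model, X, y, condition = "all", cluster = "all") {
  X <- as.matrix(X)
  imp <- relativeImportance(model, X, y)
  signs <- vapply(names(imp), function(v) {
    tm <- model@terms[model@terms$variable == v, , drop = FALSE]
    slope <- function(i) {
      x <- X[, v]
      switch(tm$form[i],
             linear = 1,
             hinge_plus = mean(x > tm$knot[i]),
             hinge_minus = -mean(x < tm$knot[i]))
    }
    net <- sum(tm$coefficient * vapply(seq_len(nrow(tm)), slope, 0))
    if (net == 0) {
      warnf("TF %s has zero net slope; sign taken from largest-|coefficient| term", v)
      iMax <- which.max(abs(tm$coefficient))
      net <- tm$coefficient[iMax] * (if (tm$form[iMax] == "hinge_minus") -1 else 1)
    }
    if (net >= 0) 1 else -1
  }, 0)
  data.frame(tf = names(imp), condition = condition, cluster = cluster,
             relative_importance = as.numeric(imp), sign = signs,
             score = model@r2 * as.numeric(imp) * signs,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Pairwise TF binding collinearity with product-moment significance
#'
#' Pearson correlations of TF binding over a gene set, with two-sided
#' p-values from t = r * sqrt((n-2)/(1-r^2)) against t_{n-2}, and
#' significance stars at p < 0.05, < 0.01, < 0.001.
#'
#' @param X A \linkS4class{PromoterSignalMatrix} or genes x TFs matrix.
#' @param genes Optional gene subset (e.g. metabolic genes).
#' @return list(r, p, stars, significant_pairs, n), class "CollinearityReport";
#'   zero-variance TF columns give NA correlations.
#' @export
collinearity <- function(X, genes = NULL) {
  m <- if (is(X, "PromoterSignalMatrix")) signalMatrix(X) else as.matrix(X)
  if (!is.null(genes)) m <- m[genes, , drop = FALSE]
  n <- nrow(m)
  if (n < 3) stopf("need at least 3 genes")
  sds <- apply(m, 2, stats::sd)
  r <- suppressWarnings(stats::cor(m))
  r[sds == 0, ] <- NA_real_; r[, sds == 0] <- NA_real_
  diag(r) <- ifelse(sds == 0, NA_real_, 1)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-300))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(r) >= 1] <- 0
  diag(p) <- NA_real_
  stars <- matrix(cut(p, breaks = c(-Inf, 0.001, 0.01, 0.05, Inf),
                      labels = c("***", "**", "*", "")),
                  ncol(m), dimnames = dimnames(p))
  ut <- which(upper.tri(p) & !is.na(p) & p < 0.05, arr.ind = TRUE)
  sig <- data.frame(a = colnames(m)[ut[, 1]], b = colnames(m)[ut[, 2]],
                    r = r[ut], p = p[ut], stringsAsFactors = FALSE)
  sig <- sig[order(sig$p, sig$a, sig$b), , drop = FALSE]
  rownames(sig) <- NULL
  structure(list(r = r, p = p, stars = stars, significant_pairs = sig, n = n),
            class = "CollinearityReport")
}

#' @export
print.CollinearityReport <- function(x, ...) {
  cat(sprintf("CollinearityReport: %d TFs over %d genes; %d pair(s) with p < 0.05\n",
              ncol(x$r), x$n, nrow(x$significant_pairs)))
  invisible(x)
}

#' Test whether selected TFs can be substituted by collinear partners
#'
#' For every TF t selected by the base model and every TF u whose binding is
#' significantly correlated with t (p < 0.05) but which was not itself
#' selected, the model is refitted with t excluded from the candidate set;
#' (t, u) is substitutable when u enters the refit's selection — evidence of
#' overlapping regulatory roles hidden by collinearity.
#'
#' @param X Predictor matrix (genes x TFs).
#' @param y Response vector.
#' @param baseModel \linkS4class{MarsModel} from \code{cvSelect} on (X, y).
#' @param report \code{\link{collinearity}} report over the same TFs.
#' @param config,folds,repeats,retainFrac,seed Passed to the refits
#'   (defaults mirror \code{cvSelect}).
#' @return data.frame(excluded, substitute, r, p) of substitutable pairs
#'   (zero rows when the base model selects nothing).
#' @export
substitutionTest <- function(X, y, baseModel, report, config = FitConfig(),
                             folds = 10, repeats = 5, retainFrac = 0.5,
                             seed = 1) {
  X <- as.matrix(X)
  sel <- baseModel@selectedTfs
  out <- data.frame(excluded = character(0), substitute = character(0),
                    r = numeric(0), p = numeric(0), stringsAsFactors = FALSE)
  if (length(sel) == 0L) return(out)
  for (t in sel) {
    partners <- colnames(X)[!is.na(report$p[t, ]) & report$p[t, ] < 0.05]
    partners <- setdiff(partners, c(sel, t))
    if (length(partners) == 0L) next
    refit <- cvSelect(X[, setdiff(colnames(X), t), drop = FALSE], y,
                      config = config, folds = folds, repeats = repeats,
                      retainFrac = retainFrac, seed = seed)
    hits <- intersect(partners, refit@selectedTfs)
    for (u in hits)
      out <- rbind(out, data.frame(excluded = t, substitute = u,
                                   r = report$r[t, u], p = report$p[t, u],
                                   stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Additive vs multiplicative two-TF regressions
#'
#' For every significantly collinear pair, fits y ~ xa + xb (additive) and
#' y ~ xa + xb + xa*xb (multiplicative, raw uncentered product) by OLS and
#' reports the R2 gain. A pair is flagged when the additive R2 exceeds 0.1
#' and the improvement ratio (r2_multiplicative / r2_additive, equivalently
#' (delta_r2 + r2_additive)/r2_additive) is at least 1.10.
#'
#' @param X Predictor matrix (genes x TFs).
#' @param y Response vector.
#' @param report \code{\link{collinearity}} report (its significant pairs
#'   are tested); alternatively a data.frame(a, b) of pairs.
#' @param center Center the TF signals before forming the product (default
#'   FALSE: the raw signal product is the tested interaction).
#' @return data.frame(tf_a, tf_b, r2_additive, r2_multiplicative, delta_r2,
#'   improvement_ratio, flagged).
#' @export
interactionScan <- function(X, y, report, center = FALSE) {
  X <- as.matrix(X)
  pairs <- if (is.data.frame(report)) report else report$significant_pairs
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    a <- pairs$a[i]; b <- pairs$b[i]
    xa <- X[, a]; xb <- X[, b]
    if (center) { xa <- xa - mean(xa); xb <- xb - mean(xb) }
    r2a <- olsFit(cbind(xa, xb), y)$r2
    r2m <- olsFit(cbind(xa, xb, xa * xb), y)$r2
    d <- max(0, r2m - r2a)
    ratio <- if (r2a > 0) (d + r2a) / r2a else NA_real_
    data.frame(tf_a = a, tf_b = b, r2_additive = r2a, r2_multiplicative = r2m,
               delta_r2 = d, improvement_ratio = ratio,
               flagged = isTRUE(r2a > 0.1 && !is.na(ratio) && ratio >= 1.10),
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(tf_a = character(0), tf_b = character(0),
               r2_additive = numeric(0), r2_multiplicative = numeric(0),
               delta_r2 = numeric(0), improvement_ratio = numeric(0),
               flagged = logical(0))
  rownames(out) <- NULL
  out
}

#' Compare binding-signal representations by prediction correlation
#'
#' Fits one model per binding representation against the same response and
#' reports the Pearson correlation between predicted and observed transcript
#' levels. Representations whose name ends in \code{"_mars"} are fitted with
#' splines enabled; all others use linear-only selection, so the comparison
#' differs only in the data representation, not the selection machinery.
#'
#' @param bindingList Named list: representation -> genes x TFs matrix or
#'   \linkS4class{PromoterSignalMatrix} (same gene universe).
#' @param y Response vector over that gene universe.
#' @param config \linkS4class{FitConfig} template (linearOnly is overridden
#'   per representation as described).
#' @return data.frame(representation, r, r2) plus attribute "mean_r".
#' @export
compareRepresentations <- function(bindingList, y, config = FitConfig()) {
  rows <- lapply(names(bindingList), function(nm) {
    el <- bindingList[[nm]]
    m <- if (is(el, "PromoterSignalMatrix")) signalMatrix(el) else as.matrix(el)
    if (nrow(m) != length(y)) {
      warnf("representation %s has a mismatched gene universe; omitted", nm)
      return(NULL)
    }
    cfg <- config
    cfg@linearOnly <- !grepl("_mars$", nm)
    fit <- marsFit(m, y, cfg)
    pred <- predict(fit, m)
    r <- if (stats::sd(pred) > 0) stats::cor(pred, y) else 0
    data.frame(representation = nm, r = r, r2 = fit@r2, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "mean_r") <- mean(out$r)
  out
}

#' Explanatory power of TF binding per promoter segment
#'
#' Tiles the promoter with fixed-width segments, sums each TF's binding in
#' each segment, and regresses expression on each segment's sum alone; the
#' reported profile value is r2 x sign(slope) at the segment midpoint. The
#' final partial segment of the range is dropped.
#'
#' @param tracks Named list TF -> \linkS4class{CoverageTrack}.
#' @param tss TSS table (chrom, tss, gene_id, strand).
#' @param y Named response over tss$gene_id.
#' @param segmentBp Segment width (default 75).
#' @param range Length-2 range relative to the TSS (default c(-1000, 1000)).
#' @param mirror Mirror windows for minus-strand genes (default TRUE).
#' @return data.frame(tf, start, end, midpoint, value).
#' @export
segmentScan <- function(tracks, tss, y, segmentBp = 75,
                        range = c(-1000, 1000), mirror = TRUE) {
  starts <- seq(range[1], range[2] - segmentBp + 1, by = segmentBp)
  y <- y[tss$gene_id]
  rows <- list()
  for (tf in names(tracks)) {
    for (s in starts) {
      e <- s + segmentBp - 1
      x <- windowSumRel(tracks[[tf]], tss, s, e, mirror = mirror)
      ok <- !is.na(x)
      val <- if (sum(ok) > 2 && stats::sd(x[ok]) > 0) {
        fit <- olsFit(cbind(seg = x[ok]), y[ok])
        fit$r2 * sign(fit$coefficients[["seg"]])
      } else 0
      rows[[length(rows) + 1L]] <- data.frame(
        tf = tf, start = s, end = e, midpoint = (s + e) / 2, value = val,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Prediction R2 as a function of symmetric promoter window half-width
#'
#' Quantifies promoter sums at growing symmetric half-widths (stepBp,
#' 2*stepBp, ...), fits a multiple regression with variable selection at
#' each, and records the model R2. The plateau half-width is the smallest
#' one within 1 percent of the curve's maximum — the window that already
#' captures essentially all consequential binding.
#'
#' @param tracks Named list TF -> \linkS4class{CoverageTrack}.
#' @param tss TSS table.
#' @param y Named response over tss$gene_id.
#' @param stepBp Increment (default 50).
#' @param maxHalfwidth Largest half-width tested (default 1000).
#' @param config \linkS4class{FitConfig} for the per-width fits (linear-only
#'   by default keeps the scan about the window, not the spline structure).
#' @param mirror Mirror windows for minus-strand genes.
#' @return list(curve = data.frame(halfwidth, r2), plateau = half-width).
#' @export
regionExtensionScan <- function(tracks, tss, y, stepBp = 50,
                                maxHalfwidth = 1000,
                                config = FitConfig(linearOnly = TRUE),
                                mirror = TRUE) {
  if (stepBp <= 0) stopf("stepBp must be > 0")
  widths <- seq(stepBp, maxHalfwidth, by = stepBp)
  y <- y[tss$gene_id]
  r2s <- vapply(widths, function(h) {
    Xw <- vapply(tracks, function(tr)
      windowSumRel(tr, tss, -h, h, mirror = mirror), numeric(nrow(tss)))
    ok <- stats::complete.cases(Xw)
    marsFit(Xw[ok, , drop = FALSE], y[ok], config)@r2
  }, 0)
  curve <- data.frame(halfwidth = widths, r2 = r2s)
  plateau <- widths[which(r2s >= 0.99 * max(r2s))[1]]
  list(curve = curve, plateau = plateau)
}

#' Detect a coordinated TF trio with inverted expression correlation
#'
#' Given the binding of exactly three TFs in a stated promoter window and
#' the matched expression, partitions genes into two groups by 2-means on
#' the jointly standardized (3 binding + 1 expression) profiles and
#' summarizes, per group, the mean pairwise binding correlation among the
#' trio and the correlation between mean trio binding and expression. A
#' "coordinated repression" call requires positive trio inter-correlation
#' and negative binding-expression correlation in the high-binding group.
#'
#' @param Xw Genes x 3 binding matrix (one window, e.g. -450..-250).
#' @param y Named/parallel expression vector.
#' @param seed Seed for the 2-means partition.
#' @return list(groups, summary = per-group data.frame, call = logical).
#' @export
trioDetection <- function(Xw, y, seed = 1) {
  Xw <- as.matrix(Xw)
  if (ncol(Xw) != 3L) stopf("trio detection needs exactly 3 TF columns")
  if (nrow(Xw) < 10L) stopf("need at least 10 genes for a trio call")
  Z <- zscoreColumns(cbind(Xw, expr = y))
  set.seed(seed)
  km <- stats::kmeans(Z, centers = 2, nstart = 10)
  groups <- km$cluster
  summarize <- function(g) {
    idx <- groups == g
    cr <- suppressWarnings(stats::cor(Xw[idx, , drop = FALSE]))
    data.frame(group = g, n = sum(idx),
               mean_binding = mean(Z[idx, 1:3]),
               trio_intercor = mean(cr[upper.tri(cr)], na.rm = TRUE),
               binding_expr_cor = suppressWarnings(
                 stats::cor(rowMeans(Xw[idx, , drop = FALSE]), y[idx])),
               stringsAsFactors = FALSE)
  }
  s <- rbind(summarize(1), summarize(2))
  high <- s$group[which.max(s$mean_binding)]
  hs <- s[s$group == high, ]
  call <- isTRUE(hs$trio_intercor > 0 && !is.na(hs$binding_expr_cor) &&
                   hs$binding_expr_cor < 0)
  list(groups = groups, summary = s, call = call, high_group = high)
}
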