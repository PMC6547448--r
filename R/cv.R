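# Cross-validated TF/spline stabilization on top of the MARS engine, and
# the GCV-deletion definition of relative variable importance.

#' Cross-validated TF and spline selection
#'
#' Fits a MARS model on every fold-complement of a repeated k-fold split,
#' then keeps only structure that recurs: a TF is retained when it is
#' selected in more than \code{retainFrac} of the fits, and keeps its hinge
#' form only when a hinge on that TF also recurs in more than
#' \code{retainFrac} of the fits (knot = median of the fold knots; the
#' reflected pair is re-formed at that knot). The final model refits the
#' retained structure on all data by OLS. This trades a little in-sample fit
#' for stability: only robust TFs and splines survive.
#'
#' @param X Predictor matrix (genes x TFs).
#' @param y Response vector.
#' @param config A \linkS4class{FitConfig}.
#' @param folds Folds per repeat (default 10); requires n >= 2*folds.
#' @param repeats Number of repeated splits (default 5).
#' @param retainFrac Strict retention threshold (default 0.5).
#' @param seed RNG seed for the fold assignments.
#' @return A \linkS4class{MarsModel}; \code{metadata$selectionFreq} and
#'   \code{metadata$hingeFreq} carry the per-TF fold frequencies,
#'   \code{metadata$nFits} the number of fold fits. If nothing is retained,
#'   an intercept-only model is returned with a diagnostic message.
#' @export
cvSelect <- function(X, y, config = FitConfig(), folds = 10, repeats = 5,
                     retainFrac = 0.5, seed = 1) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  if (n < 2 * folds) stopf("need n >= 2*folds (n = %d, folds = %d)", n, folds)
  set.seed(seed)
  vars <- colnames(X)
  selCount <- stats::setNames(numeric(length(vars)), vars)
  hingeCount <- stats::setNames(numeric(length(vars)), vars)
  knotPool <- stats::setNames(vector("list", length(vars)), vars)
  nFits <- 0L
  for (rep in seq_len(repeats)) {
    foldId <- sample(rep(seq_len(folds), length.out = n))
    for (f in seq_len(folds)) {
      train <- foldId != f
      m <- marsFit(X[train, , drop = FALSE], y[train], config)
      nFits <- nFits + 1L
      tm <- m@terms
      selCount[unique(tm$variable)] <- selCount[unique(tm$variable)] + 1
      hv <- unique(tm$variable[tm$form != "linear"])
      hingeCount[hv] <- hingeCount[hv] + 1
      for (v in hv) {
        ks <- unique(tm$knot[tm$variable == v & tm$form != "linear"])
        knotPool[[v]] <- c(knotPool[[v]], stats::median(ks))
      }
    }
  }
  selFreq <- selCount / nFits
  hingeFreq <- hingeCount / nFits
  retained <- vars[selFreq > retainFrac]
  meta <- list(selectionFreq = selFreq, hingeFreq = hingeFreq, nFits = nFits,
               folds = folds, repeats = repeats, retainFrac = retainFrac,
               seed = seed, linearOnly = config@linearOnly)
  tss <- sum((y - mean(y))^2)
  if (length(retained) == 0L) {
    message("cvSelect: no TF passed the retention threshold; intercept-only model")
    return(new("MarsModel", intercept = mean(y), terms = emptyTerms(),
               gcv = gcvScore(tss, n, 1, 0, config@penalty),
               r2 = 0, selectedTfs = character(0), metadata = meta))
  }
  rows <- list()
  for (v in retained) {
    if (!config@linearOnly && hingeFreq[v] > retainFrac) {
      k <- stats::median(knotPool[[v]])
      rows[[v]] <- data.frame(variable = v, form = c("hinge_plus", "hinge_minus"),
                              knot = k, stringsAsFactors = FALSE)
    } else {
      rows[[v]] <- data.frame(variable = v, form = "linear", knot = NA_real_,
                              stringsAsFactors = FALSE)
    }
  }
  terms <- do.call(rbind, rows)
  rownames(terms) <- NULL
  basis <- buildBasis(terms, X)
  # drop exactly collinear columns (possible when a median knot degenerates)
  qrB <- qr(cbind(1, basis))
  if (qrB$rank < ncol(basis) + 1L) {
    keep <- logical(nrow(terms))
    B <- matrix(numeric(0), n, 0)
    for (i in seq_len(nrow(terms))) {
      D2 <- cbind(1, B, basis[, i])
      if (qr(D2)$rank == ncol(D2)) { B <- cbind(B, basis[, i]); keep[i] <- TRUE }
    }
    terms <- terms[keep, , drop = FALSE]
  }
  # the retained structure is proposed by the folds but not forced: the
  # full-data refit is itself GCV-pruned, so borderline structure that the
  # whole dataset does not support is still dropped
  model <- marsPrune(terms[names(terms) != "coefficient"], X, y, config)
  if (length(model@selectedTfs) == 0L)
    message("cvSelect: retained structure rejected by full-data GCV; intercept-only model")
  model@metadata <- c(model@metadata, meta)
  model
}

#' Relative variable importance via GCV deletion
#'
#' Importance of a selected TF is the increase in the model's GCV when all
#' of that TF's terms are removed (with coefficient refit), floored at zero
#' and normalized over the selected TFs to sum to 1.
#'
#' @param model A fitted \linkS4class{MarsModel} with >= 1 selected TF.
#' @param X,y The data the model was fitted on.
#' @return Named numeric vector in [0, 1] over the selected TFs, summing to 1.
#' @export
relativeImportance <- function(model, X, y) {
  sel <- model@selectedTfs
  if (length(sel) == 0L) stopf("model has no selected TFs")
  if (length(sel) == 1L) return(stats::setNames(1, sel))
  X <- as.matrix(X)
  n <- nrow(X)
  penalty <- if (!is.null(model@metadata$penalty)) model@metadata$penalty else 2
  tss <- sum((y - mean(y))^2)
  gcvFor <- function(terms) {
    if (nrow(terms) == 0L) return(gcvScore(tss, n, 1, 0, penalty))
    fit <- olsCore(cbind(1, buildBasis(terms, X)), y)
    gcvScore(fit$rss, n, 1 + nrow(terms), countKnots(terms), penalty)
  }
  gFull <- gcvFor(model@terms)
  delta <- vapply(sel, function(v) {
    gRed <- gcvFor(model@terms[model@terms$variable != v, , drop = FALSE])
    max(0, gRed - gFull)
  }, 0)
  if (sum(delta) == 0) return(stats::setNames(rep(1 / length(sel), length(sel)), sel))
  delta / sum(delta)
}
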