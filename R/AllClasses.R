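#' @import methods
NULL

#' Per-base read coverage for one TF/condition track
#'
#' Dense per-base read counts along one or more chromosomes, as produced by
#' piling up ChIP-exo reads (fixed read length) genome-wide. Coordinates are
#' 1-based and inclusive throughout the package, matching the WIG convention.
#'
#' @slot coverage Named list, one non-negative numeric vector per chromosome;
#'   element i is the read count covering base i.
#' @slot meta Free-form list (TF name, condition, replicate, known peak
#'   positions for synthetic tracks, ...).
#' @export
setClass("CoverageTrack",
         representation(coverage = "list", meta = "list"),
         prototype(coverage = list(), meta = list()))

setValidity("CoverageTrack", function(object) {
  cov <- object@coverage
  if (length(cov) == 0L) return("coverage must contain at least one chromosome")
  if (is.null(names(cov)) || any(!nzchar(names(cov))) || anyDuplicated(names(cov)))
    return("coverage must be a uniquely named list of chromosomes")
  for (nm in names(cov)) {
    v <- cov[[nm]]
    if (!is.numeric(v)) return(sprintf("coverage[[%s]] is not numeric", nm))
    if (length(v) < 1L) return(sprintf("coverage[[%s]] is empty", nm))
    if (anyNA(v) || any(v < 0)) return(sprintf("coverage[[%s]] has NA or negative values", nm))
  }
  TRUE
})

#' Genes-by-TFs promoter binding signal (the regression design matrix)
#'
#' One quantification of TF binding per gene promoter for a single condition.
#' Rows are genes, columns are TFs; this is the X matrix of the regressions.
#'
#' @slot signal Non-negative numeric matrix, genes x TFs, with unique rownames.
#' @slot condition Condition label.
#' @slot window Length-2 numeric, (upstream_bp, downstream_bp) relative to the
#'   TSS that the quantification covered.
#' @slot representation One of "promoter_sum", "peak_window", "peak_signal".
#' @export
setClass("PromoterSignalMatrix",
         representation(signal = "matrix", condition = "character",
                        window = "numeric", representation = "character"))

setValidity("PromoterSignalMatrix", function(object) {
  m <- object@signal
  if (!is.numeric(m)) return("signal must be numeric")
  if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
    return("signal must have unique rownames (gene ids)")
  if (anyNA(m) || any(m < 0)) return("signal must be non-negative and complete")
  if (length(object@window) != 2L || any(object@window < 0))
    return("window must be two non-negative lengths (upstream, downstream)")
  if (!object@representation %in% c("promoter_sum", "peak_window", "peak_signal"))
    return("unknown representation")
  TRUE
})

#' Gene counts, lengths and FPKM across conditions (the regression response)
#'
#' Raw RNA-seq read counts per gene and sample, gene lengths, and (after
#' \code{computeFpkm}) replicate-averaged FPKM per condition.
#'
#' @slot counts Non-negative numeric matrix, genes x samples. Column s belongs
#'   to condition \code{conditions[s]}, replicate \code{replicates[s]}.
#' @slot geneLengths Gene lengths in bp, parallel to rows.
#' @slot conditions Condition label per sample column.
#' @slot replicates Replicate label per sample column.
#' @slot fpkm Genes x conditions FPKM matrix; 0x0 until computed.
#' @export
setClass("ExpressionTable",
         representation(counts = "matrix", geneLengths = "numeric",
                        conditions = "character", replicates = "character",
                        fpkm = "matrix"),
         prototype(fpkm = matrix(numeric(0), 0, 0)))

setValidity("ExpressionTable", function(object) {
  cm <- object@counts
  if (is.null(rownames(cm)) || anyDuplicated(rownames(cm)))
    return("counts must have unique gene rownames")
  if (anyNA(cm) || any(cm < 0)) return("counts must be non-negative")
  if (length(object@geneLengths) != nrow(cm)) return("geneLengths must match rows")
  if (any(object@geneLengths <= 0)) return("gene lengths must be > 0")
  if (length(object@conditions) != ncol(cm) || length(object@replicates) != ncol(cm))
    return("conditions/replicates must label every sample column")
  if (nrow(object@fpkm) > 0 && any(object@fpkm < 0)) return("fpkm must be non-negative")
  TRUE
})

#' A fitted MARS model: intercept plus linear/hinge basis terms
#'
#' Additive model Y = b0 + sum_j c_j B_j(x), where each basis term B_j is
#' either a linear term in one TF or a hinge max(0, x - t) / max(0, t - x).
#'
#' @slot intercept Intercept b0.
#' @slot terms data.frame with columns \code{variable}, \code{form}
#'   ("linear", "hinge_plus", "hinge_minus"), \code{knot} (NA for linear),
#'   \code{coefficient}.
#' @slot gcv Generalized cross-validation score of the model.
#' @slot r2 In-sample coefficient of determination.
#' @slot selectedTfs Variables with at least one term.
#' @slot deletionTrace GCV along the backward deletion path (largest model
#'   first); empty for models not produced by pruning.
#' @slot metadata Free-form list (cv fold selections, config echo, ...).
#' @export
setClass("MarsModel",
         representation(intercept = "numeric", terms = "data.frame",
                        gcv = "numeric", r2 = "numeric",
                        selectedTfs = "character", deletionTrace = "numeric",
                        metadata = "list"),
         prototype(deletionTrace = numeric(0), metadata = list()))

setValidity("MarsModel", function(object) {
  tm <- object@terms
  need <- c("variable", "form", "knot", "coefficient")
  if (!all(need %in% names(tm))) return("terms must have variable/form/knot/coefficient")
  if (nrow(tm) > 0) {
    if (!all(tm$form %in% c("linear", "hinge_plus", "hinge_minus")))
      return("unknown basis form")
    hinge <- tm$form != "linear"
    if (any(is.na(tm$knot[hinge]))) return("hinge terms must carry a knot")
    if (any(!is.na(tm$knot[!hinge]))) return("linear terms must not carry a knot")
  }
  if (object@r2 < -1e-8 || object@r2 > 1 + 1e-8) return("r2 must lie in [0, 1]")
  if (!setequal(object@selectedTfs, unique(tm$variable)))
    return("selectedTfs must equal the set of variables with terms")
  TRUE
})

#' MARS fitting configuration
#'
#' @slot maxTerms Cap on forward-pass basis terms (excluding intercept);
#'   NA means min(21, floor(n/10)) chosen at fit time.
#' @slot endspan Minimum number of observations strictly between any knot and
#'   either data extreme (default 100, boundary-knot suppression).
#' @slot penalty GCV cost per knot (default 2).
#' @slot linearOnly If TRUE no hinge candidates are considered (the
#'   "linpreds" analog: plain multiple regression with variable selection).
#' @slot tol Relative RSS improvement below which the forward pass stops.
#' @export
setClass("FitConfig",
         representation(maxTerms = "numeric", endspan = "numeric",
                        penalty = "numeric", linearOnly = "logical",
                        tol = "numeric"))

setValidity("FitConfig", function(object) {
  if (!is.na(object@maxTerms) && object@maxTerms < 1) return("maxTerms must be >= 1")
  if (object@endspan < 0) return("endspan must be >= 0")
  if (object@penalty < 0) return("penalty must be >= 0")
  if (object@tol < 0) return("tol must be >= 0")
  TRUE
})

#' Constructor for \linkS4class{FitConfig}
#'
#' @param maxTerms,endspan,penalty,linearOnly,tol See the class slots.
#' @return A \code{FitConfig}.
#' @export
FitConfig <- function(maxTerms = NA_real_, endspan = 100, penalty = 2,
                      linearOnly = FALSE, tol = 1e-6) {
  new("FitConfig", maxTerms = as.numeric(maxTerms), endspan = as.numeric(endspan),
      penalty = as.numeric(penalty), linearOnly = isTRUE(linearOnly),
      tol = as.numeric(tol))
}

#' Generative ground truth for synthetic binding/expression data
#'
#' Holds every parameter of the generative model
#' Y = b0 + sum_k f_k(X_k) + gamma * X_a * X_b + eps, where f_k is linear,
#' hinge, or saturating in the binding signal of an active TF, eps is
#' Gaussian, and designated TF pairs have collinear binding.
#'
#' @slot nGenes,nTfs Problem size.
#' @slot conditions Condition labels.
#' @slot activeTfs TF indices with non-zero effect.
#' @slot coefficients Effect size per active TF (parallel to activeTfs).
#' @slot knots Hinge threshold per active TF; NA means purely linear.
#' @slot saturationTfs Subset of activeTfs whose effect plateaus.
#' @slot saturationKnots Upper knot per saturation TF (parallel).
#' @slot collinearPairs data.frame(a, b, rho): binding-scale Pearson targets.
#' @slot interactionPair list(a, b, gamma) or empty list.
#' @slot intercept b0.
#' @slot noiseSd SD of the additive expression noise.
#' @slot bindingMeanlog,bindingSdlog Log-normal binding marginals.
#' @slot seed RNG seed; identical truth implies bit-identical output.
#' @export
setClass("SyntheticTruth",
         representation(nGenes = "numeric", nTfs = "numeric",
                        conditions = "character", activeTfs = "integer",
                        coefficients = "numeric", knots = "numeric",
                        saturationTfs = "integer", saturationKnots = "numeric",
                        collinearPairs = "data.frame", interactionPair = "list",
                        intercept = "numeric", noiseSd = "numeric",
                        bindingMeanlog = "numeric", bindingSdlog = "numeric",
                        seed = "numeric"))

setValidity("SyntheticTruth", function(object) {
  if (object@nGenes < 10) return("nGenes must be >= 10")
  if (object@nTfs < 2) return("nTfs must be >= 2")
  if (length(object@conditions) < 1) return("need at least one condition")
  if (length(object@activeTfs) > 0 &&
      (any(object@activeTfs < 1) || any(object@activeTfs > object@nTfs)))
    return("activeTfs must be a subset of 1..nTfs")
  if (length(object@coefficients) != length(object@activeTfs))
    return("coefficients must be parallel to activeTfs")
  if (length(object@knots) != length(object@activeTfs))
    return("knots must be parallel to activeTfs (NA = linear)")
  if (!all(object@saturationTfs %in% object@activeTfs))
    return("saturationTfs must be active TFs")
  if (length(object@saturationKnots) != length(object@saturationTfs))
    return("saturationKnots must be parallel to saturationTfs")
  cp <- object@collinearPairs
  if (nrow(cp) > 0) {
    if (!all(c("a", "b", "rho") %in% names(cp))) return("collinearPairs needs a, b, rho")
    if (any(cp$rho < -1 | cp$rho > 1)) return("rho must lie in [-1, 1]")
    if (any(cp$a == cp$b)) return("collinear pairs must name two distinct TFs")
  }
  ip <- object@interactionPair
  if (length(ip) > 0 && !all(c("a", "b", "gamma") %in% names(ip)))
    return("interactionPair needs a, b, gamma")
  if (object@noiseSd < 0) return("noiseSd must be >= 0")
  TRUE
})

#' Constructor for \linkS4class{SyntheticTruth}
#'
#' Defaults emulate the processed scale of the study design this package
#' targets: ~850 metabolic genes, 21 TFs, 4 chemostat conditions, heavy-tailed
#' (log-normal) promoter binding sums.
#'
#' @param nGenes,nTfs,conditions Problem size and condition labels.
#' @param activeTfs,coefficients,knots,saturationTfs,saturationKnots Effects.
#' @param collinearPairs data.frame(a, b, rho) or NULL.
#' @param interactionPair list(a=, b=, gamma=) or NULL.
#' @param intercept,noiseSd Intercept and expression noise SD.
#' @param bindingMeanlog,bindingSdlog Binding marginal parameters.
#' @param seed RNG seed.
#' @return A \code{SyntheticTruth}.
#' @export
SyntheticTruth <- function(nGenes = 850, nTfs = 21,
                           conditions = c("glucose", "nitrogen", "ethanol", "anaerobic"),
                           activeTfs = integer(0), coefficients = numeric(0),
                           knots = rep(NA_real_, length(activeTfs)),
                           saturationTfs = integer(0),
                           saturationKnots = numeric(0),
                           collinearPairs = NULL, interactionPair = NULL,
                           intercept = 0, noiseSd = 0,
                           bindingMeanlog = 2, bindingSdlog = 1, seed = 1) {
  if (is.null(collinearPairs))
    collinearPairs <- data.frame(a = integer(0), b = integer(0), rho = numeric(0))
  if (is.null(interactionPair)) interactionPair <- list()
  new("SyntheticTruth", nGenes = nGenes, nTfs = nTfs,
      conditions = as.character(conditions),
      activeTfs = as.integer(activeTfs), coefficients = as.numeric(coefficients),
      knots = as.numeric(knots), saturationTfs = as.integer(saturationTfs),
      saturationKnots = as.numeric(saturationKnots),
      collinearPairs = collinearPairs, interactionPair = interactionPair,
      intercept = intercept, noiseSd = noiseSd,
      bindingMeanlog = bindingMeanlog, bindingSdlog = bindingSdlog,
      seed = seed)
}

#' A complete synthetic dataset with its generating truth
#'
#' @slot binding Named list (condition -> \linkS4class{PromoterSignalMatrix}).
#' @slot expression \linkS4class{ExpressionTable} spanning all conditions.
#' @slot tracks Nested named list (condition -> TF -> list of replicate
#'   \linkS4class{CoverageTrack}s); may be empty when tracks were not built.
#' @slot tss data.frame(chrom, tss, gene_id, strand).
#' @slot truth The \linkS4class{SyntheticTruth} that generated everything.
#' @slot meta List (response scale factors, peak geometry, ...).
#' @export
setClass("SyntheticBundle",
         representation(binding = "list", expression = "ExpressionTable",
                        tracks = "list", tss = "data.frame",
                        truth = "SyntheticTruth", meta = "list"),
         prototype(tracks = list(), meta = list()))

setValidity("SyntheticBundle", function(object) {
  genes <- object@tss$gene_id
  for (cond in names(object@binding)) {
    b <- object@binding[[cond]]
    if (!setequal(rownames(b@signal), genes))
      return("every gene in binding must appear in tss")
  }
  if (!setequal(rownames(object@expression@counts), genes))
    return("every gene in expression must appear in tss")
  TRUE
})

#' A k-means clustering of normalized expression profiles
#'
#' @slot k Number of clusters.
#' @slot assignments Named integer vector, gene -> cluster in 1..k.
#' @slot centroids k x conditions centroid matrix.
#' @slot bicCurve data.frame(k, bic) when k was selected by BIC; else empty.
#' @slot normalizedInput The unit-norm expression matrix that was clustered.
#' @export
setClass("ClusterModel",
         representation(k = "numeric", assignments = "integer",
                        centroids = "matrix", bicCurve = "data.frame",
                        normalizedInput = "matrix"),
         prototype(bicCurve = data.frame()))

setValidity("ClusterModel", function(object) {
  a <- object@assignments
  if (is.null(names(a))) return("assignments must be named by gene")
  if (any(a < 1 | a > object@k)) return("assignments must lie in 1..k")
  if (nrow(object@centroids) != object@k) return("centroids must have k rows")
  TRUE
})

setMethod("show", "CoverageTrack", function(object) {
  lens <- vapply(object@coverage, length, 0L)
  cat("CoverageTrack:", length(lens), "chromosome(s),",
      format(sum(lens), big.mark = ","), "bp,",
      "total reads", format(round(sum(vapply(object@coverage, sum, 0)), 1)), "\n")
})

setMethod("show", "PromoterSignalMatrix", function(object) {
  cat(sprintf("PromoterSignalMatrix: %d genes x %d TFs [%s, window -%d/+%d, condition %s]\n",
              nrow(object@signal), ncol(object@signal), object@representation,
              object@window[1], object@window[2], object@condition))
})

setMethod("show", "ExpressionTable", function(object) {
  cat(sprintf("ExpressionTable: %d genes, %d samples (%d condition(s))%s\n",
              nrow(object@counts), ncol(object@counts),
              length(unique(object@conditions)),
              if (nrow(object@fpkm) > 0) ", FPKM computed" else ""))
})

setMethod("show", "MarsModel", function(object) {
  cat(sprintf("MarsModel: intercept %.4g + %d term(s) over %d TF(s); R2 = %.3f, GCV = %.4g\n",
              object@intercept, nrow(object@terms), length(object@selectedTfs),
              object@r2, object@gcv))
  if (nrow(object@terms) > 0) {
    lab <- ifelse(object@terms$form == "linear", object@terms$variable,
                  ifelse(object@terms$form == "hinge_plus",
                         sprintf("h(%s - %.3g)", object@terms$variable, object@terms$knot),
                         sprintf("h(%.3g - %s)", object@terms$knot, object@terms$variable)))
    cat("  ", paste(sprintf("%+.3g*%s", object@terms$coefficient, lab), collapse = " "), "\n")
  }
})

setMethod("show", "SyntheticTruth", function(object) {
  cat(sprintf("SyntheticTruth: %d genes x %d TFs, %d condition(s), %d active TF(s), noiseSd %.3g, seed %d\n",
              object@nGenes, object@nTfs, length(object@conditions),
              length(object@activeTfs), object@noiseSd, object@seed))
})

setMethod("show", "SyntheticBundle", function(object) {
  cat(sprintf("SyntheticBundle: %d genes, %d condition(s), %s tracks\n",
              nrow(object@tss), length(object@binding),
              if (length(object@tracks)) "with" else "no"))
})

setMethod("show", "ClusterModel", function(object) {
  cat(sprintf("ClusterModel: k = %d over %d genes x %d condition(s)%s\n",
              object@k, length(object@assignments), ncol(object@centroids),
              if (nrow(object@bicCurve)) " (k chosen by BIC)" else ""))
})
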