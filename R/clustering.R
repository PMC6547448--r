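# Expression clustering: BIC-guided choice of k, k-means partitioning,
# hypergeometric gene-set enrichment, and per-cluster linear models.

kmeansSafe <- function(m, k, restarts, seed, maxRetries = 5L) {
  for (a in 0:maxRetries) {
    set.seed(deriveSeed(seed, a))
    km <- tryCatch(stats::kmeans(m, centers = k, nstart = restarts,
                                 iter.max = 100),
                   error = function(e) NULL, warning = function(w) NULL)
    if (!is.null(km) && length(unique(km$cluster)) == k) return(km)
  }
  stopf("k-means failed to produce %d non-empty clusters after retries", k)
}

#' Select the number of clusters by BIC
#'
#' For each candidate k, runs best-of-restarts k-means (squared Euclidean)
#' and scores a spherical equal-variance Gaussian BIC; k* minimizes the
#' curve. The default \code{formula = "mixture"} is the full
#' X-means-style criterion: -2 lnL + p log(n) with
#' lnL = sum_i n_i log(n_i/n) - (n d / 2) log(2 pi s2) - (d/2)(n - k),
#' s2 = WCSS/(d (n - k)) and p = (k - 1) + k d + 1 free parameters. The
#' multinomial assignment term sum n_i log(n_i/n) matters: without it
#' (\code{formula = "simple"}, n d log(WCSS/(n d)) + k d log(n)) the
#' criterion keeps rewarding spurious splits of Gaussian clusters and
#' drifts to the top of the k range on mixture data.
#'
#' @param m Normalized genes x conditions matrix (unit-norm rows).
#' @param kRange Candidate k values (default 2:30, clipped to n/2).
#' @param restarts k-means restarts per k (default 10).
#' @param seed RNG seed; the curve is deterministic given the seed.
#' @param formula "mixture" (default) or "simple"; see Details.
#' @return list(curve = data.frame(k, bic), kStar).
#' @export
selectKBIC <- function(m, kRange = 2:30, restarts = 10, seed = 1,
                       formula = c("mixture", "simple")) {
  formula <- match.arg(formula)
  m <- as.matrix(m)
  n <- nrow(m); d <- ncol(m)
  kRange <- kRange[kRange >= 2 & kRange <= n / 2]
  if (length(kRange) == 0L) stopf("kRange must contain values in 2..n/2")
  bic <- vapply(kRange, function(k) {
    km <- kmeansSafe(m, k, restarts, deriveSeed(seed, k))
    W <- km$tot.withinss
    if (formula == "simple")
      return(n * d * log(W / (n * d)) + k * d * log(n))
    s2 <- max(W / (d * (n - k)), 1e-300)
    ni <- km$size
    lnL <- sum(ni * log(ni / n)) - (n * d / 2) * log(2 * pi * s2) -
      (d / 2) * (n - k)
    p <- (k - 1) + k * d + 1
    -2 * lnL + p * log(n)
  }, 0)
  curve <- data.frame(k = kRange, bic = bic)
  list(curve = curve, kStar = kRange[which.min(bic)])
}

#' Cluster genes by their normalized cross-condition expression
#'
#' Best-of-restarts k-means on unit-norm expression profiles.
#'
#' @param m Normalized genes x conditions matrix with gene rownames.
#' @param k Number of clusters (>= 2), e.g. the BIC choice.
#' @param restarts Restarts (default 10).
#' @param seed RNG seed.
#' @param bicCurve Optional BIC curve data.frame to record on the model.
#' @return A \linkS4class{ClusterModel}.
#' @export
clusterGenes <- function(m, k, restarts = 10, seed = 1, bicCurve = NULL) {
  m <- as.matrix(m)
  if (k < 2) stopf("k must be >= 2")
  if (k > nrow(m)) stopf("k exceeds the number of genes")
  km <- kmeansSafe(m, k, restarts, seed)
  new("ClusterModel", k = k,
      assignments = stats::setNames(as.integer(km$cluster), rownames(m)),
      centroids = km$centers,
      bicCurve = if (is.null(bicCurve)) data.frame() else bicCurve,
      normalizedInput = m)
}

#' Hypergeometric gene-set enrichment per cluster
#'
#' One-sided hypergeometric test of the overlap between every cluster and
#' every user-supplied gene set, against the background universe of all
#' clustered genes, with Benjamini-Hochberg adjustment across the full
#' cluster x set grid. Sets and clusters with empty intersection with the
#' universe are skipped.
#'
#' @param clusters A \linkS4class{ClusterModel} or named assignment vector.
#' @param geneSets Named list of character vectors (e.g. \code{readGmt}).
#' @param alpha Flagging threshold on the adjusted p-value (default 0.01).
#' @return data.frame(cluster, set_name, cluster_size, set_size, overlap,
#'   p, p_adj, flagged), ordered by p_adj.
#' @export
enrichClusters <- function(clusters, geneSets, alpha = 0.01) {
  assign <- if (is(clusters, "ClusterModel")) assignments(clusters) else clusters
  universe <- names(assign)
  N <- length(universe)
  rows <- list()
  for (cl in sort(unique(assign))) {
    clGenes <- universe[assign == cl]
    if (length(clGenes) == 0L) next
    for (sn in names(geneSets)) {
      setG <- intersect(geneSets[[sn]], universe)
      if (length(setG) == 0L) next
      ov <- length(intersect(clGenes, setG))
      p <- stats::phyper(ov - 1, length(setG), N - length(setG),
                         length(clGenes), lower.tail = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = cl, set_name = sn, cluster_size = length(clGenes),
        set_size = length(setG), overlap = ov, p = p,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(cluster = integer(0), set_name = character(0),
                      cluster_size = integer(0), set_size = integer(0),
                      overlap = integer(0), p = numeric(0),
                      p_adj = numeric(0), flagged = logical(0)))
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out$flagged <- out$p_adj < alpha
  out <- out[order(out$p_adj, out$p, out$cluster), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-cluster, per-condition linear models with importance and substitution
#'
#' Refits the TF selection inside each expression cluster: linear-only
#' cross-validated selection (splines are unstable in small gene groups)
#' per cluster x condition, signed TF-importance scores, column-wise
#' Z-scored binding and expression matrices for heatmap export, and
#' substitutable collinear TFs appended as links.
#'
#' @param clusters \linkS4class{ClusterModel} or named assignment vector.
#' @param bindingList Named list condition -> \linkS4class{PromoterSignalMatrix}
#'   (or genes x TFs matrix) over at least the clustered genes.
#' @param fpkmMat Genes x conditions FPKM matrix.
#' @param config \linkS4class{FitConfig}; linearOnly is forced TRUE.
#' @param minSize Clusters smaller than this are skipped (default 10).
#' @param folds,repeats Cross-validation plan (folds auto-shrink in small
#'   clusters so n >= 2*folds holds).
#' @param seed RNG seed.
#' @return Nested list cluster -> condition -> list(model, importance,
#'   r2, substitutions, z_binding, z_expression); skipped clusters carry a
#'   diagnostic string instead.
#' @export
perClusterModels <- function(clusters, bindingList, fpkmMat,
                             config = FitConfig(), minSize = 10,
                             folds = 10, repeats = 5, seed = 1) {
  assign <- if (is(clusters, "ClusterModel")) assignments(clusters) else clusters
  config@linearOnly <- TRUE
  out <- list()
  for (cl in sort(unique(assign))) {
    genes <- names(assign)[assign == cl]
    key <- as.character(cl)
    if (length(genes) < minSize) {
      out[[key]] <- sprintf("skipped: %d genes < minSize %d", length(genes), minSize)
      next
    }
    fIn <- max(2, min(folds, length(genes) %/% 3))
    out[[key]] <- list()
    for (cond in names(bindingList)) {
      el <- bindingList[[cond]]
      Xall <- if (is(el, "PromoterSignalMatrix")) signalMatrix(el) else as.matrix(el)
      Xc <- Xall[genes, , drop = FALSE]
      keep <- apply(Xc, 2, stats::sd) > 0
      Xc <- Xc[, keep, drop = FALSE]
      yc <- fpkmMat[genes, cond]
      sd2 <- deriveSeed(seed, cl * 131L + match(cond, names(bindingList)))
      model <- cvSelect(Xc, yc, config = config, folds = fIn,
                        repeats = repeats, seed = sd2)
      subs <- data.frame()
      imp <- NULL
      if (length(model@selectedTfs) > 0) {
        imp <- tfImportance(model, Xc, yc, condition = cond, cluster = key)
        rep <- collinearity(Xc)
        subs <- substitutionTest(Xc, yc, model, rep, config = config,
                                 folds = fIn, repeats = repeats, seed = sd2)
      }
      out[[key]][[cond]] <- list(
        model = model, importance = imp, r2 = model@r2, substitutions = subs,
        z_binding = zscoreColumns(Xc),
        z_expression = stats::setNames(
          as.numeric(scale(yc)), genes))
    }
  }
  out
}
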