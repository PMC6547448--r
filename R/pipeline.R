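# Pipeline orchestration: validated JSON run configs, the staged end-to-end
# run (quantify -> expression -> fits -> collinearity/interactions ->
# clustering -> per-cluster models -> promoter scans), and the small demo
# bundle used by documentation and the acceptance suite.

#' Default pipeline run configuration
#'
#' @param wigDir,tssPath,countsPath,outDir,geneSetsPath Input/output paths
#'   (geneSetsPath may be NULL: enrichment is skipped).
#' @param seed Master seed; every stage derives its own child seed from it.
#' @return A named list, ready for \code{validateRunConfig}/\code{runPipeline}.
#' @export
defaultRunConfig <- function(wigDir, tssPath, countsPath, outDir,
                             geneSetsPath = NULL, seed = 1) {
  list(
    wigDir = wigDir, tssPath = tssPath, countsPath = countsPath,
    geneSetsPath = geneSetsPath, outDir = outDir,
    window = c(500, 500), representation = "promoter_sum",
    minSnr = 2, peakMinSignal = 3, minReads = 1,
    endspan = 25, penalty = 2, linearOnly = FALSE,
    cvFolds = 5, cvRepeats = 2, retainFrac = 0.5,
    clusterK = "auto", kRange = c(2, 10), clusterRestarts = 10,
    enrichAlpha = 0.01, clusterMinSize = 10,
    segmentBp = 75, segmentRange = c(-1000, 1000),
    regionStepBp = 50, regionMaxHalfwidth = 600,
    seed = seed, logLevel = "info")
}

#' Read / write a run configuration (JSON)
#'
#' Plain-text key/value configuration; serialize -> parse -> serialize is
#' byte-identical.
#'
#' @param path File path.
#' @return \code{readRunConfig}: the config list.
#' @export
readRunConfig <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' @rdname readRunConfig
#' @param config Config list.
#' @export
writeRunConfig <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Validate a run configuration, reporting all problems at once
#'
#' @param config Config list (see \code{defaultRunConfig}).
#' @return Character vector of problems (empty when valid).
#' @export
validateRunConfig <- function(config) {
  probs <- character(0)
  need <- c("wigDir", "tssPath", "countsPath", "outDir", "seed")
  miss <- setdiff(need, names(config))
  if (length(miss)) probs <- c(probs, paste("missing field(s):", paste(miss, collapse = ", ")))
  for (f in intersect(c("wigDir", "tssPath", "countsPath", "geneSetsPath"), names(config))) {
    p <- config[[f]]
    if (!is.null(p) && !file.exists(p))
      probs <- c(probs, sprintf("%s does not exist: %s", f, p))
  }
  if (!is.null(config$representation) &&
      !config$representation %in% c("promoter_sum", "peak_window", "peak_signal"))
    probs <- c(probs, sprintf("unknown representation: %s", config$representation))
  if (!is.null(config$window) && (length(config$window) != 2 || any(config$window < 0)))
    probs <- c(probs, "window must be two non-negative lengths")
  probs
}

modelToList <- function(model) {
  list(intercept = model@intercept,
       terms = model@terms,
       gcv = model@gcv, r2 = model@r2,
       selected_tfs = model@selectedTfs)
}

writeJson <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Run the full pipeline from a validated configuration
#'
#' Stages: quantify (WIG -> replicate-averaged promoter signal per
#' condition, plus peak-based target overlaps) -> expression (counts ->
#' filtered FPKM) -> per-condition model fits (cross-validated selection)
#' -> importance/collinearity/substitution/interactions -> clustering
#' (normalize, BIC k, k-means, optional enrichment) -> per-cluster models
#' -> promoter segment and region-extension scans. Every output is written
#' under \code{config$outDir}; a manifest (hashed inputs, config echo,
#' seed, per-stage outputs and timings) concludes the run. A stage failure
#' halts with a stage-named error, preserving earlier outputs.
#'
#' WIG files in \code{wigDir} must be named \code{<TF>_<condition>_rep<i>.wig}.
#'
#' @param config Config list (see \code{defaultRunConfig}).
#' @return The manifest list, invisibly.
#' @export
runPipeline <- function(config) {
  probs <- validateRunConfig(config)
  if (length(probs)) stopf("invalid run config:\n  - %s", paste(probs, collapse = "\n  - "))
  out <- config$outDir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  quiet <- identical(config$logLevel, "quiet")
  note <- function(...) if (!quiet) message(sprintf(...))
  manifest <- list(package = "tfmars", seed = seed, config = config,
                   inputs = list(), stages = list())
  stage <- function(name, fun) {
    note("[%s] starting", name)
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e)
      stopf("stage '%s' failed: %s", name, conditionMessage(e)))
    manifest$stages[[name]] <<- list(
      outputs = res$outputs %||% character(0),
      seconds = round(proc.time()[["elapsed"]] - t0, 2))
    note("[%s] done (%.1fs)", name, manifest$stages[[name]]$seconds)
    res
  }

  tss <- readTss(config$tssPath)
  wigs <- list.files(config$wigDir, pattern = "\\.wig$", full.names = TRUE)
  if (length(wigs) == 0) stopf("no .wig files in %s", config$wigDir)
  inputFiles <- c(wigs, config$tssPath, config$countsPath, config$geneSetsPath)
  manifest$inputs <- lapply(inputFiles, function(p)
    list(path = p, md5 = unname(tools::md5sum(p))))

  # --- quantify -------------------------------------------------------------
  q <- stage("quantify", function() {
    info <- regmatches(basename(wigs),
                       regexec("^(.+)_(.+)_rep([0-9]+)\\.wig$", basename(wigs)))
    bad <- vapply(info, length, 0L) != 4L
    if (any(bad)) stopf("unparseable wig name(s): %s",
                        paste(basename(wigs)[bad], collapse = ", "))
    tf <- vapply(info, `[[`, "", 2L); cond <- vapply(info, `[[`, "", 3L)
    binding <- list(); peaksByCond <- list(); avgTracks <- list()
    for (cn in sort(unique(cond))) {
      sig <- list(); pk <- list()
      for (tfn in sort(unique(tf))) {
        files <- wigs[tf == tfn & cond == cn]
        if (length(files) == 0) next
        avg <- averageReplicates(lapply(files, readWig))
        avgTracks[[cn]][[tfn]] <- avg
        peaks <- detectPeaks(avg, minSnr = config$minSnr,
                             minSignal = config$peakMinSignal)
        peaks <- annotatePeaks(peaks, tss, radiusBp = config$window[1])
        pk[[tfn]] <- peaks
        sig[[tfn]] <- switch(config$representation,
          promoter_sum = promoterSum(avg, tss, window = config$window),
          peak_window = peakWindowSum(avg, peaks, tss$gene_id),
          peak_signal = peakSignalSum(peaks, tss$gene_id, minSnr = config$minSnr))
      }
      m <- do.call(cbind, sig)
      rownames(m) <- tss$gene_id
      ok <- stats::complete.cases(m)
      binding[[cn]] <- new("PromoterSignalMatrix", signal = m[ok, , drop = FALSE],
                           condition = cn, window = as.numeric(config$window),
                           representation = config$representation)
      writeSignalMatrix(binding[[cn]], file.path(out, sprintf("binding_%s.tsv", cn)))
      peaksByCond[[cn]] <- pk
    }
    # per-TF target overlaps across conditions
    overlapReport <- lapply(sort(unique(tf)), function(tfn) {
      sets <- lapply(peaksByCond, function(pl) pl[[tfn]])
      ct <- conditionTargets(sets, minSnr = config$minSnr)
      list(tf = tfn,
           n_targets = lapply(ct$targets, length),
           overlaps = as.list(ct$overlaps))
    })
    writeJson(overlapReport, file.path(out, "target_overlaps.json"))
    list(binding = binding, tracks = avgTracks,
         outputs = c(sprintf("binding_%s.tsv", names(binding)), "target_overlaps.json"))
  })

  # --- expression -----------------------------------------------------------
  e <- stage("expression", function() {
    et <- computeFpkm(filterMinCount(readCountsTable(config$countsPath),
                                     minReads = config$minReads))
    f <- fpkm(et)
    writeTsv(data.frame(gene_id = rownames(f), f, check.names = FALSE),
             file.path(out, "fpkm.tsv"))
    list(et = et, outputs = "fpkm.tsv")
  })
  fpkmMat <- fpkm(e$et)
  genes <- intersect(rownames(fpkmMat), rownames(signalMatrix(q$binding[[1]])))
  fpkmMat <- fpkmMat[genes, , drop = FALSE]

  cfg <- FitConfig(endspan = config$endspan, penalty = config$penalty,
                   linearOnly = isTRUE(config$linearOnly))

  # --- per-condition fits ---------------------------------------------------
  fits <- stage("fit", function() {
    models <- list()
    for (cn in names(q$binding)) {
      X <- signalMatrix(q$binding[[cn]])[genes, , drop = FALSE]
      y <- fpkmMat[, cn]
      m <- cvSelect(X, y, config = cfg, folds = config$cvFolds,
                    repeats = config$cvRepeats, retainFrac = config$retainFrac,
                    seed = deriveSeed(seed, 200 + match(cn, names(q$binding))))
      models[[cn]] <- m
      writeJson(modelToList(m), file.path(out, sprintf("model_%s.json", cn)))
      if (length(m@selectedTfs) > 0)
        writeTsv(tfImportance(m, X, y, condition = cn),
                 file.path(out, sprintf("importance_%s.tsv", cn)))
    }
    list(models = models,
         outputs = sprintf("model_%s.json", names(q$binding)))
  })

  # --- collinearity / substitution / interactions ---------------------------
  stage("collinearity", function() {
    outs <- character(0)
    for (cn in names(q$binding)) {
      X <- signalMatrix(q$binding[[cn]])[genes, , drop = FALSE]
      y <- fpkmMat[, cn]
      rep <- collinearity(X)
      writeTsv(data.frame(tf = rownames(rep$r), rep$r, check.names = FALSE),
               file.path(out, sprintf("collinearity_r_%s.tsv", cn)))
      writeTsv(rep$significant_pairs,
               file.path(out, sprintf("collinearity_pairs_%s.tsv", cn)))
      writeTsv(interactionScan(X, y, rep),
               file.path(out, sprintf("interactions_%s.tsv", cn)))
      subs <- substitutionTest(X, y, fits$models[[cn]], rep, config = cfg,
                               folds = config$cvFolds, repeats = config$cvRepeats,
                               seed = deriveSeed(seed, 300 + match(cn, names(q$binding))))
      writeTsv(subs, file.path(out, sprintf("substitutions_%s.tsv", cn)))
      outs <- c(outs, sprintf(c("collinearity_r_%s.tsv", "collinearity_pairs_%s.tsv",
                                "interactions_%s.tsv", "substitutions_%s.tsv"), cn))
    }
    list(outputs = outs)
  })

  # --- clustering -----------------------------------------------------------
  cl <- stage("cluster", function() {
    nm <- suppressWarnings(sumOfSquaresNormalize(fpkmMat))
    kRange <- seq(config$kRange[1], config$kRange[2])
    bic <- NULL
    if (identical(config$clusterK, "auto")) {
      sel <- selectKBIC(nm, kRange = kRange, restarts = config$clusterRestarts,
                        seed = deriveSeed(seed, 400))
      k <- sel$kStar; bic <- sel$curve
      writeTsv(bic, file.path(out, "bic_curve.tsv"))
    } else k <- as.integer(config$clusterK)
    cm <- clusterGenes(nm, k, restarts = config$clusterRestarts,
                       seed = deriveSeed(seed, 401), bicCurve = bic)
    writeTsv(data.frame(gene_id = names(assignments(cm)),
                        cluster = as.integer(assignments(cm))),
             file.path(out, "clusters.tsv"))
    outs <- c("clusters.tsv", if (!is.null(bic)) "bic_curve.tsv")
    if (!is.null(config$geneSetsPath)) {
      enr <- enrichClusters(cm, readGmt(config$geneSetsPath),
                            alpha = config$enrichAlpha)
      writeTsv(enr, file.path(out, "enrichment.tsv"))
      outs <- c(outs, "enrichment.tsv")
    }
    list(cm = cm, outputs = outs)
  })

  # --- per-cluster models ---------------------------------------------------
  stage("cluster_models", function() {
    pcm <- perClusterModels(cl$cm, q$binding, fpkmMat, config = cfg,
                            minSize = config$clusterMinSize,
                            folds = config$cvFolds, repeats = config$cvRepeats,
                            seed = deriveSeed(seed, 500))
    summary <- list()
    for (k in names(pcm)) {
      if (is.character(pcm[[k]])) { summary[[k]] <- pcm[[k]]; next }
      summary[[k]] <- lapply(pcm[[k]], function(el)
        list(r2 = el$r2, model = modelToList(el$model),
             substitutions = el$substitutions))
    }
    writeJson(summary, file.path(out, "cluster_models.json"))
    list(outputs = "cluster_models.json")
  })

  # --- promoter scans -------------------------------------------------------
  stage("scans", function() {
    outs <- character(0)
    tssG <- tss[tss$gene_id %in% genes, , drop = FALSE]
    for (cn in names(q$tracks)) {
      y <- fpkmMat[, cn]
      seg <- segmentScan(q$tracks[[cn]], tssG, y,
                         segmentBp = config$segmentBp,
                         range = config$segmentRange)
      writeTsv(seg, file.path(out, sprintf("segment_scan_%s.tsv", cn)))
      reg <- regionExtensionScan(q$tracks[[cn]], tssG, y,
                                 stepBp = config$regionStepBp,
                                 maxHalfwidth = config$regionMaxHalfwidth,
                                 config = FitConfig(endspan = config$endspan,
                                                    penalty = config$penalty,
                                                    linearOnly = TRUE))
      writeTsv(cbind(reg$curve, plateau = reg$plateau),
               file.path(out, sprintf("region_scan_%s.tsv", cn)))
      outs <- c(outs, sprintf(c("segment_scan_%s.tsv", "region_scan_%s.tsv"), cn))
    }
    list(outputs = outs)
  })

  writeJson(manifest, file.path(out, "manifest.json"))
  note("pipeline complete: %s", out)
  invisible(manifest)
}

#' Build the small demo bundle used by documentation and acceptance runs
#'
#' Writes a 200-gene, 8-TF, 2-condition synthetic bundle (coverage tracks,
#' TSS table, counts, binding matrices, truth record), a matching gene-set
#' collection, a ready-to-run pipeline config, and an expected-results
#' summary derived from the truth.
#'
#' @param seed Master seed (default 7).
#' @param dir Output directory.
#' @return list(dir, config = config list, bundle), invisibly.
#' @export
makeDemo <- function(seed = 7, dir = tempfile("tfmars_demo_")) {
  truth <- SyntheticTruth(
    nGenes = 200, nTfs = 8, conditions = c("glucose", "nitrogen"),
    activeTfs = c(1L, 2L, 3L, 5L),
    coefficients = c(3, 2, 1.5, 1),
    knots = c(10, NA, 5, NA),
    saturationTfs = 2L, saturationKnots = 40,
    collinearPairs = data.frame(a = 3L, b = 4L, rho = 0.9),
    interactionPair = list(a = 1L, b = 2L, gamma = 0.02),
    intercept = 50, noiseSd = 15, seed = seed)
  bundle <- makeSyntheticBundle(truth, geneSpacing = 1200, peakWidth = 10,
                                heightScale = 1, backgroundRate = 0.2,
                                withTracks = TRUE, trackReplicates = 2)
  writeBundle(bundle, dir)
  # two gene sets: top targets of the strongest TF, and a random control
  X <- signalMatrix(bundle@binding[[1]])
  top <- names(sort(X[, 1], decreasing = TRUE))[1:40]
  set.seed(deriveSeed(seed, 9L))
  ctrl <- sort(sample(rownames(X), 40))
  gmt <- c(paste(c("tf1_top_targets", "top binding of TF01", top), collapse = "\t"),
           paste(c("random_control", "seeded random control set", ctrl), collapse = "\t"))
  writeLines(gmt, file.path(dir, "sets.gmt"))
  config <- defaultRunConfig(
    wigDir = file.path(dir, "tracks"), tssPath = file.path(dir, "tss.tsv"),
    countsPath = file.path(dir, "counts.tsv"),
    geneSetsPath = file.path(dir, "sets.gmt"),
    outDir = file.path(dir, "results"), seed = seed)
  writeRunConfig(config, file.path(dir, "run_config.json"))
  expected <- list(
    n_genes = truth@nGenes, n_tfs = truth@nTfs,
    conditions = truth@conditions,
    active_tfs = tfIds(truth@nTfs)[truth@activeTfs],
    collinear_pair = list(a = "TF03", b = "TF04", rho = 0.9),
    interaction_pair = list(a = "TF01", b = "TF02", gamma = 0.02),
    response_scale = as.list(bundle@meta$responseScale))
  writeJson(expected, file.path(dir, "expected.json"))
  invisible(list(dir = dir, config = config, bundle = bundle))
}
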