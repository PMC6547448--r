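# Importance scoring, collinearity significance, substitution testing,
# interaction scans, promoter segment/region scans, and trio detection.

test_that("importance scores are R2 x relative importance x sign", {
  # single activating TF: score = r2 * 1.0 * (+1)
  X <- lognormalX(400, 2, seed = 11)
  y <- 2 * X[, 1] + rnorm(400, 0, 0.3 * sd(2 * X[, 1]))
  m <- cvSelect(X, y, FitConfig(linearOnly = TRUE), folds = 5, repeats = 2, seed = 1)
  imp <- tfImportance(m, X, y)
  i1 <- imp[imp$tf == "TF01", ]
  expect_equal(i1$score, modelR2(m) * i1$relative_importance * 1)
  expect_equal(i1$sign, 1)

  # repressor: negative coefficient gives a negative score
  yr <- -2 * X[, 1] + rnorm(400, 0, 0.3 * sd(2 * X[, 1]))
  mr <- cvSelect(X, yr, FitConfig(linearOnly = TRUE), folds = 5, repeats = 2, seed = 1)
  impr <- tfImportance(mr, X, yr)
  expect_equal(impr$sign[impr$tf == "TF01"], -1)
  expect_lt(impr$score[impr$tf == "TF01"], 0)

  # |scores| sum to at most the model R2 (weights sum to 1)
  X2 <- lognormalX(500, 3, seed = 12)
  y2 <- X2[, 1] + X2[, 2] - 0.5 * X2[, 3]
  y2 <- y2 + rnorm(500, 0, 0.2 * sd(y2))
  m2 <- cvSelect(X2, y2, FitConfig(linearOnly = TRUE), folds = 5, repeats = 2, seed = 2)
  imp2 <- tfImportance(m2, X2, y2)
  expect_lte(sum(abs(imp2$score)), modelR2(m2) + 1e-12)
})

test_that("collinearity p-values follow the product-moment t reference", {
  # planted rho = 0.9 at n = 1000: overwhelming significance
  tr <- SyntheticTruth(nGenes = 1000, nTfs = 3,
                       collinearPairs = data.frame(a = 1L, b = 2L, rho = 0.9),
                       seed = 6)
  rep <- collinearity(generateBindingMatrix(tr, "glucose"))
  expect_lt(rep$p["TF01", "TF02"], 1e-10)
  expect_true(any(rep$significant_pairs$a == "TF01" & rep$significant_pairs$b == "TF02"))

  # closed-form spot checks: r = 0 -> p = 1; n = 5, r = 0.878 -> p ~ 0.05
  X0 <- cbind(a = c(-1, 1, -1, 1), b = c(-1, -1, 1, 1), c = rnorm(4))
  rep0 <- collinearity(rbind(X0, X0))
  expect_equal(rep0$p["a", "b"], 1)
  r <- 0.878; n <- 5
  pWant <- 2 * pt(-abs(r * sqrt((n - 2) / (1 - r^2))), n - 2)
  expect_equal(pWant, 0.05, tolerance = 0.01)

  # implementation matches cor.test on random matrices
  set.seed(13)
  Xr <- matrix(rnorm(30 * 4), 30, 4, dimnames = list(NULL, letters[1:4]))
  repr <- collinearity(Xr)
  for (i in 1:3) for (j in (i + 1):4) {
    ct <- cor.test(Xr[, i], Xr[, j])
    expect_equal(repr$r[i, j], unname(ct$estimate), tolerance = 1e-12)
    expect_equal(repr$p[i, j], ct$p.value, tolerance = 1e-12)
  }

  # zero-variance columns are recorded as missing, matrix stays symmetric
  Xz <- cbind(Xr, z = rep(2, 30))
  repz <- suppressWarnings(collinearity(Xz))
  expect_true(all(is.na(repz$r["z", ])))
  expect_equal(repz$r, t(repz$r))
})

test_that("interaction improvement arithmetic and nesting hold exactly", {
  # delta 0.04 on additive 0.40 -> ratio 1.10, flag boundary inclusive
  expect_equal((0.04 + 0.40) / 0.40, 1.10)
  set.seed(14)
  X <- lognormalX(300, 2, seed = 14)
  y <- X[, 1] + 0.5 * X[, 2] + 0.05 * X[, 1] * X[, 2] + rnorm(300, 0, 1)
  res <- interactionScan(X, y, data.frame(a = "TF01", b = "TF02"))
  expect_gte(res$r2_multiplicative, res$r2_additive)  # nested OLS
  expect_equal(res$improvement_ratio,
               (res$delta_r2 + res$r2_additive) / res$r2_additive)

  # improvement ratio is invariant to rescaling X and y
  res2 <- interactionScan(X * 3, y * 10, data.frame(a = "TF01", b = "TF02"))
  expect_equal(res2$improvement_ratio, res$improvement_ratio, tolerance = 1e-9)
})

test_that("substitution testing finds planted collinear partners and no decoys", {
  tr <- SyntheticTruth(nGenes = 850, nTfs = 6, activeTfs = 1L, coefficients = 2,
                       knots = NA_real_,
                       collinearPairs = data.frame(a = 1L, b = 2L, rho = 0.95),
                       intercept = 10, noiseSd = 0, seed = 31)
  b <- generateBindingMatrix(tr, "glucose")
  X <- signalMatrix(b)
  y <- generateExpression(tr, b)
  y <- y + rnorm(850, 0, 0.2 * sd(y))
  cfg <- FitConfig(linearOnly = TRUE)
  m <- cvSelect(X, y, cfg, folds = 10, repeats = 2, seed = 1)
  rep <- collinearity(X)
  subs <- substitutionTest(X, y, m, rep, config = cfg, folds = 10,
                           repeats = 2, seed = 1)
  expect_true("TF01" %in% selectedTfs(m))
  expect_true(any(subs$excluded == "TF01" & subs$substitute == "TF02"))
  # independent decoys (TF03..TF06) never substitute
  expect_false(any(subs$substitute %in% c("TF03", "TF04", "TF05", "TF06")))

  # a model that selects nothing yields an empty list
  m0 <- new("MarsModel", intercept = 0, terms = tfmars:::emptyTerms(), gcv = 1,
            r2 = 0, selectedTfs = character(0))
  expect_equal(nrow(substitutionTest(X, y, m0, rep)), 0)
})

test_that("segment scans localize causal binding and carry the effect sign", {
  # causal binding confined to -450..-250; inert binding elsewhere
  n <- 300
  set.seed(41)
  tss <- data.frame(chrom = "chrA", tss = as.integer(seq(3000, by = 3000, length.out = n)),
                    gene_id = sprintf("g%03d", 1:n), strand = "+",
                    stringsAsFactors = FALSE)
  amt <- exp(rnorm(n, 2, 1))
  # width-200 pileup centered at -350 covers -450..-251
  causal <- generateCoverageTrack(tss, offsets = as.list(setNames(rep(-350, n), tss$gene_id)),
                                  heights = as.list(setNames(amt, tss$gene_id)),
                                  width = 200, backgroundRate = 0, seed = 2)
  y <- setNames(5 + 3 * promoterSum(causal, tss), tss$gene_id)
  prof <- segmentScan(list(TFC = causal), tss, y, segmentBp = 75,
                      range = c(-600, 600))
  inWin <- prof$start >= -450 & prof$end <= -226
  expect_gt(min(prof$value[inWin]), 0.9)
  expect_lt(max(abs(prof$value[prof$end <= -451 | prof$start >= -225])), 0.05)

  # a repressor gives a negative profile
  yr <- setNames(5000 - 3 * promoterSum(causal, tss), tss$gene_id)
  profr <- segmentScan(list(TFC = causal), tss, yr, segmentBp = 75,
                       range = c(-600, 600))
  expect_lt(max(profr$value[inWin]), -0.9)
})

test_that("region extension scans plateau at the causal half-width", {
  n <- 250
  set.seed(51)
  tss <- data.frame(chrom = "chrA", tss = as.integer(seq(3000, by = 3000, length.out = n)),
                    gene_id = sprintf("g%03d", 1:n), strand = "+",
                    stringsAsFactors = FALSE)
  genes <- tss$gene_id
  mk <- function(offset, width, seedAdd) {
    set.seed(seedAdd)
    amt <- exp(rnorm(n, 2, 1))
    list(track = generateCoverageTrack(tss, as.list(setNames(rep(offset, n), genes)),
                                       as.list(setNames(amt, genes)),
                                       width = width, backgroundRate = 0, seed = seedAdd),
         amt = amt)
  }
  a <- mk(-80, 40, 61)   # causal signal confined within +/-100
  b <- mk(-420, 40, 62)  # inert binding farther upstream
  y <- setNames(10 + 3 * a$amt * 40, genes)
  scan <- regionExtensionScan(list(TFA = a$track, TFB = b$track), tss, y,
                              stepBp = 50, maxHalfwidth = 500)
  expect_lte(scan$plateau, 150)
  # curve is non-decreasing up to the plateau on noise-free truth
  upto <- scan$curve$halfwidth <= scan$plateau
  expect_true(all(diff(scan$curve$r2[upto]) >= -1e-9))
})

test_that("trio detection calls coordinated repression and respects antisymmetry", {
  set.seed(71)
  n <- 300
  latent <- exp(rnorm(n, 1.5, 1))          # shared occupancy factor
  Xw <- vapply(1:3, function(i) latent * exp(rnorm(n, 0, 0.25)), numeric(n))
  colnames(Xw) <- c("Sut1like", "Ert1like", "Gcn4like")
  y <- 100 - 4 * latent + rnorm(n, 0, 3)   # repressed where binding is high
  res <- trioDetection(Xw, y, seed = 1)
  expect_true(res$call)
  hs <- res$summary[res$summary$group == res$high_group, ]
  expect_gt(hs$trio_intercor, 0)
  expect_lt(hs$binding_expr_cor, 0)

  # flipped expression: activation pattern, no repression call
  expect_false(trioDetection(Xw, 200 - y, seed = 1)$call)

  # independent TFs: no coordinated structure
  Xi <- matrix(exp(rnorm(n * 3, 1.5, 1)), n, 3)
  yi <- rnorm(n, 50, 5)
  expect_false(trioDetection(Xi, yi, seed = 1)$call)

  expect_error(trioDetection(Xw[1:5, ], y[1:5]), "10 genes")
  expect_error(trioDetection(cbind(Xw, extra = latent), y), "3 TF")
})

test_that("representation comparison prefers richer signal and splines on hinge truth", {
  # hinge-shaped truth: MARS correlation >= linear correlation (nested classes)
  X <- lognormalX(400, 3, seed = 81)
  y <- 3 * pmax(X[, 1] - 8, 0) + X[, 2]
  y <- y + rnorm(400, 0, 0.15 * sd(y))
  cmp <- compareRepresentations(
    list(promoter_sum = X, promoter_sum_mars = X), y,
    config = FitConfig(endspan = 40))
  rLin <- cmp$r[cmp$representation == "promoter_sum"]
  rMars <- cmp$r[cmp$representation == "promoter_sum_mars"]
  expect_gte(rMars, rLin - 1e-9)
  expect_equal(attr(cmp, "mean_r"), mean(cmp$r))

  # a representation with a mismatched gene universe is omitted with a warning
  expect_warning(
    cmp2 <- compareRepresentations(list(promoter_sum = X, bad = X[1:10, ]), y,
                                   config = FitConfig(linearOnly = TRUE)),
    "omitted")
  expect_equal(nrow(cmp2), 1)
})
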