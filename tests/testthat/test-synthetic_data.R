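# Synthetic-data generator: binding marginals and collinearity calibration,
# closed-form expression contributions, coverage-track geometry, determinism.

test_that("collinear pairs hit their target Pearson correlation on the binding scale", {
  tr <- SyntheticTruth(nGenes = 1000, nTfs = 4,
                       collinearPairs = data.frame(a = 1L, b = 2L, rho = 0.9),
                       seed = 1)
  B <- signalMatrix(generateBindingMatrix(tr, "glucose"))
  expect_true(all(B >= 0))
  r <- cor(B[, 1], B[, 2])
  expect_gte(r, 0.85)
  expect_lte(r, 0.95)
})

test_that("without designated pairs all binding correlations are weak", {
  tr <- SyntheticTruth(nGenes = 1000, nTfs = 6, seed = 2)
  B <- signalMatrix(generateBindingMatrix(tr, "glucose"))
  cm <- cor(B)
  expect_lt(max(abs(cm[upper.tri(cm)])), 0.2)
})

test_that("binding generation is deterministic and rejects degenerate sizes", {
  tr <- SyntheticTruth(nGenes = 50, nTfs = 3, seed = 5)
  b1 <- signalMatrix(generateBindingMatrix(tr, "nitrogen"))
  b2 <- signalMatrix(generateBindingMatrix(tr, "nitrogen"))
  expect_identical(b1, b2)
  expect_error(SyntheticTruth(nGenes = 9, nTfs = 3), "nGenes")
  expect_error(SyntheticTruth(nGenes = 50, nTfs = 1), "nTfs")
})

test_that("expression contributions follow the closed-form generative model", {
  # linear TF: beta = 2, b0 = 1, X = 3 -> Y = 7
  tr <- SyntheticTruth(nGenes = 10, nTfs = 2, activeTfs = 1L, coefficients = 2,
                       knots = NA_real_, intercept = 1, noiseSd = 0, seed = 1)
  b <- generateBindingMatrix(tr, "glucose")
  b@signal[1, 1] <- 3
  expect_equal(unname(generateExpression(tr, b)[1]), 7)

  # hinge below the knot contributes nothing: t = 5, X = 4 -> Y = b0
  trH <- SyntheticTruth(nGenes = 10, nTfs = 2, activeTfs = 1L, coefficients = 1,
                        knots = 5, intercept = 1, noiseSd = 0, seed = 1)
  bH <- generateBindingMatrix(trH, "glucose")
  bH@signal[1, 1] <- 4
  expect_equal(unname(generateExpression(trH, bH)[1]), 1)
  bH@signal[2, 1] <- 9  # above the knot: 1 * (9 - 5) + 1
  expect_equal(unname(generateExpression(trH, bH)[2]), 5)

  # pure interaction: gamma = 0.5, Xa = 2, Xb = 3 -> Y = 3
  trI <- SyntheticTruth(nGenes = 10, nTfs = 2,
                        interactionPair = list(a = 1L, b = 2L, gamma = 0.5),
                        intercept = 0, noiseSd = 0, seed = 1)
  bI <- generateBindingMatrix(trI, "glucose")
  bI@signal[1, 1] <- 2; bI@signal[1, 2] <- 3
  expect_equal(unname(generateExpression(trI, bI)[1]), 3)

  # saturating effect flattens above the second knot
  trS <- SyntheticTruth(nGenes = 10, nTfs = 2, activeTfs = 1L, coefficients = 2,
                        knots = 5, saturationTfs = 1L, saturationKnots = 8,
                        intercept = 0, noiseSd = 0, seed = 1)
  bS <- generateBindingMatrix(trS, "glucose")
  bS@signal[1, 1] <- 20  # capped at 2 * (8 - 5)
  expect_equal(unname(generateExpression(trS, bS)[1]), 6)
})

test_that("coverage tracks are pileups plus Poisson background with exact window sums", {
  tss <- data.frame(chrom = "chrA", tss = 2000L, gene_id = "g1", strand = "+",
                    stringsAsFactors = FALSE)
  # one peak height 20 width 10 at TSS-100, no background: promoter sum 200
  tr <- generateCoverageTrack(tss, offsets = list(g1 = -100), heights = list(g1 = 20),
                              width = 10, backgroundRate = 0, seed = 1)
  expect_equal(unname(promoterSum(tr, tss)[1]), 200)
  # peak outside the +/-500 window contributes nothing
  tr2 <- generateCoverageTrack(tss, offsets = list(g1 = -600), heights = list(g1 = 20),
                               width = 10, backgroundRate = 0, seed = 1)
  expect_equal(unname(promoterSum(tr2, tss)[1]), 0)
  # Poisson background totals land within 4 sd of rate * genome length
  tss3 <- data.frame(chrom = "chrA", tss = 999000L, gene_id = "g1", strand = "+",
                     stringsAsFactors = FALSE)
  tr3 <- generateCoverageTrack(tss3, offsets = list(g1 = numeric(0)),
                               heights = list(g1 = numeric(0)),
                               backgroundRate = 0.1,
                               chromLengths = c(chrA = 1e6L), seed = 42)
  total <- sum(trackCoverage(tr3)$chrA)
  expect_lt(abs(total - 0.1 * 1e6), 4 * sqrt(0.1 * 1e6))
  # invalid inputs are rejected
  expect_error(generateCoverageTrack(tss, list(g1 = -100), list(g1 = -5)), "height")
  expect_error(generateCoverageTrack(tss, list(g1 = -2500), list(g1 = 5)), "2000")
  expect_error(generateCoverageTrack(tss, list(g1 = -100), list(g1 = 5),
                                     backgroundRate = -1), "backgroundRate")
})

test_that("identical truth gives a bit-identical bundle", {
  tr <- SyntheticTruth(nGenes = 40, nTfs = 3, activeTfs = 1L, coefficients = 2,
                       knots = NA_real_, conditions = c("a", "b"),
                       intercept = 10, noiseSd = 1, seed = 11)
  b1 <- makeSyntheticBundle(tr, withTracks = TRUE, geneSpacing = 1500,
                            trackReplicates = 1)
  b2 <- makeSyntheticBundle(tr, withTracks = TRUE, geneSpacing = 1500,
                            trackReplicates = 1)
  expect_identical(signalMatrix(bundleBinding(b1)$a), signalMatrix(bundleBinding(b2)$a))
  expect_identical(countsMatrix(bundleExpression(b1)), countsMatrix(bundleExpression(b2)))
  expect_identical(trackCoverage(bundleTracks(b1)$a$TF01[[1]]),
                   trackCoverage(bundleTracks(b2)$a$TF01[[1]]))
})

test_that("effect-free TFs have no residual association with the response", {
  tr <- SyntheticTruth(nGenes = 1000, nTfs = 5, activeTfs = c(1L, 2L),
                       coefficients = c(2, 1), knots = c(NA, NA),
                       intercept = 5, noiseSd = 0, seed = 3)
  b <- generateBindingMatrix(tr, "glucose")
  y <- generateExpression(tr, b)
  X <- signalMatrix(b)
  for (j in 3:5) {
    ry <- resid(lm(y ~ X[, 1] + X[, 2]))
    rx <- resid(lm(X[, j] ~ X[, 1] + X[, 2]))
    expect_lt(abs(cor(ry, rx)), 0.05)
  }
})

test_that("the generating model explains its own data as noise vanishes", {
  base <- SyntheticTruth(nGenes = 500, nTfs = 4, activeTfs = c(1L, 2L),
                         coefficients = c(2, 1), knots = c(10, NA),
                         intercept = 5, noiseSd = 0, seed = 4)
  b <- generateBindingMatrix(base, "glucose")
  mu <- generateExpression(base, b)  # noise-free mean
  tr <- SyntheticTruth(nGenes = 500, nTfs = 4, activeTfs = c(1L, 2L),
                       coefficients = c(2, 1), knots = c(10, NA),
                       intercept = 5, noiseSd = 0.01 * sd(mu), seed = 4)
  y <- generateExpression(tr, b)
  r2 <- 1 - sum((y - mu)^2) / sum((y - mean(y))^2)
  expect_gt(r2, 0.99)
})
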