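# WIG round-trips, replicate averaging, promoter-window quantification
# against the brute-force oracle, the naive peak caller, peak annotation,
# and target-set overlap arithmetic.

test_that("fixedStep WIG round-trips losslessly and handles gaps/errors", {
  tr <- new("CoverageTrack",
            coverage = list(chr1 = c(0, 2, 4.5, 0, 1, 7, 0, 0, 3, 1)))
  f <- tempfile(fileext = ".wig")
  writeWig(tr, f)
  back <- readWig(f)
  expect_equal(trackCoverage(back)$chr1, trackCoverage(tr)$chr1)

  # variableStep with gaps: unlisted positions become 0
  f2 <- tempfile(fileext = ".wig")
  writeLines(c("variableStep chrom=chr2", "3 5", "7 2"), f2)
  v <- trackCoverage(readWig(f2))$chr2
  expect_equal(v, c(0, 0, 5, 0, 0, 0, 2))

  # empty file is an error, not an empty track
  f3 <- tempfile(fileext = ".wig")
  writeLines(character(0), f3)
  expect_error(readWig(f3), "empty")

  # malformed header names the offending line
  f4 <- tempfile(fileext = ".wig")
  writeLines(c("fixedStep chrom=chr1 start=1 step=1", "1", "2",
               "fixedStep start=5 step=1", "9"), f4)
  expect_error(readWig(f4), "line 4")

  # overlapping declarations are an error
  f5 <- tempfile(fileext = ".wig")
  writeLines(c("fixedStep chrom=chr1 start=1 step=1", "1", "2",
               "fixedStep chrom=chr1 start=2 step=1", "9"), f5)
  expect_error(readWig(f5), "overlap")
})

test_that("replicate averaging is the per-base mean and validates inputs", {
  t1 <- new("CoverageTrack", coverage = list(c1 = c(0, 2, 4)))
  t2 <- new("CoverageTrack", coverage = list(c1 = c(2, 2, 0)))
  expect_equal(trackCoverage(averageReplicates(list(t1, t2)))$c1, c(1, 2, 2))
  expect_equal(trackCoverage(averageReplicates(list(t1)))$c1, c(0, 2, 4))
  t3 <- new("CoverageTrack", coverage = list(c2 = c(1, 1, 1)))
  expect_error(averageReplicates(list(t1, t3)), "chromosome sets")
  t4 <- new("CoverageTrack", coverage = list(c1 = c(1, 1)))
  expect_error(averageReplicates(list(t1, t4)), "lengths")
})

test_that("promoter sums match the brute-force base-by-base oracle", {
  # uniform coverage of 1: the +/-500 window is inclusive -> 1001 bases
  tssU <- data.frame(chrom = "chrA", tss = 5000L, gene_id = "g1", strand = "+",
                     stringsAsFactors = FALSE)
  trU <- new("CoverageTrack", coverage = list(chrA = rep(1, 10000)))
  expect_equal(unname(promoterSum(trU, tssU)[1]), 1001)

  # minus-strand single base: counted iff the mirrored window covers it
  tssM <- data.frame(chrom = "chrA", tss = 300L, gene_id = "gm", strand = "-",
                     stringsAsFactors = FALSE)
  cov <- numeric(600); cov[200] <- 7  # tss - 100 on the genomic left
  trM <- new("CoverageTrack", coverage = list(chrA = cov))
  got <- unname(promoterSum(trM, tssM, window = c(500, 50))[1])
  expect_equal(got, bruteForceWindowSum(cov, 300, "-", 500, 50))

  # 100 random small tracks, random windows, both strands
  for (seed in 1:100) {
    fx <- randomTinyTrack(seed)
    up <- sample(10:80, 1); dn <- sample(10:80, 1)
    got <- promoterSum(fx$track, fx$tss, window = c(up, dn))
    for (i in seq_len(nrow(fx$tss))) {
      want <- bruteForceWindowSum(trackCoverage(fx$track)$chrA,
                                  fx$tss$tss[i], fx$tss$strand[i], up, dn)
      expect_equal(unname(got[fx$tss$gene_id[i]]), want)
    }
  }

  # unknown chromosome: NA with a warning, not an abort
  tssX <- rbind(tssU, data.frame(chrom = "chrZ", tss = 100L, gene_id = "g2",
                                 strand = "+", stringsAsFactors = FALSE))
  expect_warning(ps <- promoterSum(trU, tssX), "absent")
  expect_true(is.na(ps["g2"]) && !is.na(ps["g1"]))
})

test_that("replicate averaging commutes with promoter summation", {
  fx1 <- randomTinyTrack(201); fx2 <- randomTinyTrack(202)
  tracks <- list(fx1$track, fx2$track)
  avg <- averageReplicates(tracks)
  sumOfAvg <- promoterSum(avg, fx1$tss, window = c(50, 50))
  avgOfSums <- (promoterSum(tracks[[1]], fx1$tss, window = c(50, 50)) +
                  promoterSum(tracks[[2]], fx1$tss, window = c(50, 50))) / 2
  expect_equal(sumOfAvg, avgOfSums)
})

test_that("reversing the chromosome and flipping strands preserves promoter sums", {
  fx <- randomTinyTrack(303)
  fwd <- promoterSum(fx$track, fx$tss, window = c(60, 20))
  L <- length(trackCoverage(fx$track)$chrA)
  revTrack <- new("CoverageTrack", coverage = list(chrA = rev(trackCoverage(fx$track)$chrA)))
  revTss <- fx$tss
  revTss$tss <- L + 1L - revTss$tss
  revTss$strand <- ifelse(revTss$strand == "+", "-", "+")
  expect_equal(promoterSum(revTrack, revTss, window = c(60, 20)), fwd)
})

test_that("the naive peak caller thresholds strictly on local SNR", {
  # rectangular pileup height 20 on background 1: one peak, snr about 20
  cov <- rep(1, 5000); cov[2000:2019] <- 21
  pk <- detectPeaks(new("CoverageTrack", coverage = list(c1 = cov)))
  expect_equal(nrow(pk), 1)
  expect_equal(pk$local_noise, 1)
  expect_gt(pk$snr, 18); expect_lt(pk$snr, 22)
  expect_true(pk$position >= 2000 && pk$position <= 2019)

  # flat track: no local maxima, empty result
  expect_equal(nrow(detectPeaks(new("CoverageTrack",
                                    coverage = list(c1 = rep(2, 1000))))), 0)
  expect_equal(nrow(detectPeaks(new("CoverageTrack",
                                    coverage = list(c1 = rep(0, 1000))))), 0)

  # snr exactly 2 fails the strict > threshold
  cov2 <- rep(1, 5000); cov2[2000:2019] <- 2
  expect_equal(nrow(detectPeaks(new("CoverageTrack", coverage = list(c1 = cov2)))), 0)
})

test_that("peak annotation is inclusive at the radius and breaks ties lexicographically", {
  tss <- data.frame(chrom = "c1", tss = c(1000L, 2000L),
                    gene_id = c("gB", "gA"), strand = c("+", "+"),
                    stringsAsFactors = FALSE)
  mkPeak <- function(pos) data.frame(chrom = "c1", position = pos, signal = 10,
                                     local_noise = 1, snr = 10,
                                     gene_id = NA_character_,
                                     stringsAsFactors = FALSE)
  expect_equal(annotatePeaks(mkPeak(1500L), tss)$gene_id, "gA")  # equidistant 500
  expect_equal(annotatePeaks(mkPeak(1501L), tss)$gene_id, "gA")  # nearer gA
  expect_equal(annotatePeaks(mkPeak(2500L), tss)$gene_id, "gA")  # boundary inclusive
  expect_true(is.na(annotatePeaks(mkPeak(2501L), tss)$gene_id))  # just outside
})

test_that("peak-window sums count overlapping windows once per base", {
  # one annotated peak over uniform coverage 2: 101 bases x 2 = 202
  tr <- new("CoverageTrack", coverage = list(c1 = rep(2, 3000)))
  pk <- data.frame(chrom = "c1", position = 1000L, signal = 5, local_noise = 1,
                   snr = 5, gene_id = "g1", stringsAsFactors = FALSE)
  expect_equal(unname(peakWindowSum(tr, pk, "g1")[1]), 202)

  # two overlapping windows of one gene: brute-force union of bases
  set.seed(9); cov <- as.numeric(rpois(3000, 3))
  trR <- new("CoverageTrack", coverage = list(c1 = cov))
  pk2 <- rbind(pk, transform(pk, position = 1060L))
  union <- unique(c(950:1050, 1010:1110))
  expect_equal(unname(peakWindowSum(trR, pk2, "g1")[1]), sum(cov[union]))

  # no peaks -> 0
  expect_equal(unname(peakWindowSum(tr, pk, c("g1", "g2"))["g2"]), 0)
})

test_that("condition target overlaps are exact exclusive set counts", {
  ct <- conditionTargets(list(A = c("g1", "g2"), B = c("g2", "g3")))
  expect_equal(unname(ct$overlaps["A&B"]), 1L)
  expect_equal(unname(ct$overlaps["A"]), 1L)
  expect_equal(unname(ct$overlaps["B"]), 1L)

  same <- list(A = c("x", "y"), B = c("x", "y"), C = c("x", "y"), D = c("x", "y"))
  ct2 <- conditionTargets(same)
  expect_equal(unname(ct2$overlaps["A&B&C&D"]), 2L)
  expect_true(all(ct2$overlaps[names(ct2$overlaps) != "A&B&C&D"] == 0))

  ct3 <- conditionTargets(list(A = "g1", B = "g2"))
  expect_equal(unname(ct3$overlaps["A&B"]), 0L)
})

test_that("representation values are monotone for nested noise-free windows", {
  # peaks inside the promoter: promoter sum >= peak-window sum >= summit signal
  tss <- data.frame(chrom = "chrA", tss = c(3000L, 9000L),
                    gene_id = c("g1", "g2"), strand = c("+", "-"),
                    stringsAsFactors = FALSE)
  tr <- generateCoverageTrack(tss, offsets = list(g1 = -150, g2 = -200),
                              heights = list(g1 = 30, g2 = 12),
                              width = 20, backgroundRate = 0, seed = 1)
  pk <- annotatePeaks(detectPeaks(tr), tss)
  ps <- promoterSum(tr, tss, mirror = FALSE)
  pw <- peakWindowSum(tr, pk, tss$gene_id)
  pg <- peakSignalSum(pk, tss$gene_id)
  expect_true(all(ps >= pw - 1e-9))
  expect_true(all(pw >= pg - 1e-9))
  expect_true(all(pg > 0))
})

test_that("GEM-like peak lists read with sensible defaults", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("chrom\tposition\tsignal", "c1\t1200\t44", "c1\t2900\t7"), f)
  pk <- readPeaks(f)
  expect_equal(nrow(pk), 2)
  expect_true(all(is.infinite(pk$snr)))  # pre-filtered list passes thresholds
  expect_true(all(is.na(pk$gene_id)))
  tss <- data.frame(chrom = "c1", tss = 1000L, gene_id = "g1", strand = "+",
                    stringsAsFactors = FALSE)
  ann <- annotatePeaks(pk, tss)
  expect_equal(ann$gene_id, c("g1", NA))
  expect_error(readPeaks({f2 <- tempfile(); writeLines("chrom\tpos", f2); f2}),
               "needs columns")
})
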