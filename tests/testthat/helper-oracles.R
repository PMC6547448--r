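# Independent oracles and small fixture builders used across the suite.
# Oracles are deliberately naive (loops, enumeration, closed forms) and
# share no code with the implementation paths they check.

# Base-by-base promoter sum for one gene: the brute-force oracle.
bruteForceWindowSum <- function(coverage, tssPos, strand, upstream, downstream,
                                mirror = TRUE) {
  total <- 0
  for (pos in seq_len(length(coverage))) {
    rel <- pos - tssPos
    if (mirror && strand == "-") rel <- -rel
    if (rel >= -upstream && rel <= downstream) total <- total + coverage[pos]
  }
  total
}

# A random small single-chromosome track plus a random TSS table.
randomTinyTrack <- function(seed, len = 400, nGenes = 3) {
  set.seed(seed)
  cov <- list(chrA = as.numeric(rpois(len, 2)))
  tss <- data.frame(chrom = "chrA",
                    tss = sample(seq(30, len - 30), nGenes),
                    gene_id = sprintf("g%02d", seq_len(nGenes)),
                    strand = sample(c("+", "-"), nGenes, replace = TRUE),
                    stringsAsFactors = FALSE)
  list(track = new("CoverageTrack", coverage = cov), tss = tss)
}

# Exhaustive-subset GCV oracle: refits every subset of the candidate terms
# with lm() and scores GCV = (RSS/n)/(1 - C/n)^2,
# C = #coefficients + penalty * #distinct (variable, knot) hinge combos.
exhaustiveGcvMin <- function(terms, X, y, penalty = 2) {
  X <- as.matrix(X)
  n <- length(y)
  evalBasisCol <- function(i) {
    x <- X[, terms$variable[i]]
    switch(terms$form[i],
           linear = x,
           hinge_plus = pmax(x - terms$knot[i], 0),
           hinge_minus = pmax(terms$knot[i] - x, 0))
  }
  gcvOfSubset <- function(idx) {
    if (length(idx) == 0) {
      rss <- sum((y - mean(y))^2); C <- 1; nk <- 0
    } else {
      B <- vapply(idx, evalBasisCol, numeric(n))
      fit <- lm(y ~ B)
      rss <- sum(resid(fit)^2)
      h <- terms$form[idx] != "linear"
      nk <- if (any(h)) nrow(unique(terms[idx, ][h, c("variable", "knot")])) else 0
      C <- 1 + length(idx)
    }
    Ctot <- C + penalty * nk
    if (Ctot >= n) return(Inf)
    (rss / n) / (1 - Ctot / n)^2
  }
  m <- nrow(terms)
  best <- Inf
  for (mask in 0:(2^m - 1)) {
    idx <- which(as.logical(bitwAnd(mask, 2^(seq_len(m) - 1))))
    g <- gcvOfSubset(idx)
    if (g < best) best <- g
  }
  best
}

# Exact hypergeometric tail by enumeration over all cluster draws from a
# tiny universe: P(overlap >= k) for a draw of size drawn from a universe
# containing setSize marked genes.
enumHyperTail <- function(k, setSize, universe, drawn) {
  combos <- combn(universe, drawn)
  marked <- seq_len(setSize)  # wlog the first setSize ids are the set
  hits <- apply(combos, 2, function(cc) sum(cc %in% marked))
  mean(hits >= k)
}

# Log-normal predictor matrix used by regression simulations.
lognormalX <- function(n, p, seed, meanlog = 2, sdlog = 1) {
  set.seed(seed)
  matrix(exp(rnorm(n * p, meanlog, sdlog)), n, p,
         dimnames = list(sprintf("g%04d", seq_len(n)),
                         sprintf("TF%02d", seq_len(p))))
}
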