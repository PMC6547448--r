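# From-scratch MARS engine: ordinary least squares, hinge-basis greedy
# forward pass, and GCV-based backward pruning. Degree is fixed at 1
# (additive model); multiplicative interactions are tested outside MARS.

#' Ordinary least squares with R2
#'
#' Fits y = b0 + X b by least squares (intercept added automatically).
#' Rank-deficient designs fall back to the minimum-norm solution with a
#' warning.
#'
#' @param X Design matrix (n x p, n > p) without intercept column.
#' @param y Response vector.
#' @param addIntercept Prepend an intercept column (default TRUE).
#' @return list(coefficients, fitted, residuals, rss, r2).
#' @export
olsFit <- function(X, y, addIntercept = TRUE) {
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stopf("X and y disagree on n")
  if (anyNA(X) || anyNA(y)) stopf("missing values are not supported")
  fit <- olsCore(if (addIntercept) cbind(`(Intercept)` = 1, X) else X, y,
                 warnRank = TRUE)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) max(0, min(1, 1 - fit$rss / tss)) else 0
  c(fit, list(r2 = r2))
}

# QR least squares on the full design (intercept included by caller).
olsCore <- function(D, y, warnRank = FALSE) {
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    if (warnRank) warnf("rank-deficient design; returning minimum-norm solution")
    sv <- svd(D)
    pos <- sv$d > max(sv$d) * 1e-10
    beta <- drop(sv$v[, pos, drop = FALSE] %*%
                   ((t(sv$u[, pos, drop = FALSE]) %*% y) / sv$d[pos]))
  } else {
    beta <- qr.coef(qrD, y)
  }
  names(beta) <- colnames(D)
  fitted <- drop(D %*% beta)
  res <- y - fitted
  list(coefficients = beta, fitted = fitted, residuals = res,
       rss = sum(res^2))
}

emptyTerms <- function() {
  data.frame(variable = character(0), form = character(0),
             knot = numeric(0), coefficient = numeric(0),
             stringsAsFactors = FALSE)
}

# Evaluate the basis matrix of a term table on data X (no intercept column).
buildBasis <- function(terms, X) {
  X <- as.matrix(X)
  if (nrow(terms) == 0L) return(matrix(numeric(0), nrow(X), 0))
  cols <- lapply(seq_len(nrow(terms)), function(i) {
    x <- X[, terms$variable[i]]
    switch(terms$form[i],
           linear = x,
           hinge_plus = pmax(x - terms$knot[i], 0),
           hinge_minus = pmax(terms$knot[i] - x, 0))
  })
  B <- do.call(cbind, cols)
  colnames(B) <- termLabels(terms)
  B
}

termLabels <- function(terms) {
  ifelse(terms$form == "linear", terms$variable,
         ifelse(terms$form == "hinge_plus",
                sprintf("h(%s-%.6g)", terms$variable, terms$knot),
                sprintf("h(%.6g-%s)", terms$knot, terms$variable)))
}

# Distinct (variable, knot) combinations among hinge terms: a hinge pair at
# one knot costs a single knot in the GCV complexity.
countKnots <- function(terms) {
  h <- terms$form != "linear"
  if (!any(h)) return(0L)
  nrow(unique(terms[h, c("variable", "knot")]))
}

# GCV(M) = (RSS/n) / (1 - C(M)/n)^2 with C(M) = #coefficients + penalty*#knots.
gcvScore <- function(rss, n, nCoef, nKnots, penalty) {
  C <- nCoef + penalty * nKnots
  if (C >= n) return(Inf)
  (rss / n) / (1 - C / n)^2
}

# Sorted unique values of x admissible as knots under the endspan rule:
# at least max(endspan, 1) observations strictly below and strictly above.
admissibleKnots <- function(x, endspan) {
  u <- sort(unique(x))
  cnt <- tabulate(match(x, u), nbins = length(u))
  below <- cumsum(cnt) - cnt
  above <- length(x) - cumsum(cnt)
  need <- max(endspan, 1)
  u[below >= need & above >= need]
}

#' MARS forward pass: greedy additive hinge/linear term selection
#'
#' At each step the candidate set is every not-yet-included linear term plus
#' a reflected hinge pair max(0, x-t) / max(0, t-x) at every admissible knot
#' of every variable; the addition with the largest RSS reduction wins.
#' Knots are restricted to observed values with at least \code{endspan}
#' observations strictly between the knot and each data extreme. The pass
#' stops at \code{maxTerms} or when the relative RSS improvement falls below
#' \code{tol}. Ties break to the lowest variable index, linear before hinge,
#' then the lowest knot.
#'
#' @param X Predictor matrix (genes x TFs).
#' @param y Response vector.
#' @param config A \linkS4class{FitConfig}.
#' @return list(terms = candidate term table, rssTrace = RSS after each
#'   addition (first entry: intercept-only)).
#' @export
marsForward <- function(X, y, config = FitConfig()) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(p))
  if (n != length(y)) stopf("X and y disagree on n")
  maxTerms <- if (is.na(config@maxTerms)) min(21, max(1, floor(n / 10)))
              else config@maxTerms
  terms <- data.frame(variable = character(0), form = character(0),
                      knot = numeric(0), stringsAsFactors = FALSE)
  tss <- sum((y - mean(y))^2)
  rssTrace <- tss
  if (tss == 0) return(list(terms = terms, rssTrace = rssTrace))
  kand <- if (config@linearOnly) replicate(p, numeric(0), simplify = FALSE)
          else lapply(seq_len(p), function(j) admissibleKnots(X[, j], config@endspan))
  B <- matrix(numeric(0), n, 0)

  repeat {
    D <- cbind(1, B)
    Q <- qr.Q(qr(D))
    r <- drop(y - Q %*% crossprod(Q, y))
    rss <- sum(r^2)
    if (rss <= 1e-12 * tss) break
    free <- maxTerms - nrow(terms)
    if (free < 1L) break
    best <- list(drop = 0, var = NA_integer_, type = "", knot = NA_real_)
    for (j in seq_len(p)) {
      x <- X[, j]
      xp <- drop(x - Q %*% crossprod(Q, x))
      nx2 <- sum(xp^2)
      hasX <- nx2 > 1e-10 * (sum(x^2) + 1e-300)
      vn <- colnames(X)[j]
      if (hasX && !any(terms$variable == vn & terms$form == "linear")) {
        dLin <- sum(xp * r)^2 / nx2
        if (dLin > best$drop)
          best <- list(drop = dLin, var = j, type = "linear", knot = NA_real_)
      }
      if (free >= 2L && length(kand[[j]]) > 0L) {
        used <- terms$knot[terms$variable == vn & terms$form != "linear"]
        ks <- setdiff(kand[[j]], used)
        if (length(ks) == 0L) next
        H <- pmax(outer(x, ks, "-"), 0)
        A <- H - Q %*% crossprod(Q, H)
        dropx <- 0
        if (hasX) {
          u <- xp / sqrt(nx2)
          A <- A - u %*% crossprod(u, H)
          dropx <- sum(u * r)^2
        }
        cn2 <- colSums(A^2)
        pr <- drop(crossprod(A, r))
        d2 <- ifelse(cn2 > 1e-10 * (colSums(H^2) + 1e-300), pr^2 / cn2, 0)
        pairDrop <- dropx + d2
        kb <- which.max(pairDrop)   # ks sorted: first max = lowest knot
        if (pairDrop[kb] > best$drop)
          best <- list(drop = pairDrop[kb], var = j, type = "hinge", knot = ks[kb])
      }
    }
    if (is.na(best$var) || best$drop < config@tol * rss) break
    vn <- colnames(X)[best$var]
    newRows <- if (best$type == "linear") {
      data.frame(variable = vn, form = "linear", knot = NA_real_,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(variable = vn, form = c("hinge_plus", "hinge_minus"),
                 knot = best$knot, stringsAsFactors = FALSE)
    }
    # add columns one at a time, skipping any that is linearly dependent on
    # the current span (e.g. the minus hinge when the linear term is present)
    for (i in seq_len(nrow(newRows))) {
      cand <- buildBasis(newRows[i, , drop = FALSE], X)
      D2 <- cbind(1, B, cand)
      if (qr(D2)$rank == ncol(D2)) {
        B <- cbind(B, cand)
        terms <- rbind(terms, newRows[i, , drop = FALSE])
      }
    }
    Dnow <- cbind(1, B)
    Qn <- qr.Q(qr(Dnow))
    rssTrace <- c(rssTrace, sum((y - Qn %*% crossprod(Qn, y))^2))
  }
  list(terms = terms, rssTrace = rssTrace)
}

#' MARS backward pass: GCV-guided term deletion
#'
#' Selects, from the forward-pass term set, the sub-model minimizing
#' GCV = (RSS/n) / (1 - C/n)^2, C = #coefficients + penalty * #knots
#' (the intercept-only model is always a candidate; sizes with C >= n are
#' excluded with a warning). Up to \code{exhaustiveLimit} terms every
#' subset is refitted and scored, so the returned GCV is the exact subset
#' minimum; above the limit the classical greedy backward deletion path is
#' used (greedy can miss the optimum by a small margin on correlated
#' bases, which matters at the sizes where enumeration is no longer
#' cheap). The deletion trace records the best GCV per model size,
#' largest first.
#'
#' @param terms Term table from \code{marsForward}.
#' @param X,y Data the terms were grown on.
#' @param config A \linkS4class{FitConfig}.
#' @param exhaustiveLimit Largest term count for exact subset search
#'   (default 10; 2^10 refits).
#' @return A \linkS4class{MarsModel}.
#' @export
marsPrune <- function(terms, X, y, config = FitConfig(), exhaustiveLimit = 10) {
  X <- as.matrix(X)
  n <- nrow(X)
  tss <- sum((y - mean(y))^2)
  basis <- buildBasis(terms, X)

  evalSubset <- function(idx) {
    if (length(idx) == 0L)
      return(list(rss = tss, coef = mean(y), gcv = gcvScore(tss, n, 1, 0, config@penalty)))
    fit <- olsCore(cbind(1, basis[, idx, drop = FALSE]), y)
    g <- gcvScore(fit$rss, n, 1 + length(idx),
                  countKnots(terms[idx, , drop = FALSE]), config@penalty)
    list(rss = fit$rss, coef = fit$coefficients, gcv = g)
  }

  m <- nrow(terms)
  if (is.infinite(evalSubset(seq_len(m))$gcv))
    warnf("model size with C(M) >= n excluded from GCV selection")
  if (m <= exhaustiveLimit) {
    bestPerSize <- rep(Inf, m + 1)
    best <- list(idx = integer(0), fit = evalSubset(integer(0)))
    bestPerSize[1] <- best$fit$gcv
    for (mask in seq_len(2^m - 1)) {
      idx <- which(as.logical(bitwAnd(mask, 2^(seq_len(m) - 1L))))
      cand <- evalSubset(idx)
      sz <- length(idx) + 1L
      if (cand$gcv < bestPerSize[sz]) bestPerSize[sz] <- cand$gcv
      if (cand$gcv < best$fit$gcv) best <- list(idx = idx, fit = cand)
    }
    trace <- rev(bestPerSize)
  } else {
    current <- seq_len(m)
    cur <- evalSubset(current)
    trace <- cur$gcv
    best <- list(idx = current, fit = cur)
    while (length(current) > 0L) {
      cands <- lapply(seq_along(current), function(i) evalSubset(current[-i]))
      gcvs <- vapply(cands, `[[`, 0, "gcv")
      iDel <- which.min(gcvs)
      current <- current[-iDel]
      cur <- cands[[iDel]]
      trace <- c(trace, cur$gcv)
      if (cur$gcv < best$fit$gcv) best <- list(idx = current, fit = cur)
    }
  }

  keep <- terms[best$idx, , drop = FALSE]
  co <- best$fit$coef
  if (length(best$idx) > 0L) {
    keep$coefficient <- as.numeric(co[-1])
    intercept <- as.numeric(co[1])
  } else {
    keep$coefficient <- numeric(0)
    intercept <- as.numeric(co)
  }
  r2 <- if (tss > 0) max(0, min(1, 1 - best$fit$rss / tss)) else 0
  new("MarsModel", intercept = intercept, terms = keep,
      gcv = best$fit$gcv, r2 = r2,
      selectedTfs = unique(keep$variable), deletionTrace = trace,
      metadata = list(penalty = config@penalty, endspan = config@endspan,
                      linearOnly = config@linearOnly))
}

#' Fit a MARS model (forward pass + GCV pruning)
#'
#' @param X Predictor matrix (genes x TFs).
#' @param y Response vector.
#' @param config A \linkS4class{FitConfig}.
#' @return A \linkS4class{MarsModel}.
#' @export
marsFit <- function(X, y, config = FitConfig()) {
  fw <- marsForward(X, y, config)
  m <- marsPrune(fw$terms, X, y, config)
  m@metadata$forwardRssTrace <- fw$rssTrace
  m@metadata$forwardTerms <- fw$terms
  m
}

#' Predict transcript levels from a fitted MARS model
#'
#' @param object A \linkS4class{MarsModel}.
#' @param newdata Predictor matrix with the model's variables as columns.
#' @param ... Ignored.
#' @return Numeric vector of predictions.
#' @export
setMethod("predict", "MarsModel", function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  miss <- setdiff(object@terms$variable, colnames(newdata))
  if (length(miss)) stopf("newdata lacks variable(s): %s", paste(miss, collapse = ", "))
  if (nrow(object@terms) == 0L)
    return(rep(object@intercept, nrow(newdata)))
  drop(object@intercept +
         buildBasis(object@terms, newdata) %*% object@terms$coefficient)
})
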