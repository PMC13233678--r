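# Independent brute-force oracles the implementation is checked against.

# Grunwald-Letnikov weights via the generalized binomial coefficient:
# w_k = (-1)^k * C(alpha, k), equal to (-1)^k Gamma(a+1)/(k! Gamma(a-k+1)).
oracleGlWeights <- function(alpha, kMax) {
  k <- 0:kMax
  (-1)^k * choose(alpha, k)
}

# Formula evaluation mirroring the published expressions (NA at zero
# denominators), written independently of the package internals.
oracleIndex <- function(name, r1, r2, r3 = NULL) {
  div <- function(num, den) ifelse(abs(den) < 1e-12, NA_real_, num / den)
  switch(name,
    DI = r1 - r2,
    OSI = div((1 + 0.45) * (2 * r2 + 1), r1 + 0.45),
    SASI = div((1 + 0.5) * (r1 - r2), r1 + r2 + 0.5),
    TBI1 = div(r1, r2 * r3),
    TBI2 = div(r1, r2 + r3),
    TBI3 = div(r1 - r2, r1 + r3),
    TBI4 = div(r1 - r2, r1 - r3),
    TBI5 = div(r1 + r2, r3),
    TBI6 = div(r1 - r2, (r1 - r2) - (r1 - r3)),
    TBI7 = (r1 - r2) - (r1 - r3),
    stop("unknown formula ", name)
  )
}

# Plain nested-loop exhaustive search sharing the documented skip
# conventions: mask |den| < 1e-12; skip a tuple when masked samples
# exceed maxMaskFrac * n, fewer than 3 remain, or either variance
# term (m*Svv - Sv^2 form) falls below 1e-12; strict |r| improvement
# with exact ties resolved to the lexicographically smallest tuple.
oracleSearch <- function(name, X, y, arity, maxMaskFrac = 0.05) {
  B <- ncol(X)
  n <- nrow(X)
  best <- list(absR = -1, r = NA, i = NA, j = NA, k = NA)
  skipped <- 0
  ks <- if (arity == 3) seq_len(B) else 1L
  tupleStat <- function(v) {
    keep <- !is.na(v)
    if (sum(!keep) > floor(maxMaskFrac * n)) return(NULL)
    m <- sum(keep)
    if (m < 3) return(NULL)
    v <- v[keep]; yy <- y[keep]
    vv <- m * sum(v^2) - sum(v)^2
    vy <- m * sum(yy^2) - sum(yy)^2
    if (vv < 1e-12 || vy < 1e-12) return(NULL)
    (m * sum(v * yy) - sum(v) * sum(yy)) / sqrt(vv * vy)
  }
  lexLess <- function(a, b) { # a strictly before b
    for (d in seq_along(a)) {
      if (a[d] < b[d]) return(TRUE)
      if (a[d] > b[d]) return(FALSE)
    }
    FALSE
  }
  for (i in seq_len(B)) for (j in seq_len(B)) for (k in ks) {
    v <- oracleIndex(name, X[, i], X[, j],
      if (arity == 3) X[, k] else NULL)
    r <- tupleStat(v)
    if (is.null(r)) { skipped <- skipped + 1; next }
    a <- abs(r)
    if (a > best$absR ||
        (a == best$absR && lexLess(c(i, j, k),
          c(best$i, best$j, best$k)))) {
      best <- list(absR = a, r = r, i = i, j = j, k = k)
    }
  }
  best$nSkipped <- skipped
  best$nTuples <- B^arity
  best
}

# Pearson r of one formula at one fixed tuple, over unmasked samples.
oracleTupleR <- function(name, X, y, i, j, k = NULL) {
  v <- oracleIndex(name, X[, i], X[, j], if (!is.null(k)) X[, k])
  keep <- !is.na(v)
  stats::cor(v[keep], y[keep])
}

# Textbook R^2 / RMSE.
oracleMetrics <- function(y, yhat) {
  c(R2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2),
    RMSE = sqrt(mean((y - yhat)^2)))
}

# SPA projection chain from one start band via lm residuals: at each
# step add the band with maximal residual sum of squares after
# regressing (without intercept, columns pre-centered) on the selected
# columns. Returns the chain and the recorded norms.
oracleSpaChain <- function(X, start, kMax) {
  Xc <- scale(X, center = TRUE, scale = FALSE)
  chain <- start
  norms <- numeric(0)
  while (length(chain) < kMax) {
    sel <- Xc[, chain, drop = FALSE]
    resid2 <- vapply(seq_len(ncol(Xc)), function(b) {
      if (b %in% chain) return(-Inf)
      r <- stats::lm.fit(sel, Xc[, b])$residuals
      sum(r^2)
    }, numeric(1))
    if (max(resid2) < 1e-24) break
    nxt <- which.max(resid2)
    chain <- c(chain, nxt)
    norms <- c(norms, resid2[nxt])
  }
  list(chain = chain, norms = norms)
}
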