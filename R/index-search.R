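## Two- and three-band spectral indices with free wavelengths (Table-2
## style formulas) and the exhaustive correlation search that picks, per
## formula and per fractional order, the band combination most
## correlated with nitrogen. Ordered tuples spanning the full square /
## cube are searched; equality-singular tuples mask themselves out.

#' The multi-band spectral-index formula library
#'
#' Two-band: DI (difference), OSI, SASI. Three-band: TBI1-TBI7.
#' OSI is implemented literally as published — lambda2 in the numerator,
#' lambda1 in the denominator. The published TBI6 string is
#' mis-parenthesized; by default it is read as the three-band fraction
#' (R1-R2) / ((R1-R2) - (R1-R3)), with the literal transcription
#' (which collapses to 1 - (R1-R3)) available via
#' \code{literalTBI6 = TRUE} in the evaluators. TBI7 as published
#' simplifies algebraically to R3 - R2 and is kept literal.
#'
#' @return data.frame with columns \code{name}, \code{arity}, \code{id}.
#' @export
indexFormulas <- function() {
  data.frame(
    name = c("DI", "OSI", "SASI", paste0("TBI", 1:7)),
    arity = c(2L, 2L, 2L, rep(3L, 7)),
    id = 1:10,
    stringsAsFactors = FALSE
  )
}

.formulaId <- function(name, literalTBI6 = FALSE) {
  f <- indexFormulas()
  i <- match(name, f$name)
  if (is.na(i)) stop("unknown index formula: ", name)
  id <- f$id[i]
  if (name == "TBI6" && literalTBI6) id <- 11L
  list(id = id, arity = f$arity[i])
}

# R-side formula evaluation; returns values with NA where the
# denominator vanishes. Mirrors the compiled kernel.
.evalFormulaR <- function(id, r1, r2, r3 = NULL) {
  guard <- function(num, den) ifelse(abs(den) < 1e-12, NA_real_, num / den)
  switch(as.character(id),
    "1" = r1 - r2,
    "2" = guard(1.45 * (2 * r2 + 1), r1 + 0.45),
    "3" = guard(1.5 * (r1 - r2), r1 + r2 + 0.5),
    "4" = guard(r1, r2 * r3),
    "5" = guard(r1, r2 + r3),
    "6" = guard(r1 - r2, r1 + r3),
    "7" = guard(r1 - r2, r1 - r3),
    "8" = guard(r1 + r2, r3),
    "9" = guard(r1 - r2, (r1 - r2) - (r1 - r3)),
    "10" = (r1 - r2) - (r1 - r3),
    "11" = guard(r1 - r2, r1 - r2) - (r1 - r3),
    stop("unknown formula id ", id)
  )
}

#' Evaluate a spectral-index formula at a fixed band tuple
#'
#' @param formula formula name from \code{\link{indexFormulas}}.
#' @param d a \linkS4class{SpectraSet} or \linkS4class{DerivativeSpectra}.
#' @param bands wavelengths (nm), length = formula arity; resolved to the
#'   grid via \code{\link{nearestBand}}.
#' @param literalTBI6 use the literal published TBI6 transcription.
#' @return Per-sample numeric vector; samples hitting a zero denominator
#'   are NA.
#' @export
evalIndex <- function(formula, d, bands, literalTBI6 = FALSE) {
  fi <- .formulaId(formula, literalTBI6)
  if (length(bands) != fi$arity) {
    stop(formula, " takes ", fi$arity, " bands, got ", length(bands))
  }
  X <- reflectance(d)
  wl <- wavelengths(d)
  idx <- vapply(bands, function(w) nearestBand(wl, w), integer(1))
  as.numeric(.evalFormulaR(fi$id, X[, idx[1]], X[, idx[2]],
    if (fi$arity == 3) X[, idx[3]] else NULL))
}

# Band indices admitted to the search: strided, excluding edge-affected
# bands of a derivative transform.
.searchGrid <- function(d, stride) {
  B <- nBands(d)
  idx <- seq(1L, B, by = as.integer(stride))
  if (methods::is(d, "DerivativeSpectra")) idx <- idx[!edgeMask(d)[idx]]
  idx
}

#' Exhaustive best-band-combination search for one formula
#'
#' Evaluates the formula on every ordered band tuple of the strided grid,
#' computes the Pearson correlation with nitrogen over unmasked samples
#' (tuples with > \code{maxMaskFrac} masked samples, or with a degenerate
#' variance, are skipped), and returns the tuple maximizing |r|. Ties
#' keep the lexicographically smallest tuple.
#'
#' @param formula formula name from \code{\link{indexFormulas}}.
#' @param d a \linkS4class{SpectraSet} or \linkS4class{DerivativeSpectra}.
#' @param nitrogen response vector; defaults to the one stored in
#'   \code{d}.
#' @param stride search every stride-th band of the grid (default 2).
#' @param maxMaskFrac maximal tolerated fraction of masked samples.
#' @param literalTBI6 see \code{\link{indexFormulas}}.
#' @param surface for 2-band formulas, also return the full correlation
#'   surface as attribute \code{"surface"} (bands x bands, NA = skipped).
#' @return One-row data.frame: \code{formula}, \code{alpha},
#'   \code{lambda1..lambda3} (nm; lambda3 NA for 2-band formulas),
#'   \code{r}, \code{absR}, \code{nTuples}, \code{nSkipped},
#'   \code{stride}.
#' @export
searchBestCombination <- function(formula, d, nitrogen = NULL, stride = 2L,
                                  maxMaskFrac = 0.05, literalTBI6 = FALSE,
                                  surface = FALSE) {
  stopifnot(stride >= 1)
  fi <- .formulaId(formula, literalTBI6)
  if (is.null(nitrogen)) nitrogen <- .getNitrogen(d)
  if (is.null(nitrogen)) stop("nitrogen values are required for the search")
  idx <- .searchGrid(d, stride)
  X <- reflectance(d)[, idx, drop = FALSE]
  wl <- wavelengths(d)[idx]
  res <- if (fi$arity == 2) {
    .cppSearch2(X, nitrogen, fi$id, maxMaskFrac)
  } else {
    .cppSearch3(X, nitrogen, fi$id, maxMaskFrac)
  }
  if (res$nSkipped >= res$nTuples) {
    stop("all band combinations were skipped for ", formula)
  }
  alpha <- if (methods::is(d, "DerivativeSpectra")) derivOrder(d) else 0
  out <- data.frame(
    formula = formula, alpha = alpha,
    lambda1 = wl[res$i], lambda2 = wl[res$j],
    lambda3 = if (fi$arity == 3) wl[res$k] else NA_real_,
    r = res$r, absR = abs(res$r),
    nTuples = res$nTuples, nSkipped = res$nSkipped,
    stride = as.integer(stride), stringsAsFactors = FALSE
  )
  if (surface && fi$arity == 2) {
    surf <- .cppSurface2(X, nitrogen, fi$id, maxMaskFrac)
    dimnames(surf) <- list(wl, wl)
    attr(out, "surface") <- surf
  }
  out
}

#' Search all formulas across the fractional-order grid
#'
#' Runs \code{\link{searchBestCombination}} for every (formula, order)
#' pair, transforming the spectra once per order.
#'
#' @param s a \linkS4class{SpectraSet} with nitrogen attached.
#' @param formulas formula names (default: all ten).
#' @param orders fractional orders (default 0 to 2 by 0.25).
#' @param stride,maxMaskFrac,literalTBI6 passed through.
#' @param edgeBands edge bands to mask per transform.
#' @return data.frame with one row per (formula, order); the per-formula
#'   best rows (max |r| over orders; ties to the lower order) are in
#'   \code{attr(, "bestPerFormula")}.
#' @export
searchOverOrders <- function(s, formulas = indexFormulas()$name,
                             orders = fractionalOrderGrid(), stride = 2L,
                             maxMaskFrac = 0.05, literalTBI6 = FALSE,
                             edgeBands = 2L) {
  stopifnot(methods::is(s, "SpectraSet"))
  nit <- .getNitrogen(s)
  if (is.null(nit)) stop("nitrogen values are required for the search")
  rows <- list()
  for (a in orders) {
    d <- fodTransform(s, a, edgeBands = edgeBands)
    for (f in formulas) {
      rows[[length(rows) + 1]] <- searchBestCombination(
        f, d, nitrogen = nit, stride = stride,
        maxMaskFrac = maxMaskFrac, literalTBI6 = literalTBI6)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  best <- do.call(rbind, lapply(split(out, out$formula), function(g) {
    g[which.max(g$absR), , drop = FALSE]
  }))
  best <- best[match(intersect(formulas, best$formula), best$formula), ]
  rownames(best) <- NULL
  attr(out, "bestPerFormula") <- best
  out
}
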