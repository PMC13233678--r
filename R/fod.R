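## Grunwald-Letnikov fractional-order differentiation along the
## wavelength axis. Unit-step convention: no division by the grid
## spacing^alpha — band-index units; Pearson correlation downstream is
## scale invariant, so results are unaffected. The sum is left-sided and
## truncated at the series start (expanding window), so the first few
## bands are edge affected and flagged rather than padded.

#' Grunwald-Letnikov binomial weights
#'
#' The weight sequence w_0..w_kmax of the fractional difference of order
#' \code{alpha}: w_0 = 1, w_k = w_{k-1} (k - 1 - alpha)/k, equal to
#' (-1)^k Gamma(alpha+1) / (k! Gamma(alpha-k+1)). Integer orders recover
#' the usual finite-difference stencils ((1,-1) and (1,-2,1)).
#'
#' @param alpha derivative order.
#' @param kMax largest lag (>= 0).
#' @return Numeric vector of length \code{kMax + 1}.
#' @examples
#' glWeights(1, 3)   # 1 -1 0 0
#' glWeights(0.5, 3) # 1 -0.5 -0.125 -0.0625
#' @export
glWeights <- function(alpha, kMax) {
  stopifnot(kMax >= 0)
  w <- numeric(kMax + 1)
  w[1] <- 1
  if (kMax > 0) {
    for (k in seq_len(kMax)) w[k + 1] <- w[k] * (k - 1 - alpha) / k
  }
  w
}

#' Fractional-order derivative of a spectra set
#'
#' Applies the Grunwald-Letnikov transform band-wise: the value at band i
#' is sum_{k=0..i-1} w_k(alpha) R_{i-k}, the expanding-window left-sided
#' sum. alpha = 0 is the identity; alpha = 1 and 2 reproduce first and
#' second finite differences exactly (beyond the truncated start).
#'
#' @param s a \linkS4class{SpectraSet}.
#' @param alpha derivative order; the studied grid is [0, 2] — orders
#'   outside it require \code{allowOutside = TRUE}.
#' @param edgeBands how many leading bands to flag as edge affected
#'   (default 2; ignored at alpha = 0, where the transform is exact).
#' @param allowOutside permit alpha outside [0, 2].
#' @return A \linkS4class{DerivativeSpectra}.
#' @seealso \code{\link{glWeights}}, \code{\link{fractionalOrderGrid}}
#' @export
fodTransform <- function(s, alpha, edgeBands = 2L, allowOutside = FALSE) {
  stopifnot(methods::is(s, "SpectraSet"))
  if (!allowOutside && (alpha < 0 || alpha > 2)) {
    stop("alpha outside the studied [0, 2] grid; set allowOutside = TRUE")
  }
  X <- reflectance(s)
  B <- ncol(X)
  if (alpha == 0) {
    return(.newDerivativeSpectra(s, X, 0, rep(FALSE, B)))
  }
  w <- glWeights(alpha, B - 1)
  ## out[, i] = sum_k w_k X[, i-k]  <=>  out = X %*% M, M[j, i] = w[i-j]
  M <- matrix(0, B, B)
  for (i in seq_len(B)) M[seq_len(i), i] <- rev(w[seq_len(i)])
  out <- X %*% M
  mask <- rep(FALSE, B)
  mask[seq_len(min(edgeBands, B))] <- TRUE
  .newDerivativeSpectra(s, out, alpha, mask)
}

#' The fractional-order grid
#'
#' @param from,to,by grid limits and spacing; defaults 0 to 2 by 0.25.
#' @return Sorted unique numeric vector of orders, all within [0, 2]
#'   unless explicitly widened.
#' @export
fractionalOrderGrid <- function(from = 0, to = 2, by = 0.25) {
  g <- sort(unique(seq(from, to, by = by)))
  if (any(g < 0)) stop("orders must be non-negative")
  g
}

#' Band-wise Pearson correlation with nitrogen
#'
#' @param d a \linkS4class{DerivativeSpectra} or \linkS4class{SpectraSet}.
#' @param nitrogen reference values; defaults to \code{nitrogen(d)}.
#' @return data.frame with columns \code{wavelength}, \code{r} and
#'   \code{zeroVariance}; constant bands are reported as r = 0 with the
#'   flag set rather than NA, so downstream maxima stay well defined.
#' @export
bandCorrelations <- function(d, nitrogen = NULL) {
  stopifnot(methods::is(d, "SpectraSet"))
  if (is.null(nitrogen)) nitrogen <- .getNitrogen(d)
  if (is.null(nitrogen)) stop("nitrogen values are required")
  if (length(nitrogen) < 3) stop("need at least 3 samples for correlation")
  X <- reflectance(d)
  sds <- apply(X, 2, stats::sd)
  flat <- sds == 0
  r <- rep(0, ncol(X))
  if (any(!flat)) {
    r[!flat] <- as.numeric(stats::cor(X[, !flat, drop = FALSE], nitrogen))
  }
  data.frame(wavelength = wavelengths(d), r = r, zeroVariance = flat)
}
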