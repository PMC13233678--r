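## Shapley-value attribution of the stacked ensemble's base learners and
## meta-weighted fusion into one feature ranking. Tree bases use exact
## tree-path (TreeSHAP) attributions; linear bases use the exact linear
## decomposition coefficient * (x - mean(x)). Additivity — contributions
## plus baseline equal the prediction — holds for both.

#' Per-sample Shapley attributions of one base learner
#'
#' @param learner a fitted base learner (an element of
#'   \code{fit$bases} from \code{\link{fitStacking}}, or
#'   \code{fit$model} from \code{\link{fitSingle}} for tree/linear
#'   models).
#' @param X feature matrix the attributions are computed on (the
#'   background for linear baselines is \code{colMeans(X)}).
#' @return list with \code{phi} (n x p contribution matrix) and
#'   \code{baseline} (expected prediction, length-1): for every sample,
#'   \code{sum(phi[i, ]) + baseline == prediction[i]} within numerical
#'   tolerance.
#' @export
baseAttributions <- function(learner, X) {
  stopifnot(inherits(learner, "canopyn_learner"))
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- learner$featureNames
  X <- X[, learner$featureNames, drop = FALSE]
  if (learner$kind == "boost") {
    cm <- stats::predict(learner$fit, xgboost::xgb.DMatrix(X),
      predcontrib = TRUE)
    phi <- cm[, seq_len(ncol(cm) - 1L), drop = FALSE] # last col = bias
    colnames(phi) <- learner$featureNames
    baseline <- unname(cm[1, ncol(cm)])
  } else if (learner$kind == "linear") {
    centers <- colMeans(X)
    phi <- sweep(X, 2, centers) * rep(learner$coef, each = nrow(X))
    colnames(phi) <- learner$featureNames
    baseline <- sum(centers * learner$coef) + learner$intercept
  } else {
    stop("Shapley attribution supports tree and linear learners, not ",
      learner$name)
  }
  list(phi = phi, baseline = baseline)
}

#' Meta-weighted fusion of base-learner attributions
#'
#' Per-base global importance is the mean absolute per-sample
#' contribution of each feature; the fused score weights bases by the
#' absolute meta-learner coefficient (normalized to sum 1), or — behind
#' \code{weightScheme = "oofR2"} — by the out-of-fold R^2 of each base.
#'
#' @param stack a fitted \code{canopynStack}, or a list of attribution
#'   lists (as from \code{\link{baseAttributions}}) plus explicit
#'   \code{weights}.
#' @param X feature matrix (required when \code{stack} is a
#'   \code{canopynStack}).
#' @param weights optional explicit base weights (normalized
#'   internally), overriding the scheme.
#' @param weightScheme \code{"metaCoef"} (default) or \code{"oofR2"}.
#' @return data.frame with \code{feature}, \code{score}, \code{rank}
#'   (descending score), ordered by rank; per-base importances in
#'   \code{attr(, "perBase")}, weights in \code{attr(, "weights")}.
#' @export
fuseImportance <- function(stack, X = NULL, weights = NULL,
                           weightScheme = c("metaCoef", "oofR2")) {
  weightScheme <- match.arg(weightScheme)
  if (inherits(stack, "canopynStack")) {
    if (is.null(X)) stop("X is required to attribute a fitted stack")
    attrs <- lapply(stack$bases, function(b) baseAttributions(b, X))
    if (is.null(weights)) {
      if (weightScheme == "metaCoef") {
        weights <- abs(stack$meta$coef)
      } else {
        weights <- vapply(seq_len(ncol(stack$oof)), function(b) {
          r <- stats::cor(stack$oof[, b], stack$yTrain)
          if (is.na(r)) 0 else r^2
        }, numeric(1))
      }
      names(weights) <- names(stack$bases)
    }
  } else {
    attrs <- stack
    if (is.null(weights)) stop("explicit weights required for a raw list")
  }
  if (all(weights == 0)) stop("all base weights are zero; fusion undefined")
  w <- weights / sum(weights)
  perBase <- vapply(attrs, function(a) colMeans(abs(a$phi)),
    numeric(ncol(attrs[[1]]$phi)))
  wAligned <- if (!is.null(colnames(perBase)) && !is.null(names(w))) {
    w[colnames(perBase)]
  } else {
    w
  }
  fused <- as.numeric(perBase %*% wAligned)
  out <- data.frame(
    feature = rownames(perBase), score = fused,
    stringsAsFactors = FALSE
  )
  out$rank <- rank(-out$score, ties.method = "first")
  out <- out[order(out$rank), ]
  rownames(out) <- NULL
  attr(out, "perBase") <- perBase
  attr(out, "weights") <- w
  out
}
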