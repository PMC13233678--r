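## Model training and evaluation: 70/30 stratified split, grid search
## with 5-fold CV, six learners (latent-variable linear regression, SVR,
## random forest, GBDT, regularized XGBoost, stacking), calibration /
## prediction metrics, and per-pixel map prediction from a cube.

#' Calibration/prediction metrics
#'
#' R^2 = 1 - sum((y - yhat)^2) / sum((y - ybar)^2) and
#' RMSE = sqrt(sum((y - yhat)^2) / n), computed exactly in these forms.
#'
#' @param observed,predicted numeric vectors of equal length >= 2.
#' @return Named numeric vector \code{c(R2, RMSE)}.
#' @examples
#' computeMetrics(c(1, 2, 3), c(1.1, 1.9, 3.2)) # R2 = 0.97
#' @export
computeMetrics <- function(observed, predicted) {
  if (length(observed) != length(predicted)) stop("length mismatch")
  if (length(observed) < 2) stop("need at least 2 observations")
  sst <- sum((observed - mean(observed))^2)
  if (sst == 0) stop("observed values are constant; R^2 undefined")
  sse <- sum((observed - predicted)^2)
  c(R2 = 1 - sse / sst, RMSE = sqrt(sse / length(observed)))
}

.evalMetrics <- function(yTrain, pTrain, yTest, pTest) {
  mc <- computeMetrics(yTrain, pTrain)
  mp <- computeMetrics(yTest, pTest)
  data.frame(R2C = mc[["R2"]], RMSEC = mc[["RMSE"]],
    R2P = mp[["R2"]], RMSEP = mp[["RMSE"]])
}

#' Stratified train/test split
#'
#' Random split stratified by nitrogen quartile so calibration and
#' prediction sets share the response distribution. Falls back to a
#' simple random split (with a warning) when strata are too small.
#'
#' @param y nitrogen vector (or a \linkS4class{SpectraSet}).
#' @param ratio training fraction, in (0, 1); default 0.7.
#' @param seed integer seed.
#' @return list with integer index vectors \code{train} and \code{test}
#'   (disjoint, exhaustive).
#' @export
splitDataset <- function(y, ratio = 0.7, seed = 1L) {
  if (methods::is(y, "SpectraSet")) y <- .getNitrogen(y)
  if (ratio <= 0 || ratio >= 1) stop("ratio must be in (0, 1)")
  n <- length(y)
  set.seed(seed)
  strata <- tryCatch(
    cut(y, stats::quantile(y, 0:4 / 4), include.lowest = TRUE,
      labels = FALSE),
    error = function(e) NULL)
  if (is.null(strata) || min(table(strata)) < 2) {
    warning("strata too small; falling back to a simple random split")
    train <- sort(sample.int(n, round(ratio * n)))
  } else {
    train <- sort(unlist(lapply(split(seq_len(n), strata), function(id) {
      sample(id, round(ratio * length(id)))
    }), use.names = FALSE))
  }
  list(train = train, test = setdiff(seq_len(n), train))
}

#' Default hyperparameter grids
#'
#' Small literature-standard search grids per learner (tree counts
#' 100-400, depths 3-5, learning rates 0.05-0.1, SVR cost/gamma log
#' grids, 2-10 latent components). All overridable in
#' \code{\link{fitSingle}}.
#'
#' @param model learner name.
#' @return data.frame, one row per grid point.
#' @export
defaultGrid <- function(model) {
  switch(model,
    plsr = data.frame(ncomp = c(2L, 4L, 6L, 8L, 10L)),
    svr = expand.grid(cost = c(1, 10, 100), gamma = c(0.001, 0.01, 0.1)),
    rf = expand.grid(num.trees = c(200L, 400L), min.node.size = c(3L, 5L)),
    gbdt = ,
    xgb = expand.grid(nrounds = c(100L, 200L), max_depth = c(3L, 5L),
      eta = c(0.05, 0.1)),
    ridge = data.frame(lambda = c(0.01, 0.1, 1, 10)),
    bayesridge = data.frame(dummy = 0),
    stop("no default grid for ", model)
  )
}

#' Fit one learner with grid search and k-fold CV
#'
#' The grid point with minimal mean cross-validated RMSE on the training
#' folds wins (ties: first row); the model is refit on the full training
#' set and scored on both sets.
#'
#' @param model one of \code{"plsr"}, \code{"svr"}, \code{"rf"},
#'   \code{"gbdt"}, \code{"xgb"}, \code{"ridge"}.
#' @param X feature matrix (samples x features).
#' @param y nitrogen vector (mg/g).
#' @param split a \code{\link{splitDataset}} result.
#' @param grid data.frame of candidate hyperparameters (default
#'   \code{\link{defaultGrid}}); a one-row grid is a direct fit.
#' @param folds CV folds within the training set.
#' @param seed integer seed (folds and stochastic learners).
#' @return list (class \code{canopynFit}): \code{model}, \code{params},
#'   \code{cvTable} (grid + mean CV-RMSE), \code{metrics} (one-row
#'   data.frame R2C/RMSEC/R2P/RMSEP), \code{split}.
#' @export
fitSingle <- function(model, X, y, split, grid = NULL, folds = 5L,
                      seed = 1L) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  if (is.null(grid)) grid <- defaultGrid(model)
  if (nrow(grid) == 0) stop("empty hyperparameter grid")
  Xtr <- X[split$train, , drop = FALSE]
  ytr <- y[split$train]
  id <- .makeFolds(length(ytr), min(folds, length(ytr)), seed)
  cvRmse <- vapply(seq_len(nrow(grid)), function(g) {
    params <- as.list(grid[g, , drop = FALSE])
    pred <- numeric(length(ytr))
    for (f in sort(unique(id))) {
      tr <- id != f
      obj <- .fitLearner(model, Xtr[tr, , drop = FALSE], ytr[tr],
        params, seed)
      pred[!tr] <- .predictLearner(obj, Xtr[!tr, , drop = FALSE])
    }
    sqrt(mean((ytr - pred)^2))
  }, numeric(1))
  best <- which.min(cvRmse)
  params <- as.list(grid[best, , drop = FALSE])
  obj <- .fitLearner(model, Xtr, ytr, params, seed)
  pTrain <- .predictLearner(obj, Xtr)
  pTest <- .predictLearner(obj, X[split$test, , drop = FALSE])
  out <- list(
    model = obj, params = params,
    cvTable = cbind(grid, cvRmse = cvRmse),
    metrics = .evalMetrics(ytr, pTrain, y[split$test], pTest),
    split = split
  )
  class(out) <- "canopynFit"
  out
}

#' @export
predict.canopynFit <- function(object, newdata, ...) {
  .predictLearner(object$model, newdata)
}

#' Stacked-ensemble configuration
#'
#' Base learners: regularized gradient-boosted trees ("xgb"), classical
#' gradient-boosting trees ("gbdt") and L2-penalized linear regression
#' ("ridge"); meta-learner: Bayesian ridge regression fit on strictly
#' out-of-fold base predictions.
#'
#' @param baseLearners character vector of learner names (>= 2).
#' @param folds out-of-fold folds (>= 2).
#' @param baseParams named list of parameter lists per base learner.
#' @return list of class \code{StackingSpec}.
#' @export
stackingSpec <- function(baseLearners = c("xgb", "gbdt", "ridge"),
                         folds = 5L, baseParams = list()) {
  if (length(baseLearners) < 2) stop("need at least 2 base learners")
  if (folds < 2) stop("need at least 2 folds")
  structure(list(baseLearners = baseLearners, folds = as.integer(folds),
    baseParams = baseParams), class = "StackingSpec")
}

#' Fit the stacked ensemble
#'
#' Train-set meta-features are strictly out-of-fold base predictions
#' (each sample's meta-feature comes from bases that never saw it); the
#' Bayesian ridge meta-learner is fit on that OOF matrix; bases are then
#' refit on the full training set to produce test-time meta-features.
#'
#' @param X feature matrix; @param y nitrogen vector.
#' @param split a \code{\link{splitDataset}} result.
#' @param spec a \code{\link{stackingSpec}}.
#' @param seed integer seed.
#' @return list (class \code{canopynStack}): \code{bases} (refit on full
#'   train), \code{meta} (with coefficients), \code{oof} (n_train x
#'   n_bases matrix), \code{foldid}, \code{metrics}, \code{split},
#'   \code{spec}.
#' @export
fitStacking <- function(X, y, split, spec = stackingSpec(), seed = 1L) {
  stopifnot(inherits(spec, "StackingSpec"))
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  Xtr <- X[split$train, , drop = FALSE]
  ytr <- y[split$train]
  if (spec$folds > length(ytr)) stop("more folds than training samples")
  foldid <- .makeFolds(length(ytr), spec$folds, seed)
  oof <- matrix(NA_real_, length(ytr), length(spec$baseLearners),
    dimnames = list(NULL, spec$baseLearners))
  for (b in spec$baseLearners) {
    for (f in sort(unique(foldid))) {
      tr <- foldid != f
      obj <- .fitLearner(b, Xtr[tr, , drop = FALSE], ytr[tr],
        spec$baseParams[[b]] %||% list(), seed)
      oof[!tr, b] <- .predictLearner(obj, Xtr[!tr, , drop = FALSE])
    }
  }
  meta <- .fitLearner("bayesridge", oof, ytr, list(), seed)
  bases <- lapply(stats::setNames(spec$baseLearners, spec$baseLearners),
    function(b) {
      .fitLearner(b, Xtr, ytr, spec$baseParams[[b]] %||% list(), seed)
    })
  Xte <- X[split$test, , drop = FALSE]
  baseTest <- vapply(bases, function(b) .predictLearner(b, Xte),
    numeric(length(split$test)))
  baseTrain <- vapply(bases, function(b) .predictLearner(b, Xtr),
    numeric(length(split$train)))
  pTrain <- .predictLearner(meta, baseTrain)
  pTest <- .predictLearner(meta, baseTest)
  out <- list(
    bases = bases, meta = meta, oof = oof, foldid = foldid, yTrain = ytr,
    metrics = .evalMetrics(ytr, pTrain, y[split$test], pTest),
    split = split, spec = spec
  )
  class(out) <- "canopynStack"
  out
}

#' @export
predict.canopynStack <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  mf <- vapply(object$bases, function(b) .predictLearner(b, newdata),
    numeric(nrow(newdata)))
  if (is.null(dim(mf))) {
    mf <- matrix(mf, nrow = 1, dimnames = list(NULL, names(object$bases)))
  }
  .predictLearner(object$meta, mf)
}

## ---- feature recipes -----------------------------------------------------

#' Feature-construction recipe
#'
#' Captures how a design matrix is built from raw spectra — the selected
#' band subset, the screened vegetation indices, and the optimized
#' multi-band spectral indices (formula + order + band tuple) — so the
#' identical construction can be replayed on new tabular spectra or on
#' every pixel of a cube.
#'
#' @param selection a \linkS4class{SelectionResult}, or NULL.
#' @param viNames names of screened vegetation indices, or NULL.
#' @param siBest data.frame of optimized index rows (as produced by
#'   \code{attr(searchOverOrders(...), "bestPerFormula")}), or NULL.
#' @param literatureForms,literalTBI6,edgeBands evaluation options.
#' @return list of class \code{FeatureRecipe}.
#' @export
featureRecipe <- function(selection = NULL, viNames = NULL, siBest = NULL,
                          literatureForms = FALSE, literalTBI6 = FALSE,
                          edgeBands = 2L) {
  structure(list(selection = selection, viNames = viNames,
    siBest = siBest, literatureForms = literatureForms,
    literalTBI6 = literalTBI6, edgeBands = as.integer(edgeBands)),
    class = "FeatureRecipe")
}

#' Build a design matrix from a recipe
#'
#' @param s a \linkS4class{SpectraSet}.
#' @param recipe a \code{\link{featureRecipe}}.
#' @param sets which blocks to include: any of \code{"spectra"},
#'   \code{"vi"}, \code{"si"}; fused sets are column-wise concatenations.
#' @return Numeric matrix, samples x features, with named columns
#'   (\code{B<wl>}, \code{VI_<name>}, \code{SI_<formula>}).
#' @export
buildFeatures <- function(s, recipe, sets = c("spectra", "vi", "si")) {
  stopifnot(inherits(recipe, "FeatureRecipe"))
  blocks <- list()
  if ("spectra" %in% sets) {
    if (is.null(recipe$selection)) stop("recipe has no band selection")
    idx <- selectedBands(recipe$selection)
    m <- reflectance(s)[, idx, drop = FALSE]
    colnames(m) <- paste0("B", wavelengths(s)[idx])
    blocks$spectra <- m
  }
  if ("vi" %in% sets) {
    if (is.null(recipe$viNames)) stop("recipe has no vegetation indices")
    vt <- computeVITable(s, literatureForms = recipe$literatureForms)
    m <- vt[, recipe$viNames, drop = FALSE]
    colnames(m) <- paste0("VI_", recipe$viNames)
    blocks$vi <- m
  }
  if ("si" %in% sets) {
    if (is.null(recipe$siBest)) stop("recipe has no spectral indices")
    sb <- recipe$siBest
    cache <- list()
    m <- matrix(NA_real_, nSamples(s), nrow(sb))
    colnames(m) <- paste0("SI_", sb$formula)
    for (i in seq_len(nrow(sb))) {
      key <- as.character(sb$alpha[i])
      if (is.null(cache[[key]])) {
        cache[[key]] <- fodTransform(s, sb$alpha[i],
          edgeBands = recipe$edgeBands)
      }
      bands <- c(sb$lambda1[i], sb$lambda2[i], sb$lambda3[i])
      bands <- bands[!is.na(bands)]
      m[, i] <- evalIndex(sb$formula[i], cache[[key]], bands,
        literalTBI6 = recipe$literalTBI6)
    }
    if (anyNA(m)) { # isolated singular pixels: impute the column median
      for (j in seq_len(ncol(m))) {
        m[is.na(m[, j]), j] <- stats::median(m[, j], na.rm = TRUE)
      }
    }
    blocks$si <- m
  }
  do.call(cbind, blocks)
}

.featureSetDefs <- list(
  Spectra = "spectra", VIs = "vi", SIs = "si",
  `Spectra-VIs` = c("spectra", "vi"), `Spectra-SIs` = c("spectra", "si"),
  `Spectra-VIs-SIs` = c("spectra", "vi", "si")
)

#' Evaluate models across the six feature sets
#'
#' Builds the six canonical feature sets (Spectra, VIs, SIs and their
#' fusions) from one recipe and scores every requested model on each,
#' reusing a single train/test split throughout.
#'
#' @param s a \linkS4class{SpectraSet} with nitrogen attached.
#' @param recipe a \code{\link{featureRecipe}} with all three blocks.
#' @param models learner names; \code{"stacking"} uses
#'   \code{\link{fitStacking}}.
#' @param featureSets subset of the six set names (default: all).
#' @param split optional precomputed split; otherwise 70/30 from
#'   \code{seed}.
#' @param grids named list of grids per model (default
#'   \code{\link{defaultGrid}}).
#' @param stacking a \code{\link{stackingSpec}}.
#' @param folds,seed CV folds and seed.
#' @param returnFits also return the fitted models (attribute
#'   \code{"fits"}).
#' @return data.frame: one row per feature set x model with the four
#'   metrics.
#' @export
evaluateFeatureSets <- function(s, recipe,
                                models = c("plsr", "svr", "rf", "gbdt",
                                  "xgb", "stacking"),
                                featureSets = names(.featureSetDefs),
                                split = NULL, grids = list(),
                                stacking = stackingSpec(), folds = 5L,
                                seed = 1L, returnFits = FALSE) {
  y <- .getNitrogen(s)
  if (is.null(y)) stop("nitrogen values are required")
  if (is.null(split)) split <- splitDataset(y, 0.7, seed)
  rows <- list()
  fits <- list()
  for (fs in featureSets) {
    X <- buildFeatures(s, recipe, .featureSetDefs[[fs]])
    for (m in models) {
      fit <- if (m == "stacking") {
        fitStacking(X, y, split, stacking, seed)
      } else {
        fitSingle(m, X, y, split, grid = grids[[m]], folds = folds,
          seed = seed)
      }
      rows[[length(rows) + 1]] <- cbind(
        data.frame(featureSet = fs, model = m, stringsAsFactors = FALSE),
        fit$metrics)
      if (returnFits) fits[[paste(fs, m, sep = ":")]] <- fit
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (returnFits) attr(out, "fits") <- fits
  out
}

#' Predict a nitrogen map from a reflectance cube
#'
#' Applies the training-time feature recipe to every pixel and predicts
#' with the fitted model; a cube assembled from tabular spectra
#' reproduces the tabular predictions exactly.
#'
#' @param fit a \code{canopynFit} or \code{canopynStack}.
#' @param cube a \linkS4class{ReflectanceCube} on the training grid.
#' @param recipe the training \code{\link{featureRecipe}}.
#' @param sets feature blocks the model was trained on.
#' @param trainWavelengths wavelength grid used in training, for the
#'   coverage check (optional).
#' @return Numeric matrix rows x cols of nitrogen (mg/g).
#' @export
predictCube <- function(fit, cube, recipe,
                        sets = c("spectra", "vi", "si"),
                        trainWavelengths = NULL) {
  stopifnot(methods::is(cube, "ReflectanceCube"))
  if (!is.null(trainWavelengths) &&
      !isTRUE(all.equal(trainWavelengths, cube@wavelengths))) {
    stop("cube wavelength grid does not match the training grid")
  }
  s <- cubeToSpectra(cube)
  X <- buildFeatures(s, recipe, sets)
  p <- stats::predict(fit, X)
  d <- dim(cube@values)
  matrix(p, d[1], d[2], byrow = TRUE)
}
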