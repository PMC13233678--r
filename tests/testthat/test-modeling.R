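test_that("metrics follow the printed formulas exactly", {
  m <- computeMetrics(c(1, 2, 3), c(1.1, 1.9, 3.2))
  expect_equal(unname(m["R2"]), 0.97) # SSE = 0.06, SST = 2
  expect_equal(unname(m["RMSE"]), sqrt(0.06 / 3))
  y <- c(2, 4, 7, 5)
  expect_equal(unname(computeMetrics(y, y)), c(1, 0))
  expect_equal(unname(computeMetrics(y, rep(mean(y), 4))["R2"]), 0)
  expect_error(computeMetrics(rep(1, 3), c(1, 2, 3)), "constant")
  expect_error(computeMetrics(1, 1), "2 observations")
  set.seed(2)
  yy <- rnorm(50)
  pp <- yy + rnorm(50, 0, 0.3)
  expect_equal(unname(computeMetrics(yy, pp)),
    unname(oracleMetrics(yy, pp)), tolerance = 1e-12)
})

test_that("the stratified split partitions 200 samples into 140/60", {
  set.seed(5)
  y <- rnorm(200, 19, 1)
  sp <- splitDataset(y, 0.7, seed = 11)
  expect_length(sp$train, 140)
  expect_length(sp$test, 60)
  expect_setequal(c(sp$train, sp$test), 1:200)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_identical(splitDataset(y, 0.7, seed = 11), sp)
  # roughly 70% of each nitrogen quartile lands in the training set
  q <- cut(y, quantile(y, 0:4 / 4), include.lowest = TRUE, labels = FALSE)
  frac <- tapply(seq_along(y) %in% sp$train, q, mean)
  expect_true(all(abs(frac - 0.7) < 0.03))
  expect_warning(splitDataset(c(1, 2, 3, 4), 0.5, 1), "simple random")
  expect_error(splitDataset(y, 1.2), "ratio")
})

test_that("a singleton grid is a direct fit and grids pick the CV minimum", {
  set.seed(8)
  n <- 60
  X <- matrix(rnorm(n * 8), n, 8)
  y <- X %*% rnorm(8) + rnorm(n, 0, 0.3)
  sp <- splitDataset(y, 0.7, 3)
  one <- fitSingle("plsr", X, y, sp, grid = data.frame(ncomp = 3), seed = 4)
  direct <- canopyn:::.fitLearner("plsr", X[sp$train, ], y[sp$train],
    list(ncomp = 3), seed = 4)
  expect_equal(predict(one, X[sp$test, ]),
    canopyn:::.predictLearner(direct, X[sp$test, ]))

  fit <- fitSingle("plsr", X, y, sp, grid = data.frame(ncomp = c(1, 2, 4, 6)),
    seed = 4)
  # exhaustive re-evaluation of every grid point with the same folds
  id <- canopyn:::.makeFolds(length(sp$train), 5, 4)
  rmse <- vapply(c(1, 2, 4, 6), function(nc) {
    pred <- numeric(length(sp$train))
    for (f in 1:5) {
      obj <- canopyn:::.fitLearner("plsr",
        X[sp$train[id != f], , drop = FALSE], y[sp$train[id != f]],
        list(ncomp = nc), seed = 4)
      pred[id == f] <- canopyn:::.predictLearner(obj,
        X[sp$train[id == f], , drop = FALSE])
    }
    sqrt(mean((y[sp$train] - pred)^2))
  }, numeric(1))
  expect_equal(fit$params$ncomp, c(1, 2, 4, 6)[which.min(rmse)])
  expect_equal(unname(fit$cvTable$cvRmse), unname(rmse), tolerance = 1e-10)
  # seeded repeats pick the same parameters
  expect_identical(fitSingle("xgb", X, y, sp,
    grid = expand.grid(nrounds = c(20L, 40L), max_depth = c(2L, 3L)),
    seed = 9)$params,
  fitSingle("xgb", X, y, sp,
    grid = expand.grid(nrounds = c(20L, 40L), max_depth = c(2L, 3L)),
    seed = 9)$params)
  expect_error(fitSingle("plsr", X, y, sp, grid = data.frame()), "empty")
})

test_that("every learner trains and predicts finite values", {
  set.seed(12)
  n <- 50
  X <- matrix(rnorm(n * 6), n, 6)
  y <- 19 + X[, 2] - 0.5 * X[, 5] + rnorm(n, 0, 0.2)
  sp <- splitDataset(y, 0.7, 2)
  for (m in c("plsr", "svr", "rf", "gbdt", "xgb", "ridge")) {
    fit <- fitSingle(m, X, y, sp, grid = defaultGrid(m)[1, , drop = FALSE],
      seed = 3)
    expect_true(all(is.finite(unlist(fit$metrics))), label = m)
    expect_gte(fit$metrics$R2C, 0)
  }
})

test_that("stacking builds leakage-free out-of-fold meta-features", {
  set.seed(19)
  n <- 80
  X <- matrix(rnorm(n * 5), n, 5)
  y <- 19 + X %*% c(1, -0.5, 0.3, 0, 0.2) + rnorm(n, 0, 0.2)
  y <- as.numeric(y)
  sp <- splitDataset(y, 0.7, 6)
  st <- fitStacking(X, y, sp, stackingSpec(folds = 4), seed = 2)
  expect_identical(dim(st$oof), c(length(sp$train), 3L))
  expect_identical(colnames(st$oof), c("xgb", "gbdt", "ridge"))
  expect_false(anyNA(st$oof))
  # corrupt fold 2's labels: fold 2's OOF rows must be unchanged,
  # because the models that produced them never saw fold 2
  y2 <- y
  y2[sp$train[st$foldid == 2]] <- y2[sp$train[st$foldid == 2]] + 5
  st2 <- fitStacking(X, y2, sp, stackingSpec(folds = 4), seed = 2)
  expect_identical(st2$foldid, st$foldid)
  expect_equal(st2$oof[st$foldid == 2, ], st$oof[st$foldid == 2, ])
  expect_false(isTRUE(all.equal(st2$oof[st$foldid != 2, ],
    st$oof[st$foldid != 2, ])))
  expect_error(fitStacking(X, y, sp, stackingSpec(folds = 200)), "folds")
  expect_error(stackingSpec(baseLearners = "xgb"), "2 base learners")
})

test_that("the Bayesian ridge meta-learner recovers an identity feed", {
  set.seed(25)
  y <- rnorm(100, 19, 1.2)
  feed <- cbind(xgb = y, gbdt = y, ridge = y)
  meta <- canopyn:::.fitLearner("bayesridge", feed, y)
  pred <- canopyn:::.predictLearner(meta, feed)
  expect_gt(unname(computeMetrics(y, pred)["R2"]), 0.99)
})

test_that("the feature-set grid covers 6 sets x 6 models with shared split", {
  sim <- simulateCanopy(syntheticConfig(nPerTreatment = 15,
    wavelengths = seq(400, 1000, 10)))
  s <- sim$spectra
  sel <- spaSelect(s, 3, 6)
  best <- attr(searchOverOrders(s, formulas = c("DI", "TBI2"),
    orders = c(0, 1), stride = 2), "bestPerFormula")
  recipe <- featureRecipe(selection = sel,
    viNames = c("MTCI", "NDVI", "REP"), siBest = best)
  Xall <- buildFeatures(s, recipe)
  expect_equal(ncol(Xall), length(selectedBands(sel)) + 3 + 2)
  singleton <- lapply(
    c(plsr = "plsr", svr = "svr", rf = "rf", gbdt = "gbdt", xgb = "xgb"),
    function(m) defaultGrid(m)[1, , drop = FALSE])
  grid <- evaluateFeatureSets(s, recipe, grids = singleton, seed = 3)
  expect_equal(nrow(grid), 36)
  expect_setequal(unique(grid$featureSet),
    c("Spectra", "VIs", "SIs", "Spectra-VIs", "Spectra-SIs",
      "Spectra-VIs-SIs"))
  expect_true(all(is.finite(grid$R2P)))
  expect_true(all(grid$RMSEP >= 0))
})

test_that("cube prediction replays the tabular pipeline per pixel", {
  sim <- simulateCanopy(syntheticConfig(nPerTreatment = 10,
    wavelengths = seq(400, 1000, 10)))
  s <- sim$spectra
  sel <- spaSelect(s, 2, 4)
  recipe <- featureRecipe(selection = sel, viNames = c("MTCI", "NDVI"))
  X <- buildFeatures(s, recipe, sets = c("spectra", "vi"))
  sp <- splitDataset(s, 0.7, 5)
  fit <- fitSingle("plsr", X, nitrogen(s), sp,
    grid = data.frame(ncomp = 3), seed = 5)
  # a cube assembled from the test-set spectra reproduces predictions
  testSpec <- reflectance(s)[sp$test, , drop = FALSE]
  nr <- 4
  nc <- length(sp$test) / 4
  cube <- spectraToCube(SpectraSet(testSpec, wavelengths(s)), nr, nc)
  mp <- predictCube(fit, cube, recipe, sets = c("spectra", "vi"),
    trainWavelengths = wavelengths(s))
  expect_identical(dim(mp), c(4L, 3L))
  expect_equal(as.numeric(t(mp)),
    unname(predict(fit, X[sp$test, , drop = FALSE])))
  # identical pixels give a constant map
  one <- reflectance(s)[rep(1, 6), , drop = FALSE]
  cube1 <- spectraToCube(SpectraSet(one, wavelengths(s)), 2, 3)
  mp1 <- predictCube(fit, cube1, recipe, sets = c("spectra", "vi"))
  expect_equal(max(mp1) - min(mp1), 0)
  expect_equal(unname(mp1[1, 1]),
    unname(predict(fit, X[1, , drop = FALSE])))
  expect_error(predictCube(fit, cube1, recipe,
    trainWavelengths = seq(400, 1000, 5)), "grid")
})
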