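test_that("attributions are additive for tree and linear learners", {
  set.seed(33)
  n <- 60
  X <- matrix(rnorm(n * 6), n, 6,
    dimnames = list(NULL, paste0("f", 1:6)))
  y <- 19 + 1.2 * X[, 1] - 0.7 * X[, 4] + rnorm(n, 0, 0.2)
  for (m in c("xgb", "gbdt", "ridge", "plsr")) {
    obj <- canopyn:::.fitLearner(m, X, y, list(), seed = 2)
    at <- baseAttributions(obj, X)
    pred <- canopyn:::.predictLearner(obj, X)
    relErr <- max(abs(rowSums(at$phi) + at$baseline - pred)) /
      mean(abs(pred))
    expect_lt(relErr, 1e-6)
    expect_identical(colnames(at$phi), colnames(X))
  }
  svr <- canopyn:::.fitLearner("svr", X, y, list(), seed = 2)
  expect_error(baseAttributions(svr, X), "supports")
})

test_that("null and duplicated features attribute as symmetry demands", {
  set.seed(35)
  n <- 50
  X <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("f", 1:4)))
  X[, 3] <- 0.7 # zero variance
  y <- 19 + X[, 1] + rnorm(n, 0.2)
  for (m in c("xgb", "ridge")) {
    obj <- canopyn:::.fitLearner(m, X, y, list(), seed = 1)
    at <- baseAttributions(obj, X)
    expect_equal(unname(at$phi[, 3]), rep(0, n), label = m)
  }
  # exactly duplicated columns with a ridge penalty share the weight
  X2 <- cbind(a = X[, 1], b = X[, 1], c = X[, 2])
  obj <- canopyn:::.fitLearner("ridge", X2, y, list(lambda = 0.5))
  at <- baseAttributions(obj, X2)
  expect_equal(at$phi[, "a"], at$phi[, "b"], tolerance = 1e-4)
})

test_that("fusion weights combine per-base importances as specified", {
  phiA <- matrix(0, 4, 3, dimnames = list(NULL, c("x", "y", "z")))
  phiA[, "x"] <- c(1, -1, 1, -1) # mean |phi| = 1 on feature x
  phiB <- matrix(0, 4, 3, dimnames = list(NULL, c("x", "y", "z")))
  phiB[, "y"] <- c(1, 1, -1, -1)
  attrs <- list(A = list(phi = phiA, baseline = 0),
    B = list(phi = phiB, baseline = 0))
  fused <- fuseImportance(attrs, weights = c(A = 0.75, B = 0.25))
  expect_equal(fused$score[match(c("x", "y", "z"), fused$feature)],
    c(0.75, 0.25, 0))
  expect_identical(fused$feature, c("x", "y", "z"))
  # supplying the bases in the other order changes nothing
  fused2 <- fuseImportance(list(B = attrs$B, A = attrs$A),
    weights = c(B = 0.25, A = 0.75))
  expect_equal(fused2$score, fused$score)
  # a zero-weight base contributes nothing
  fused3 <- fuseImportance(attrs, weights = c(A = 1, B = 0))
  expect_equal(fused3$score[fused3$feature == "y"], 0)
  # a single base reproduces its own ranking
  solo <- fuseImportance(attrs["A"], weights = c(A = 1))
  expect_identical(solo$feature[1], "x")
  expect_error(fuseImportance(attrs, weights = c(A = 0, B = 0)), "zero")
})

test_that("a fitted stack fuses via meta coefficients or OOF R^2", {
  set.seed(37)
  n <- 70
  X <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("f", 1:5)))
  y <- as.numeric(19 + X %*% c(2, 0, 0, -1, 0) + rnorm(n, 0, 0.3))
  sp <- splitDataset(y, 0.7, 4)
  st <- fitStacking(X, y, sp, seed = 3)
  fm <- fuseImportance(st, X[sp$train, ])
  expect_setequal(fm$feature, colnames(X))
  expect_equal(sum(attr(fm, "weights")), 1)
  expect_identical(fm$rank, seq_len(5))
  # the informative features dominate the fused ranking
  expect_true(all(c("f1", "f4") %in% fm$feature[1:3]))
  fo <- fuseImportance(st, X[sp$train, ], weightScheme = "oofR2")
  expect_equal(sum(attr(fo, "weights")), 1)
})
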