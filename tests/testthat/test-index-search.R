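test_that("index evaluation honours the published algebra", {
  s <- toySpectra(10, 30, seed = 6)
  wl <- wavelengths(s)
  X <- reflectance(s)
  # DI at equal bands is identically zero
  expect_equal(evalIndex("DI", s, c(wl[3], wl[3])), rep(0, 10))
  # TBI4 with lambda1 = lambda3 hits a zero denominator everywhere
  expect_true(all(is.na(evalIndex("TBI4", s, c(wl[2], wl[5], wl[2])))))
  # TBI7 collapses to R3 - R2
  expect_equal(evalIndex("TBI7", s, wl[c(1, 4, 9)]),
    unname(X[, 9] - X[, 4]))
  # SASI antisymmetry, TBI5 swap symmetry
  expect_equal(evalIndex("SASI", s, wl[c(2, 7)]),
    -evalIndex("SASI", s, wl[c(7, 2)]))
  expect_equal(evalIndex("TBI5", s, wl[c(2, 7, 11)]),
    evalIndex("TBI5", s, wl[c(7, 2, 11)]))
  expect_error(evalIndex("TBI1", s, wl[1:2]), "3 bands")
  expect_error(evalIndex("nope", s, wl[1:2]), "unknown")
})

test_that("values agree with an independent formula oracle", {
  s <- toySpectra(12, 25, seed = 14)
  wl <- wavelengths(s)
  X <- reflectance(s)
  f <- indexFormulas()
  set.seed(3)
  for (row in seq_len(nrow(f))) {
    bands <- sample(25, f$arity[row])
    got <- evalIndex(f$name[row], s, wl[bands])
    want <- oracleIndex(f$name[row], X[, bands[1]], X[, bands[2]],
      if (f$arity[row] == 3) X[, bands[3]] else NULL)
    expect_equal(got, unname(want), tolerance = 1e-12,
      label = f$name[row])
  }
})

test_that("the compiled search equals the nested-loop oracle on a 20-band grid", {
  set.seed(41)
  n <- 15
  B <- 20
  X <- matrix(runif(n * B, 0.05, 0.95), n, B)
  y <- 19 + 1.5 * X[, 8] - X[, 15] + rnorm(n, 0, 0.2)
  s <- SpectraSet(X, seq(500, by = 2, length.out = B), nitrogen = y)
  f <- indexFormulas()
  wlGrid <- wavelengths(s)
  for (row in seq_len(nrow(f))) {
    nm <- f$name[row]
    got <- searchBestCombination(nm, s, stride = 1)
    want <- oracleSearch(nm, X, y, f$arity[row])
    # the optimum |r| agrees to 1e-12, and the returned tuple attains
    # it (formulas like TBI2 harbour exact algebraic |r| ties between
    # tuples, where only the attained optimum is well defined)
    expect_equal(got$absR, want$absR, tolerance = 1e-12, label = nm)
    rAt <- oracleTupleR(nm, X, y, match(got$lambda1, wlGrid),
      match(got$lambda2, wlGrid),
      if (f$arity[row] == 3) match(got$lambda3, wlGrid))
    expect_equal(abs(rAt), want$absR, tolerance = 1e-12, label = nm)
    expect_equal(got$r, rAt, tolerance = 1e-10, label = nm)
    expect_equal(got$nSkipped, want$nSkipped, label = nm)
    expect_equal(got$nTuples, want$nTuples, label = nm)
  }
})

test_that("the DI correlation surface is antisymmetric", {
  s <- toySpectra(14, 15, seed = 9)
  res <- searchBestCombination("DI", s, stride = 1, surface = TRUE)
  surf <- attr(res, "surface")
  ok <- !is.na(surf) & !is.na(t(surf))
  expect_lt(max(abs((surf + t(surf))[ok])), 1e-12)
  # |r| never exceeds 1; skipped bookkeeping conserves the tuple count
  expect_lte(res$absR, 1)
  expect_equal(sum(!is.na(surf)) + res$nSkipped, res$nTuples)
})

test_that("a planted band combination is recovered at stride 1", {
  set.seed(23)
  wl <- seq(400, 1000, 10)
  n <- 60
  X <- matrix(runif(n * length(wl), 0.05, 0.95), n, length(wl))
  s0 <- SpectraSet(X, wl)
  target <- evalIndex("TBI2", s0, c(650, 720, 800))
  nit <- target + rnorm(n, 0, 0.005 * sd(target))
  s <- SpectraSet(X, wl, nitrogen = nit)
  res <- searchBestCombination("TBI2", s, stride = 1)
  expect_equal(c(res$lambda1, res$lambda2, res$lambda3),
    c(650, 720, 800))
})

test_that("searching over orders covers the grid and finds planted orders", {
  set.seed(29)
  wl <- seq(400, 700, 10)
  n <- 50
  X <- matrix(0, n, length(wl))
  X[, 1] <- runif(n, 0.2, 0.8)
  for (b in 2:length(wl)) {
    X[, b] <- pmin(pmax(X[, b - 1] + rnorm(n, 0, 0.05), 0), 1)
  }
  s0 <- SpectraSet(X, wl)
  d1 <- fodTransform(s0, 1)
  planted <- evalIndex("DI", d1, c(520, 620))
  nit <- planted + rnorm(n, 0, 0.01 * sd(planted))
  s <- SpectraSet(X, wl, nitrogen = nit)
  res <- searchOverOrders(s, formulas = c("DI", "OSI"),
    orders = c(0, 0.5, 1, 1.5), stride = 1)
  expect_equal(nrow(res), 2 * 4) # formulas x orders
  best <- attr(res, "bestPerFormula")
  # the per-formula optimum dominates its order-0 member
  for (f in c("DI", "OSI")) {
    expect_gte(best$absR[best$formula == f],
      res$absR[res$formula == f & res$alpha == 0])
  }
  expect_equal(best$alpha[best$formula == "DI"], 1)
})

test_that("degenerate searches fail loudly", {
  s <- SpectraSet(matrix(0.5, 10, 4), seq(500, 530, 10),
    nitrogen = rnorm(10, 19))
  expect_error(searchBestCombination("DI", s, stride = 1), "skipped")
  expect_error(searchBestCombination("DI", toySpectra(5, 5,
    nitrogen = FALSE), stride = 1), "nitrogen")
})
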