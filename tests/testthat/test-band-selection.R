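# A 50-band set where nitrogen is a linear combination of bands 20 and
# 35 plus noise; the planted pair is the recoverable signal.
plantedSet <- function(seed = 7, n = 80, B = 50,
                       bands = c(20, 35)) {
  set.seed(seed)
  X <- matrix(runif(n * B, 0.1, 0.9), n, B)
  y <- 3 * X[, bands[1]] - 2 * X[, bands[2]] + rnorm(n, 0, 0.05)
  SpectraSet(X, seq(500, by = 2, length.out = B), nitrogen = y)
}

test_that("GA is reproducible from its seed and rejects unusable input", {
  s <- plantedSet()
  cfg <- gaConfig(populationSize = 12, generations = 5, seed = 3)
  a <- gaSelect(s, cfg)
  b <- gaSelect(s, cfg)
  expect_identical(selectedBands(a), selectedBands(b))
  expect_identical(a@trace, b@trace)
  expect_error(gaSelect(toySpectra(10, 8, nitrogen = FALSE)), "nitrogen")
  flat <- SpectraSet(matrix(0.5, 10, 6), seq(500, 510, 2),
    nitrogen = rnorm(10) + 18)
  expect_error(gaSelect(flat), "constant")
  expect_error(gaConfig(populationSize = 2), "population")
  expect_error(gaConfig(mutationProb = 1.5), "probabilities")
})

test_that("GA recovers a planted band pair at least as well as all bands", {
  s <- plantedSet()
  ga <- gaSelect(s, gaConfig(seed = 5))
  full <- canopyn:::.cvRmsePls(reflectance(s), nitrogen(s),
    folds = 5, seed = 5)
  expect_lte(ga@cvRmse, full)
  expect_true(all(c(20, 35) %in% selectedBands(ga)))
})

test_that("a single-band set returns that band", {
  s <- toySpectra(10, 1)
  expect_identical(selectedBands(gaSelect(s)), 1L)
})

test_that("SPA projection chains match the lm-based brute-force oracle", {
  set.seed(21)
  X <- matrix(runif(5 * 4), 5, 4) # 5 samples x 4 bands
  got <- canopyn:::.spaChains(X, kMax = 4)
  for (start in 1:4) {
    want <- oracleSpaChain(X, start, kMax = 4)
    expect_identical(got$chains[[start]], want$chain)
    expect_equal(got$norms[[start]], unname(want$norms),
      tolerance = 1e-10)
  }
})

test_that("SPA residual norms are non-increasing and duplicates are shunned", {
  set.seed(22)
  X <- matrix(runif(20 * 8), 20, 8)
  X[, 5] <- X[, 2] # exact duplicate column
  ch <- canopyn:::.spaChains(X, kMax = 8)
  for (start in 1:8) {
    norms <- ch$norms[[start]]
    if (length(norms) > 1) expect_true(all(diff(norms) <= 1e-12))
    chain <- ch$chains[[start]]
    # once one of the identical pair is in, its twin never follows
    expect_lte(sum(chain %in% c(2, 5)), 1)
  }
})

test_that("SPA selects by inner CV and honours the size range", {
  s <- plantedSet(seed = 10, n = 60, B = 20, bands = c(8, 15))
  res <- spaSelect(s, kMin = 2, kMax = 6)
  expect_s4_class(res, "SelectionResult")
  expect_true(length(selectedBands(res)) >= 2 &&
    length(selectedBands(res)) <= 6)
  expect_error(spaSelect(s, 2, 50), "kMax")
  # kMin = kMax = 1: the band with the largest centered column norm
  one <- spaSelect(s, 1, 1)
  norms <- colSums(scale(reflectance(s), center = TRUE, scale = FALSE)^2)
  expect_identical(selectedBands(one), unname(which.max(norms)))
})

test_that("GA-SPA refines the GA pool and matches SPA on the restriction", {
  s <- plantedSet(seed = 7, n = 60, B = 30, bands = c(12, 25))
  cfg <- gaConfig(populationSize = 20, generations = 10, seed = 5)
  ga <- gaSelect(s, cfg)
  gs <- gaSpaSelect(s, cfg, kMin = 2, kMax = 8)
  expect_true(all(selectedBands(gs) %in% selectedBands(ga)))
  pool <- selectedBands(ga)
  manual <- spaSelect(methods::as(s[pool, ], "SpectraSet"),
    kMin = 2, kMax = min(8, length(pool)))
  expect_identical(selectedBands(gs), sort(pool[selectedBands(manual)]))
  expect_identical(selectedBands(gs),
    selectedBands(gaSpaSelect(s, cfg, kMin = 2, kMax = 8)))
})

test_that("GA-SPA fails loudly when the pool is too small", {
  s <- toySpectra(10, 1)
  expect_error(gaSpaSelect(s, gaConfig(), kMin = 2, kMax = 1), "pool")
})
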