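test_that("index arithmetic follows the published formulas", {
  s <- bandsSpectra(list(
    `800` = c(0.5, 0.5), `680` = c(0.1, 0.15),
    `750` = c(0.55, 0.55), `710` = c(0.25, 0.25)
  ), fill = 0.3)
  vt <- computeVITable(s)
  expect_equal(unname(vt[1, "NDVI"]), (0.5 - 0.1) / (0.5 + 0.1))
  expect_equal(unname(vt[1, "MTCI"]), 2.0) # (0.55-0.25)/(0.25-0.10)
  expect_equal(unname(vt[2, "MTCI"]), 3.0) # (0.55-0.25)/(0.25-0.15)
})

test_that("RVI1 and RVI2 duplicate each other as published", {
  s <- toySpectra(8, 301, seed = 5, wl = seq(400, 1000, 2))
  vt <- computeVITable(s)
  expect_identical(vt[, "RVI1"], vt[, "RVI2"])
})

test_that("zero denominators are flagged undefined per sample", {
  s <- bandsSpectra(list(`740` = c(0.3, 0.4), `700` = c(0.3, 0.2)),
    fill = 0.3)
  vt <- computeVITable(s)
  expect_true(is.na(vt[1, "REP"])) # R740 == R700
  expect_false(is.na(vt[2, "REP"]))
  expect_true(attr(vt, "undefined")[1, "REP"])
})

test_that("insufficient grid coverage names the failing index", {
  s <- toySpectra(4, 100, wl = seq(450, 945, 5))
  expect_error(computeVITable(s), "Mrer") # needs 419 nm
})

test_that("literature forms replace the transcribed oddities only", {
  s <- toySpectra(6, 301, seed = 8, wl = seq(400, 1000, 2))
  lit <- computeVITable(s, literatureForms = TRUE)
  pub <- computeVITable(s)
  same <- setdiff(colnames(pub), c("MCARI", "TVI", "MCAVI", "NDSI"))
  expect_equal(pub[, same], lit[, same])
  expect_false(isTRUE(all.equal(pub[, "MCARI"], lit[, "MCARI"])))
})

test_that("rank matrix columns are permutations with perfect predictors first", {
  set.seed(31)
  n <- 40
  nit <- rnorm(n, 19, 1)
  vt <- matrix(rnorm(n * 24), n, 24,
    dimnames = list(NULL, paste0("V", 1:24)))
  vt[, 7] <- nit # a perfect predictor
  rm <- buildRankMatrix(vt, nit, seed = 2, nRepeats = 2)
  expect_identical(dim(rm), c(24L, 7L))
  for (j in seq_len(ncol(rm))) {
    expect_setequal(rm[, j], 1:24)
  }
  expect_equal(unname(rm["V7", c("Pearson", "Spearman", "Ftest")]),
    c(1L, 1L, 1L))
  # the F statistic is monotone in |r|, so its ranks equal Pearson's
  expect_identical(rm[, "Ftest"], rm[, "Pearson"])
  expect_error(buildRankMatrix(vt, rep(19, n)), "constant")
  expect_error(buildRankMatrix(vt[1:5, ], nit[1:5]), "10 samples")
})

test_that("ODCA equals rank-sum ordering and respects its symmetries", {
  set.seed(13)
  for (rep in 1:5) {
    J <- 12
    rm <- vapply(1:5, function(j) sample(J), integer(J))
    rownames(rm) <- paste0("V", 1:J)
    od <- odcaRank(rm, k = 4)
    # brute-force oracle: order by rank sum, ties by best single rank,
    # then input row order
    ord <- order(rowSums(rm), apply(rm, 1, min), seq_len(J))
    want <- integer(J)
    want[ord] <- seq_len(J)
    expect_identical(od$finalRank, want)
    # column permutation invariance
    od2 <- odcaRank(rm[, c(3, 1, 5, 2, 4)], k = 4)
    expect_identical(od2$finalRank, od$finalRank)
  }
  # a single-criterion matrix reproduces that criterion's ranks
  single <- matrix(sample(8), ncol = 1,
    dimnames = list(letters[1:8], "only"))
  expect_identical(odcaRank(single, k = 3)$finalRank,
    as.integer(single[, 1]))
  expect_error(odcaRank(single, k = 9), "k exceeds")
  expect_error(odcaRank(cbind(a = c(1, 1, 3)), k = 1), "permutation")
})

test_that("improving one criterion rank never worsens the score", {
  set.seed(17)
  rm <- vapply(1:6, function(j) sample(10), integer(10))
  od <- odcaRank(rm, k = 3)
  # swap ranks in column 2 so row 4 improves, row holding the better
  # rank degrades; all other entries fixed
  worse <- which(rm[, 2] == rm[4, 2] - 1)
  rm2 <- rm
  rm2[4, 2] <- rm[4, 2] - 1
  rm2[worse, 2] <- rm[4, 2]
  if (rm[4, 2] > 1) {
    od2 <- odcaRank(rm2, k = 3)
    expect_lte(od2$score[4], od$score[4])
  }
})

test_that("the shipped published rank table aggregates to its printed consensus", {
  pt <- publishedRankTable()
  expect_identical(dim(pt$ranks), c(24L, 7L))
  od <- odcaRank(pt$ranks, k = 10)
  # tie-free rows (three rank-sum-tied pairs excluded; the published
  # order of one tied pair follows a rule this aggregation cannot know)
  tied <- c("GNDVI", "NDRE", "OSAVI", "DDN", "MCARI", "EVI2")
  free <- setdiff(od$index, tied)
  expect_identical(od$finalRank[match(free, od$index)],
    unname(pt$finalPublished[free]))
  expect_identical(attr(od, "topk"),
    c("MTCI", "Ndchi", "Mrer", "mND705", "SAVI2", "CIrededge", "SR1",
      "REP", "NDSI", "NDVI"))
})
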