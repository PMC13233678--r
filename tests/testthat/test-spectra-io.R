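test_that("well-formed CSV parses to a validated SpectraSet", {
  path <- withr::local_tempfile(fileext = ".csv")
  wl <- seq(400, 1000, by = 2)
  hdr <- paste(c("id", wl, "nitrogen"), collapse = ",")
  rows <- vapply(1:3, function(i) {
    paste(c(sprintf("S%d", i), rep(0.4 + i / 100, length(wl)), 18 + i),
      collapse = ",")
  }, character(1))
  writeLines(c(hdr, rows), path)
  s <- readSpectraCSV(path)
  expect_s4_class(s, "SpectraSet")
  expect_equal(nSamples(s), 3)
  expect_equal(nBands(s), 301)
  expect_equal(nitrogen(s), c(19, 20, 21))
  expect_equal(wavelengths(s), wl)
})

test_that("malformed tables are rejected with informative errors", {
  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("700,700", "0.1,0.2"), dup)
  expect_error(readSpectraCSV(dup), "duplicated")

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("700,herring", "0.1,0.2"), bad)
  expect_error(readSpectraCSV(bad), "non-numeric")

  nan <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("700,702", "0.1,NA"), nan)
  expect_error(readSpectraCSV(nan), "702")

  expect_error(readSpectraCSV(tempfile()), "not found")
})

test_that("write/read roundtrip is the identity, with and without nitrogen", {
  for (withN in c(TRUE, FALSE)) {
    s <- toySpectra(5, 17, seed = 3, nitrogen = withN)
    path <- withr::local_tempfile(fileext = ".csv")
    writeSpectraCSV(s, path)
    s2 <- readSpectraCSV(path)
    expect_identical(reflectance(s2), reflectance(s))
    expect_identical(wavelengths(s2), wavelengths(s))
    expect_identical(nitrogen(s2), nitrogen(s))
    expect_identical(sampleIds(s2), sampleIds(s))
    hdr <- strsplit(readLines(path, n = 1), ",")[[1]]
    if (withN) {
      expect_identical(hdr[length(hdr)], "nitrogen")
    } else {
      expect_false("nitrogen" %in% hdr)
    }
  }
})

test_that("unsorted wavelength columns are re-ordered ascending", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("710,700,705", "0.3,0.1,0.2"), path)
  s <- readSpectraCSV(path)
  expect_equal(wavelengths(s), c(700, 705, 710))
  expect_equal(as.numeric(reflectance(s)), c(0.1, 0.2, 0.3))
})

test_that("nearestBand resolves targets, breaks ties downward, enforces tolerance", {
  s <- SpectraSet(matrix(0.2, 1, 301), seq(400, 1000, 2))
  expect_equal(wavelengths(s)[nearestBand(s, 800)], 800)
  expect_equal(wavelengths(s)[nearestBand(s, 705)], 704) # tie 704/706
  expect_error(nearestBand(s, 1200, tolerance = 10), "1200")
  expect_error(nearestBand(s, 800, tolerance = -1), "positive")
  # every grid wavelength resolves to its own index
  wl <- wavelengths(s)
  expect_equal(vapply(wl, function(w) nearestBand(s, w), integer(1)),
    seq_along(wl))
})

test_that("cube flattening is row-major and exactly invertible", {
  set.seed(9)
  a <- array(runif(3 * 4 * 5), c(3, 4, 5))
  cube <- ReflectanceCube(a, seq(500, 540, 10))
  s <- cubeToSpectra(cube)
  expect_equal(nSamples(s), 12)
  # pixel (2, 3) sits at row-major position (2-1)*4 + 3
  expect_identical(as.numeric(reflectance(s)[(2 - 1) * 4 + 3, ]),
    as.numeric(a[2, 3, ]))
  back <- spectraToCube(s, 3, 4)
  expect_identical(back@values, cube@values)
})

test_that("container validity catches inconsistent inputs", {
  expect_error(SpectraSet(matrix(1:6 / 10, 2, 3), c(500, 510)),
    "one wavelength")
  expect_error(SpectraSet(matrix(2, 2, 2), c(500, 510)), "\\[0, 1.5\\]")
  expect_error(SpectraSet(matrix(0.5, 2, 2), c(500, 510),
    nitrogen = c(1, 2, 3)), "nitrogen")
  s <- toySpectra(4, 6)
  expect_error(nitrogen(s) <- 1:3, "nitrogen")
  expect_error(ReflectanceCube(array(1, c(2, 2, 3)), c(500, 510)),
    "wavelength")
})
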