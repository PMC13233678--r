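## Spectral table I/O. CSV dialect: comma-separated, '.' decimal, UTF-8,
## header of numeric wavelengths in nm; "id" and "nitrogen" are reserved
## column names (id first, nitrogen last on write).

#' Read a sample-by-wavelength reflectance table
#'
#' Expects a CSV whose header row is numeric wavelengths in nm, with an
#' optional leading \code{id} column and an optional \code{nitrogen}
#' column (mg/g). Wavelength columns are re-sorted ascending if needed.
#'
#' @param path path to the CSV file.
#' @param checkRange passed to \code{\link{SpectraSet}}; set \code{FALSE}
#'   for tables of derivative (not raw) spectra.
#' @return A validated \linkS4class{SpectraSet}.
#' @seealso \code{\link{writeSpectraCSV}}
#' @export
readSpectraCSV <- function(path, checkRange = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  nm <- names(df)
  idCol <- which(nm == "id")
  nitCol <- which(nm == "nitrogen")
  wlCols <- setdiff(seq_along(nm), c(idCol, nitCol))
  wl <- suppressWarnings(as.numeric(nm[wlCols]))
  if (anyNA(wl)) {
    stop("non-numeric wavelength header(s): ",
      paste(nm[wlCols][is.na(wl)], collapse = ", "))
  }
  ids <- if (length(idCol)) as.character(df[[idCol]]) else NULL
  nit <- if (length(nitCol)) as.numeric(df[[nitCol]]) else NULL
  m <- as.matrix(df[, wlCols, drop = FALSE])
  storage.mode(m) <- "double"
  SpectraSet(m, wavelengths = wl, sampleIds = ids, nitrogen = nit,
    checkRange = checkRange)
}

#' Write a SpectraSet to CSV
#'
#' Inverse of \code{\link{readSpectraCSV}}: wavelengths as column headers,
#' \code{id} first, \code{nitrogen} last when present. The roundtrip is
#' the identity on valid sets (values written at full precision).
#'
#' @param s a \linkS4class{SpectraSet}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeSpectraCSV <- function(s, path) {
  stopifnot(methods::is(s, "SpectraSet"))
  m <- reflectance(s)
  # %.17g guarantees a bitwise double roundtrip through the text form
  num <- function(x) sprintf("%.17g", x)
  df <- data.frame(id = sampleIds(s), check.names = FALSE,
    stringsAsFactors = FALSE)
  wl <- wavelengths(s)
  for (j in seq_along(wl)) df[[num(wl[j])]] <- num(m[, j])
  nit <- nitrogen(s)
  if (!is.null(nit)) df$nitrogen <- num(nit)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
    fileEncoding = "UTF-8")
  invisible(path)
}

#' Resolve a named wavelength to the nearest sensor band
#'
#' Vegetation-index definitions name wavelengths (e.g. R705) that need not
#' be sampled exactly by the sensor grid. \code{nearestBand} returns the
#' index of the grid wavelength closest to the target; exact ties between
#' two neighbours are broken toward the lower wavelength.
#'
#' @param s a \linkS4class{SpectraSet}, or a numeric wavelength grid.
#' @param target wavelength in nm.
#' @param tolerance maximal accepted |grid - target| distance in nm;
#'   defaults to one grid step.
#' @return Integer band index into the grid.
#' @examples
#' s <- SpectraSet(matrix(0.2, 1, 301), seq(400, 1000, 2))
#' nearestBand(s, 705) # tie 704/706 resolved to 704
#' @export
nearestBand <- function(s, target, tolerance = NULL) {
  wl <- if (is.numeric(s)) s else wavelengths(s)
  if (is.null(tolerance)) {
    tolerance <- if (length(wl) > 1) min(diff(wl)) else Inf
  }
  if (tolerance <= 0) stop("tolerance must be positive")
  d <- abs(wl - target)
  i <- which(d == min(d))[1] # ties: lower wavelength wins (grid is sorted)
  if (d[i] > tolerance) {
    stop(sprintf("no band within %g nm of %g nm (closest: %g nm)",
      tolerance, target, wl[i]))
  }
  i
}

## ---- reflectance cubes ---------------------------------------------------

#' Flatten a ReflectanceCube into a SpectraSet
#'
#' Pixels are unrolled row-major (row 1 left-to-right, then row 2, ...),
#' so \code{spectraToCube} on the result reproduces the cube exactly.
#'
#' @param cube a \linkS4class{ReflectanceCube}.
#' @param checkRange passed to \code{\link{SpectraSet}}.
#' @return A \linkS4class{SpectraSet} with \code{rows*cols} samples.
#' @export
cubeToSpectra <- function(cube, checkRange = TRUE) {
  stopifnot(methods::is(cube, "ReflectanceCube"))
  d <- dim(cube@values)
  m <- matrix(NA_real_, d[1] * d[2], d[3])
  k <- 1L
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      m[k, ] <- cube@values[i, j, ]
      k <- k + 1L
    }
  }
  SpectraSet(m, wavelengths = cube@wavelengths,
    sampleIds = sprintf("px_%d", seq_len(d[1] * d[2])),
    checkRange = checkRange)
}

#' Rebuild a ReflectanceCube from row-major pixel spectra
#'
#' @param s a \linkS4class{SpectraSet} with \code{nrows*ncols} samples in
#'   row-major pixel order.
#' @param nrows,ncols spatial dimensions of the target cube.
#' @return A \linkS4class{ReflectanceCube}.
#' @export
spectraToCube <- function(s, nrows, ncols) {
  stopifnot(methods::is(s, "SpectraSet"))
  if (nSamples(s) != nrows * ncols) {
    stop("sample count does not match nrows * ncols")
  }
  m <- reflectance(s)
  a <- array(NA_real_, c(nrows, ncols, nBands(s)))
  k <- 1L
  for (i in seq_len(nrows)) {
    for (j in seq_len(ncols)) {
      a[i, j, ] <- m[k, ]
      k <- k + 1L
    }
  }
  ReflectanceCube(a, wavelengths(s))
}

#' Read a reflectance cube from a flat CSV plus wavelength sidecar
#'
#' The cube is stored as a plain-text pair: a CSV of row-major pixel
#' spectra (as written by \code{\link{writeSpectraCSV}}) and the spatial
#' dimensions. Full ENVI-cube ingestion is out of scope.
#'
#' @param path CSV of pixel spectra.
#' @param nrows,ncols spatial dimensions.
#' @return A \linkS4class{ReflectanceCube}.
#' @export
readCubeCSV <- function(path, nrows, ncols) {
  spectraToCube(readSpectraCSV(path), nrows, ncols)
}
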