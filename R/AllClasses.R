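#' SpectraSet: sample-by-wavelength canopy reflectance
#'
#' The central data container of the package, extending
#' \link[SummarizedExperiment]{SummarizedExperiment}: bands are rows
#' (with their wavelength in \code{rowData(x)$wavelength_nm}), samples are
#' columns, and the single assay \code{"reflectance"} holds the spectral
#' matrix. Reference nitrogen measurements, when present, live in
#' \code{colData(x)$nitrogen} (mg/g dry weight).
#'
#' Use the \code{\link{SpectraSet}} constructor rather than \code{new()};
#' it takes the matrix in the natural samples-x-bands orientation and
#' checks the raw-reflectance range.
#'
#' @slot \dots see \code{SummarizedExperiment}.
#' @seealso \code{\link{readSpectraCSV}}, \code{\link{simulateCanopy}}
#' @export
setClass("SpectraSet", contains = "SummarizedExperiment")

#' DerivativeSpectra: a fractional-order derivative of a SpectraSet
#'
#' A \linkS4class{SpectraSet} whose assay holds the Grunwald-Letnikov
#' derivative of order \code{alpha} of the source reflectance, aligned
#' with the source wavelength grid. Values are no longer confined to
#' [0, 1]; the first few bands are flagged edge affected (see
#' \code{\link{edgeMask}}).
#'
#' @slot alpha numeric(1), the derivative order in [0, 2].
#' @slot edgeMask logical vector, \code{TRUE} for edge-affected bands.
#' @seealso \code{\link{fodTransform}}
#' @export
setClass("DerivativeSpectra",
  contains = "SpectraSet",
  slots = c(alpha = "numeric", edgeMask = "logical")
)

#' ReflectanceCube: a rows x cols x bands reflectance image
#'
#' Spatial reflectance data (e.g. an orthorectified UAV scene) sharing the
#' wavelength grid of the tabular spectra, used for per-pixel nitrogen map
#' prediction.
#'
#' @slot values numeric 3-d array, rows x cols x bands.
#' @slot wavelengths numeric vector of band-center wavelengths (nm).
#' @seealso \code{\link{cubeToSpectra}}, \code{\link{predictCube}}
#' @export
setClass("ReflectanceCube",
  slots = c(values = "array", wavelengths = "numeric")
)

#' SelectionResult: outcome of a wavelength-selection run
#'
#' @slot method one of \code{"GA"}, \code{"SPA"}, \code{"GA-SPA"}.
#' @slot indices sorted unique band indices into the source grid.
#' @slot wavelengths the corresponding wavelengths (nm).
#' @slot trace method-specific progress trace (GA: best fitness per
#'   generation; SPA: cross-validated RMSE per candidate subset size).
#' @slot cvRmse inner cross-validated RMSE of the selected subset (mg/g).
#' @slot seed integer seed the run is reproducible from.
#' @slot config the configuration list used.
#' @export
setClass("SelectionResult",
  slots = c(
    method = "character", indices = "integer", wavelengths = "numeric",
    trace = "numeric", cvRmse = "numeric", seed = "integer", config = "list"
  )
)

setValidity("SpectraSet", function(object) {
  wl <- SummarizedExperiment::rowData(object)$wavelength_nm
  if (is.null(wl)) {
    return("rowData must contain a 'wavelength_nm' column")
  }
  if (!is.numeric(wl) || anyNA(wl)) {
    return("wavelengths must be numeric and non-missing")
  }
  if (length(wl) > 1 && any(diff(wl) <= 0)) {
    return("wavelengths must be strictly increasing")
  }
  a <- SummarizedExperiment::assay(object)
  if (!all(is.finite(a))) {
    return("reflectance values must all be finite")
  }
  nit <- SummarizedExperiment::colData(object)$nitrogen
  if (!is.null(nit) && length(nit) != ncol(object)) {
    return("nitrogen vector length must equal the number of samples")
  }
  TRUE
})

setValidity("DerivativeSpectra", function(object) {
  if (length(object@alpha) != 1 || !is.finite(object@alpha)) {
    return("alpha must be a single finite number")
  }
  if (length(object@edgeMask) != nrow(object)) {
    return("edgeMask length must equal the number of bands")
  }
  TRUE
})

setValidity("ReflectanceCube", function(object) {
  d <- dim(object@values)
  if (length(d) != 3) {
    return("values must be a rows x cols x bands array")
  }
  if (d[3] != length(object@wavelengths)) {
    return("third array dimension must match the wavelength grid")
  }
  if (!all(is.finite(object@values))) {
    return("cube values must all be finite")
  }
  if (length(object@wavelengths) > 1 && any(diff(object@wavelengths) <= 0)) {
    return("wavelengths must be strictly increasing")
  }
  TRUE
})

setValidity("SelectionResult", function(object) {
  if (length(object@indices) == 0) {
    return("selection must be non-empty")
  }
  if (anyDuplicated(object@indices)) {
    return("selected indices must be unique")
  }
  if (is.unsorted(object@indices)) {
    return("selected indices must be sorted")
  }
  if (length(object@indices) != length(object@wavelengths)) {
    return("indices and wavelengths must be aligned")
  }
  TRUE
})

#' Construct a SpectraSet
#'
#' @param reflectance numeric matrix, samples x bands, unitless reflectance.
#' @param wavelengths numeric vector (nm), one per band, strictly
#'   increasing; columns are re-ordered to match if supplied unsorted.
#' @param sampleIds optional character vector of sample labels; defaults to
#'   \code{"S1"..}.
#' @param nitrogen optional numeric vector (mg/g dry weight).
#' @param checkRange when \code{TRUE} (the default for raw, order-0
#'   spectra) values must lie in [0, 1.5] — calibration overshoot above 1
#'   is tolerated, but values outside that window indicate unit problems.
#' @return A validated \linkS4class{SpectraSet}.
#' @examples
#' s <- SpectraSet(matrix(0.5, 3, 5), wavelengths = seq(500, 540, 10))
#' nBands(s)
#' @export
SpectraSet <- function(reflectance, wavelengths, sampleIds = NULL,
                       nitrogen = NULL, checkRange = TRUE) {
  reflectance <- as.matrix(reflectance)
  if (!is.numeric(reflectance)) {
    stop("reflectance must be a numeric matrix")
  }
  if (length(wavelengths) != ncol(reflectance)) {
    stop("need one wavelength per reflectance column")
  }
  if (anyDuplicated(wavelengths)) {
    stop("duplicated wavelengths in the grid: ",
      paste(unique(wavelengths[duplicated(wavelengths)]), collapse = ", "))
  }
  o <- order(wavelengths)
  wavelengths <- wavelengths[o]
  reflectance <- reflectance[, o, drop = FALSE]
  if (anyNA(reflectance)) {
    bad <- which(is.na(reflectance), arr.ind = TRUE)[1, ]
    stop(sprintf("missing reflectance at row %d, wavelength %g nm",
      bad[1], wavelengths[bad[2]]))
  }
  if (checkRange &&
      (min(reflectance) < 0 || max(reflectance) > 1.5)) {
    stop("raw reflectance outside [0, 1.5]; check units or calibration")
  }
  if (is.null(sampleIds)) sampleIds <- paste0("S", seq_len(nrow(reflectance)))
  dimnames(reflectance) <- NULL
  cd <- S4Vectors::DataFrame(row.names = sampleIds)
  if (!is.null(nitrogen)) {
    if (length(nitrogen) != nrow(reflectance)) {
      stop("nitrogen vector length must equal the number of samples")
    }
    cd$nitrogen <- as.numeric(nitrogen)
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(reflectance = t(reflectance)),
    rowData = S4Vectors::DataFrame(wavelength_nm = as.numeric(wavelengths)),
    colData = cd
  )
  methods::new("SpectraSet", se)
}

.newDerivativeSpectra <- function(source, values, alpha, edgeMask) {
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(reflectance = t(values)),
    rowData = SummarizedExperiment::rowData(source),
    colData = SummarizedExperiment::colData(source)
  )
  methods::new("DerivativeSpectra", methods::new("SpectraSet", se),
    alpha = alpha, edgeMask = edgeMask)
}

#' Construct a ReflectanceCube
#'
#' @param values numeric array, rows x cols x bands.
#' @param wavelengths numeric vector (nm), length = number of bands.
#' @return A validated \linkS4class{ReflectanceCube}.
#' @export
ReflectanceCube <- function(values, wavelengths) {
  methods::new("ReflectanceCube", values = values,
    wavelengths = as.numeric(wavelengths))
}

## ---- accessors -----------------------------------------------------------

#' @rdname wavelengths
#' @export
setMethod("wavelengths", "SpectraSet", function(x) {
  as.numeric(SummarizedExperiment::rowData(x)$wavelength_nm)
})

#' @rdname wavelengths
#' @export
setMethod("wavelengths", "ReflectanceCube", function(x) x@wavelengths)

#' @rdname reflectance
#' @export
setMethod("reflectance", "SpectraSet", function(x) {
  m <- t(SummarizedExperiment::assay(x, "reflectance"))
  dimnames(m) <- list(colnames(x), as.character(wavelengths(x)))
  m
})

#' @rdname nitrogen
#' @export
setMethod("nitrogen", "SpectraSet", function(x) {
  n <- SummarizedExperiment::colData(x)$nitrogen
  if (is.null(n)) NULL else as.numeric(n)
})

#' @rdname nitrogen
#' @export
setReplaceMethod("nitrogen", "SpectraSet", function(x, value) {
  if (!is.null(value) && length(value) != ncol(x)) {
    stop("nitrogen vector length must equal the number of samples")
  }
  SummarizedExperiment::colData(x)$nitrogen <- value
  methods::validObject(x)
  x
})

#' @rdname sampleIds
#' @export
setMethod("sampleIds", "SpectraSet", function(x) colnames(x))

#' @rdname nSamples
#' @export
setMethod("nSamples", "SpectraSet", function(x) ncol(x))

#' @rdname nSamples
#' @export
setMethod("nBands", "SpectraSet", function(x) nrow(x))

#' @rdname derivOrder
#' @export
setMethod("derivOrder", "DerivativeSpectra", function(x) x@alpha)

#' @rdname edgeMask
#' @export
setMethod("edgeMask", "DerivativeSpectra", function(x) x@edgeMask)

#' @rdname selectedBands
#' @export
setMethod("selectedBands", "SelectionResult", function(x) x@indices)

## ---- show ----------------------------------------------------------------

setMethod("show", "SpectraSet", function(object) {
  wl <- wavelengths(object)
  cat(sprintf("%s: %d samples x %d bands (%g-%g nm)\n",
    class(object), ncol(object), nrow(object), min(wl), max(wl)))
  if (methods::is(object, "DerivativeSpectra")) {
    cat(sprintf("  fractional derivative order alpha = %g (%d edge bands masked)\n",
      object@alpha, sum(object@edgeMask)))
  }
  nit <- nitrogen(object)
  if (!is.null(nit)) {
    cat(sprintf("  nitrogen: %.2f-%.2f mg/g (mean %.2f)\n",
      min(nit), max(nit), mean(nit)))
  } else {
    cat("  nitrogen: absent\n")
  }
})

setMethod("show", "ReflectanceCube", function(object) {
  d <- dim(object@values)
  cat(sprintf("ReflectanceCube: %d x %d pixels, %d bands (%g-%g nm)\n",
    d[1], d[2], d[3], min(object@wavelengths), max(object@wavelengths)))
})

setMethod("show", "SelectionResult", function(object) {
  cat(sprintf("SelectionResult (%s): %d bands, inner CV-RMSE %.4f mg/g\n",
    object@method, length(object@indices), object@cvRmse))
  cat("  wavelengths (nm):", paste(object@wavelengths, collapse = " "), "\n")
})
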