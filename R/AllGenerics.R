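#' @import methods
#' @importFrom stats cor sd predict quantile rnorm runif median coef var
#' @importFrom utils read.csv write.csv head
NULL

#' Wavelength grid of a spectral object
#'
#' @param x a \linkS4class{SpectraSet}, \linkS4class{DerivativeSpectra} or
#'   \linkS4class{ReflectanceCube}.
#' @return Numeric vector of wavelengths in nm, strictly increasing.
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' Reflectance matrix (samples x bands)
#'
#' Returns the spectral data matrix with one row per sample and one column
#' per band, columns named by wavelength. This is the transpose of the
#' underlying \code{SummarizedExperiment} assay, which stores bands as rows.
#'
#' @param x a \linkS4class{SpectraSet}.
#' @return Numeric matrix, \code{n_samples x n_bands}.
#' @export
setGeneric("reflectance", function(x) standardGeneric("reflectance"))

#' Nitrogen content vector
#'
#' @param x a \linkS4class{SpectraSet}.
#' @return Numeric vector of canopy nitrogen content in mg/g dry weight,
#'   or \code{NULL} when the set carries no reference measurements.
#' @export
setGeneric("nitrogen", function(x) standardGeneric("nitrogen"))

#' @rdname nitrogen
#' @param value numeric vector of length \code{nSamples(x)}, or \code{NULL}.
#' @export
setGeneric("nitrogen<-", function(x, value) standardGeneric("nitrogen<-"))

#' Sample identifiers
#'
#' @param x a \linkS4class{SpectraSet}.
#' @return Character vector of sample labels.
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' Number of samples / bands
#'
#' @param x a \linkS4class{SpectraSet}.
#' @return Integer count.
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname nSamples
#' @export
setGeneric("nBands", function(x) standardGeneric("nBands"))

#' Fractional derivative order of a transformed spectra set
#'
#' @param x a \linkS4class{DerivativeSpectra}.
#' @return The Grunwald-Letnikov order alpha used for the transform.
#' @export
setGeneric("derivOrder", function(x) standardGeneric("derivOrder"))

#' Edge-band validity mask
#'
#' The expanding-window derivative sum is truncated at the start of the
#' series, so the first few bands of a transformed spectrum are edge
#' affected. \code{edgeMask} flags them (\code{TRUE} = edge affected).
#'
#' @param x a \linkS4class{DerivativeSpectra}.
#' @return Logical vector of length \code{nBands(x)}.
#' @export
setGeneric("edgeMask", function(x) standardGeneric("edgeMask"))

#' Selected band indices of a selection result
#'
#' @param x a \linkS4class{SelectionResult}.
#' @return Sorted integer indices into the wavelength grid.
#' @export
setGeneric("selectedBands", function(x) standardGeneric("selectedBands"))
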