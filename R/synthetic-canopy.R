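## Phenomenological canopy reflectance simulator. Four fertilization
## treatments set the nitrogen distribution; nitrogen then drives the
## depth of the blue/red chlorophyll absorptions, the green-peak height,
## the red-edge inflection wavelength and (weakly) the NIR plateau, so
## every downstream stage has a planted, recoverable signal.

#' Configuration for the synthetic canopy generator
#'
#' Defaults encode the study conditions the generator emulates: four
#' nitrogen treatments with mean canopy nitrogen 17.5/18.5/19.5/20.0 mg/g
#' and spread increasing with fertilization, 50 samples per treatment
#' (200 total), three planting densities entering as NIR-plateau scaling,
#' and a 400-1000 nm grid at 2 nm (301 bands).
#'
#' @param nPerTreatment samples per treatment group (>= 2).
#' @param treatmentMeans group mean nitrogen, mg/g, strictly increasing.
#' @param treatmentSds group standard deviations, mg/g, all positive.
#' @param densityFactors named NIR-plateau multipliers, one per planting
#'   density level.
#' @param noiseSd multiplicative noise standard deviation, reflectance
#'   units (an additive component of a quarter this size is also applied).
#' @param wavelengths wavelength grid, nm.
#' @param seed integer RNG seed.
#' @return A validated configuration list of class \code{SyntheticConfig}.
#' @export
syntheticConfig <- function(nPerTreatment = 50,
                            treatmentMeans = c(17.5, 18.5, 19.5, 20.0),
                            treatmentSds = c(0.8, 0.9, 1.0, 1.1),
                            densityFactors = c(D1 = 0.95, D2 = 1.00, D3 = 1.05),
                            noiseSd = 0.008,
                            wavelengths = seq(400, 1000, by = 2),
                            seed = 42L) {
  cfg <- list(
    nPerTreatment = as.integer(nPerTreatment),
    treatmentMeans = as.numeric(treatmentMeans),
    treatmentSds = as.numeric(treatmentSds),
    densityFactors = densityFactors,
    noiseSd = as.numeric(noiseSd),
    wavelengths = as.numeric(wavelengths),
    seed = as.integer(seed)
  )
  if (cfg$nPerTreatment < 2) stop("nPerTreatment must be >= 2")
  if (any(diff(cfg$treatmentMeans) <= 0)) {
    stop("treatment means must be strictly increasing")
  }
  if (any(cfg$treatmentSds <= 0)) stop("treatment sds must be positive")
  if (length(cfg$treatmentSds) != length(cfg$treatmentMeans)) {
    stop("one sd per treatment mean required")
  }
  if (cfg$noiseSd < 0) stop("noiseSd must be non-negative")
  if (any(diff(cfg$wavelengths) <= 0)) {
    stop("wavelength grid must be strictly increasing")
  }
  class(cfg) <- "SyntheticConfig"
  cfg
}

#' Draw per-sample nitrogen content from the treatment design
#'
#' Each treatment contributes \code{nPerTreatment} draws from a normal
#' distribution truncated at zero (negative draws are redrawn; with the
#' default means ~17-20 mg/g truncation is never active in practice).
#'
#' @param cfg a \code{\link{syntheticConfig}}.
#' @return data.frame with columns \code{nitrogen} (mg/g) and
#'   \code{treatment} (factor N0, N1, ...), in treatment order.
#' @export
simulateNitrogen <- function(cfg = syntheticConfig()) {
  stopifnot(inherits(cfg, "SyntheticConfig"))
  set.seed(cfg$seed)
  g <- length(cfg$treatmentMeans)
  labs <- paste0("N", seq_len(g) - 1)
  nit <- numeric(0)
  trt <- character(0)
  for (i in seq_len(g)) {
    x <- stats::rnorm(cfg$nPerTreatment, cfg$treatmentMeans[i],
      cfg$treatmentSds[i])
    while (any(x <= 0)) {
      x[x <= 0] <- stats::rnorm(sum(x <= 0), cfg$treatmentMeans[i],
        cfg$treatmentSds[i])
    }
    nit <- c(nit, x)
    trt <- c(trt, rep(labs[i], cfg$nPerTreatment))
  }
  data.frame(nitrogen = nit, treatment = factor(trt, levels = labs))
}

## Noise-free spectrum for one sample. N in mg/g, dens a NIR multiplier.
## Visible part: flat base + green peak (lower at high N) minus Gaussian
## chlorophyll absorptions at ~470 and ~670 nm (deeper at high N); a
## logistic red edge whose inflection moves to longer wavelengths with N
## blends into a density-scaled NIR plateau with a ~930 nm water feature.
.cleanSpectrum <- function(wl, N, dens) {
  z <- N - 18.75 # centre of the default treatment range
  greenPeak <- pmax(0.10 - 0.012 * z, 0.02)
  blueDepth <- pmax(0.025 + 0.004 * z, 0)
  redDepth <- pmax(0.035 + 0.010 * z, 0.005)
  redEdgePos <- 712 + 5 * z
  nir <- (0.46 + 0.012 * z) * dens
  vis <- 0.06 +
    greenPeak * exp(-0.5 * ((wl - 550) / 28)^2) -
    blueDepth * exp(-0.5 * ((wl - 470) / 20)^2) -
    redDepth * exp(-0.5 * ((wl - 670) / 25)^2)
  s <- stats::plogis((wl - redEdgePos) / 12)
  water <- 0.05 * (nir / 0.46) * exp(-0.5 * ((wl - 930) / 18)^2)
  vis * (1 - s) + nir * s - water
}

#' Simulate canopy reflectance for given nitrogen values
#'
#' @param nitrogen numeric vector of nitrogen content (mg/g), all positive.
#' @param cfg a \code{\link{syntheticConfig}}; \code{cfg$seed} drives the
#'   density assignment and the noise.
#' @param treatment optional treatment labels carried into the truth table.
#' @return list with elements \code{spectra} (a \linkS4class{SpectraSet}
#'   with nitrogen attached) and \code{truth} (a list holding the
#'   per-sample table — nitrogen, treatment, density — and the noise-free
#'   spectral matrix \code{clean}).
#' @export
simulateReflectance <- function(nitrogen, cfg = syntheticConfig(),
                                treatment = NULL) {
  stopifnot(inherits(cfg, "SyntheticConfig"))
  if (any(!is.finite(nitrogen)) || any(nitrogen <= 0)) {
    stop("nitrogen values must be finite and positive")
  }
  n <- length(nitrogen)
  wl <- cfg$wavelengths
  set.seed(cfg$seed + 1L) # distinct stream from the nitrogen draws
  dens <- sample(names(cfg$densityFactors), n, replace = TRUE)
  clean <- t(vapply(seq_len(n), function(i) {
    .cleanSpectrum(wl, nitrogen[i], cfg$densityFactors[[dens[i]]])
  }, numeric(length(wl))))
  noisy <- clean * (1 + matrix(stats::rnorm(n * length(wl), 0, cfg$noiseSd),
    n, length(wl))) +
    matrix(stats::rnorm(n * length(wl), 0, cfg$noiseSd / 4), n, length(wl))
  noisy <- pmin(pmax(noisy, 0), 1)
  ids <- sprintf("S%03d", seq_len(n))
  truthTab <- data.frame(
    id = ids, nitrogen = nitrogen,
    treatment = if (is.null(treatment)) NA else treatment,
    density = dens, stringsAsFactors = FALSE
  )
  list(
    spectra = SpectraSet(noisy, wl, sampleIds = ids, nitrogen = nitrogen),
    truth = list(table = truthTab, clean = clean)
  )
}

#' Simulate a complete labelled canopy data set
#'
#' Convenience wrapper: \code{\link{simulateNitrogen}} then
#' \code{\link{simulateReflectance}} under one configuration.
#'
#' @param cfg a \code{\link{syntheticConfig}}.
#' @return As \code{\link{simulateReflectance}}.
#' @examples
#' sim <- simulateCanopy(syntheticConfig(nPerTreatment = 5))
#' sim$spectra
#' @export
simulateCanopy <- function(cfg = syntheticConfig()) {
  nit <- simulateNitrogen(cfg)
  simulateReflectance(nit$nitrogen, cfg, treatment = nit$treatment)
}
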