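# Programmatic fixtures shared across tests.

# A small random SpectraSet with an optional linear nitrogen link.
toySpectra <- function(n = 12, B = 20, seed = 1, nitrogen = TRUE,
                       wl = seq(500, by = 2, length.out = B)) {
  set.seed(seed)
  X <- matrix(runif(n * B, 0.05, 0.95), n, B)
  nit <- if (nitrogen) 18 + 2 * X[, max(1, B %/% 2)] + rnorm(n, 0, 0.1)
  SpectraSet(X, wl, nitrogen = nit)
}

# A SpectraSet on a 1-nm grid where chosen wavelengths carry fixed
# per-sample values; every other band holds `fill`.
bandsSpectra <- function(values, fill = 0.3, wlRange = c(400, 1000)) {
  wl <- seq(wlRange[1], wlRange[2], by = 1)
  n <- length(values[[1]])
  X <- matrix(fill, n, length(wl))
  for (w in names(values)) X[, which(wl == as.numeric(w))] <- values[[w]]
  SpectraSet(X, wl)
}
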