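## Wavelength selection from raw spectra: a binary-chromosome genetic
## algorithm, the classical successive projections algorithm, and the
## GA -> SPA hybrid (SPA refines the GA-selected pool). The fitness /
## subset-evaluation model throughout is the cross-validated
## latent-variable linear regression of learners.R.

#' Genetic-algorithm configuration for band selection
#'
#' @param populationSize chromosomes per generation (>= 4).
#' @param generations number of generations.
#' @param crossoverProb probability of single-point crossover per pair.
#' @param mutationProb per-gene bit-flip probability.
#' @param elitism number of best chromosomes copied unchanged.
#' @param cvFolds folds of the inner cross-validated fitness model.
#' @param sizePenalty lambda of the cardinality penalty
#'   \code{lambda * n_selected / n_bands}, discouraging near-full-band
#'   chromosomes.
#' @param initProb probability a gene starts switched on.
#' @param seed integer seed; a GA run is fully reproducible from it.
#' @return Configuration list of class \code{GAConfig}.
#' @export
gaConfig <- function(populationSize = 50L, generations = 100L,
                     crossoverProb = 0.8, mutationProb = 0.01,
                     elitism = 2L, cvFolds = 5L, sizePenalty = 0.05,
                     initProb = 0.1, seed = 1L) {
  cfg <- list(
    populationSize = as.integer(populationSize),
    generations = as.integer(generations),
    crossoverProb = crossoverProb, mutationProb = mutationProb,
    elitism = as.integer(elitism), cvFolds = as.integer(cvFolds),
    sizePenalty = sizePenalty, initProb = initProb, seed = as.integer(seed)
  )
  if (cfg$populationSize < 4) stop("population must be >= 4")
  probs <- c(cfg$crossoverProb, cfg$mutationProb, cfg$initProb)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  class(cfg) <- "GAConfig"
  cfg
}

# SPA projection chains: from each start band, repeatedly add the band
# whose column has the largest squared norm after projection onto the
# orthogonal complement of the chosen set (ties: lowest index). Returns
# per-start chains and the non-increasing sequence of residual norms.
.spaChains <- function(X, kMax) {
  B <- ncol(X)
  Xc <- sweep(X, 2, colMeans(X))
  chains <- vector("list", B)
  normsList <- vector("list", B)
  for (start in seq_len(B)) {
    chain <- start
    trace <- numeric(0) # residual norm of each added band
    R <- Xc # residuals after projecting out selected columns
    repeat {
      if (length(chain) >= kMax) break
      v <- R[, chain[length(chain)]]
      nv <- sum(v^2)
      if (nv < 1e-24) break
      R <- R - outer(v, as.numeric(crossprod(R, v)) / nv)
      norms <- colSums(R^2)
      norms[chain] <- -Inf
      if (max(norms) < 1e-24) break # only duplicates of selected left
      nxt <- which.max(norms) # which.max: lowest index on ties
      chain <- c(chain, nxt)
      trace <- c(trace, norms[nxt])
    }
    chains[[start]] <- chain
    normsList[[start]] <- trace
  }
  list(chains = chains, norms = normsList)
}

# fitness = -(mean CV-RMSE) - lambda * fraction of bands selected
.gaFitness <- function(chrom, Xmat, yvec, cfg) {
  bands <- which(chrom)
  if (length(bands) == 0) return(-Inf)
  -.cvRmsePls(Xmat, yvec, bands, folds = cfg$cvFolds, seed = cfg$seed) -
    cfg$sizePenalty * length(bands) / ncol(Xmat)
}

#' Genetic-algorithm wavelength selection
#'
#' Binary chromosomes encode band inclusion; fitness is the negative mean
#' cross-validated RMSE of a latent-variable linear regression restricted
#' to the chromosome's bands, minus a mild cardinality penalty. Selection
#' is by tournament (size 3) with elitism; crossover is single-point.
#' The best chromosome ever seen is returned.
#'
#' @param s a \linkS4class{SpectraSet} with nitrogen attached.
#' @param cfg a \code{\link{gaConfig}}.
#' @return A \linkS4class{SelectionResult} (method \code{"GA"}) whose
#'   trace records the best fitness per generation.
#' @export
gaSelect <- function(s, cfg = gaConfig()) {
  stopifnot(methods::is(s, "SpectraSet"), inherits(cfg, "GAConfig"))
  y <- nitrogen(s)
  if (is.null(y)) stop("nitrogen values are required for selection")
  X <- reflectance(s)
  B <- ncol(X)
  if (all(apply(X, 2, stats::sd) == 0)) {
    stop("all-constant spectra: selection is degenerate")
  }
  if (B == 1) {
    return(.selectionResult("GA", 1L, s, .cvRmsePls(X, y, 1L,
      folds = cfg$cvFolds, seed = cfg$seed), 0, cfg))
  }
  set.seed(cfg$seed)
  pop <- matrix(stats::runif(cfg$populationSize * B) < cfg$initProb,
    cfg$populationSize, B)
  empty <- rowSums(pop) == 0
  for (i in which(empty)) pop[i, sample.int(B, 1)] <- TRUE
  fit <- apply(pop, 1, .gaFitness, Xmat = X, yvec = y, cfg = cfg)
  bestChrom <- pop[which.max(fit), ]
  bestFit <- max(fit)
  trace <- numeric(cfg$generations)
  for (g in seq_len(cfg$generations)) {
    ord <- order(fit, decreasing = TRUE)
    newPop <- matrix(FALSE, cfg$populationSize, B)
    nElite <- min(cfg$elitism, cfg$populationSize)
    newPop[seq_len(nElite), ] <- pop[ord[seq_len(nElite)], ]
    i <- nElite
    while (i < cfg$populationSize) {
      # tournament selection, size 3
      pick <- function() {
        cand <- sample.int(cfg$populationSize, 3, replace = TRUE)
        cand[which.max(fit[cand])]
      }
      p1 <- pop[pick(), ]
      p2 <- pop[pick(), ]
      if (stats::runif(1) < cfg$crossoverProb && B > 1) {
        cut <- sample.int(B - 1, 1)
        c1 <- c(p1[seq_len(cut)], p2[(cut + 1):B])
        c2 <- c(p2[seq_len(cut)], p1[(cut + 1):B])
      } else {
        c1 <- p1
        c2 <- p2
      }
      for (ch in list(c1, c2)) {
        if (i >= cfg$populationSize) break
        flip <- stats::runif(B) < cfg$mutationProb
        ch <- xor(ch, flip)
        if (!any(ch)) ch[sample.int(B, 1)] <- TRUE
        i <- i + 1
        newPop[i, ] <- ch
      }
    }
    pop <- newPop
    fit <- apply(pop, 1, .gaFitness, Xmat = X, yvec = y, cfg = cfg)
    if (max(fit) > bestFit) {
      bestFit <- max(fit)
      bestChrom <- pop[which.max(fit), ]
    }
    trace[g] <- bestFit
  }
  idx <- which(bestChrom)
  .selectionResult("GA", idx, s,
    .cvRmsePls(X, y, idx, folds = cfg$cvFolds, seed = cfg$seed),
    trace, cfg)
}

#' Successive-projections-algorithm wavelength selection
#'
#' Classical SPA: starting from each candidate band, iteratively add the
#' band whose column has the largest norm after projection onto the
#' orthogonal complement of the already-selected columns (ties go to the
#' lowest band index); then pick the chain prefix (subset size within
#' [kMin, kMax]) and start band minimizing the inner cross-validated
#' RMSE. Deterministic.
#'
#' @param s a \linkS4class{SpectraSet} with nitrogen attached.
#' @param kMin,kMax candidate subset-size range; \code{kMax} must not
#'   exceed the band count.
#' @param cvFolds folds for the subset-evaluation model.
#' @return A \linkS4class{SelectionResult} (method \code{"SPA"}) whose
#'   trace records CV-RMSE per candidate size for the winning start band.
#' @export
spaSelect <- function(s, kMin = 2L, kMax = 20L, cvFolds = 5L) {
  stopifnot(methods::is(s, "SpectraSet"))
  y <- nitrogen(s)
  if (is.null(y)) stop("nitrogen values are required for selection")
  X <- reflectance(s)
  B <- ncol(X)
  if (kMax > B) stop("kMax exceeds the number of bands")
  kMin <- max(1L, as.integer(kMin))
  kMax <- as.integer(kMax)
  if (kMin > kMax) stop("kMin must be <= kMax")
  if (kMax == 1L) {
    # single-band case: the projection criterion itself decides — the
    # band with the largest mean-centered column norm (ties: lowest)
    norms <- colSums(sweep(X, 2, colMeans(X))^2)
    idx <- which.max(norms)
    return(.selectionResult("SPA", idx, s,
      .cvRmsePls(X, y, idx, folds = cvFolds, seed = 0L), norms[idx],
      list(kMin = kMin, kMax = kMax, cvFolds = cvFolds,
        startBand = idx)))
  }
  chains <- .spaChains(X, kMax)$chains
  best <- list(rmse = Inf)
  for (start in seq_len(B)) {
    chain <- chains[[start]]
    if (length(chain) < kMin) next
    for (k in seq(kMin, min(kMax, length(chain)))) {
      rmse <- .cvRmsePls(X, y, chain[seq_len(k)], folds = cvFolds, seed = 0L)
      if (rmse < best$rmse - 1e-12) {
        best <- list(rmse = rmse, start = start, k = k)
      }
    }
  }
  if (!is.finite(best$rmse)) stop("SPA found no admissible subset")
  chain <- chains[[best$start]]
  trace <- vapply(seq(kMin, min(kMax, length(chain))), function(k) {
    .cvRmsePls(X, y, chain[seq_len(k)], folds = cvFolds, seed = 0L)
  }, numeric(1))
  idx <- sort(chain[seq_len(best$k)])
  .selectionResult("SPA", idx, s, best$rmse, trace,
    list(kMin = kMin, kMax = kMax, cvFolds = cvFolds,
      startBand = best$start))
}

#' Hybrid GA -> SPA wavelength selection
#'
#' Runs the GA first to form a pool of potentially important bands, then
#' refines it with SPA restricted to the pool. The result is a subset of
#' the GA pool and identical to \code{\link{spaSelect}} applied to the
#' pool-restricted spectra.
#'
#' @param s a \linkS4class{SpectraSet} with nitrogen attached.
#' @param gaCfg a \code{\link{gaConfig}}.
#' @param kMin,kMax,cvFolds passed to \code{\link{spaSelect}}; the GA pool
#'   must contain at least \code{kMin} bands.
#' @return A \linkS4class{SelectionResult} (method \code{"GA-SPA"}).
#' @export
gaSpaSelect <- function(s, gaCfg = gaConfig(), kMin = 2L, kMax = 20L,
                        cvFolds = 5L) {
  ga <- gaSelect(s, gaCfg)
  pool <- selectedBands(ga)
  if (length(pool) < kMin) {
    stop("GA pool (", length(pool), " bands) smaller than kMin = ", kMin)
  }
  sub <- s[pool, ]
  spa <- spaSelect(methods::as(sub, "SpectraSet"),
    kMin = kMin, kMax = min(kMax, length(pool)), cvFolds = cvFolds)
  idx <- sort(pool[selectedBands(spa)])
  .selectionResult("GA-SPA", idx, s, spa@cvRmse, spa@trace,
    list(ga = ga@config, spa = spa@config, pool = pool))
}

.selectionResult <- function(method, idx, s, cvRmse, trace, config) {
  idx <- sort(as.integer(idx))
  methods::new("SelectionResult",
    method = method, indices = idx,
    wavelengths = wavelengths(s)[idx],
    trace = as.numeric(trace), cvRmse = cvRmse,
    seed = as.integer(config$seed %||% NA_integer_),
    config = unclass(config))
}
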