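## The 24-index vegetation-index library, the seven-criterion scoring of
## each index against nitrogen, and the ODCA (overall difference
## combination assessment) rank aggregation that picks the top-10 set.

#' Definitions of the 24 vegetation indices
#'
#' Returns the index library: name, required wavelengths (nm) and the
#' arithmetic expression over reflectances R_lambda. By default the
#' formulas are implemented exactly as published in the source index
#' table, including its idiosyncrasies (RVI1 and RVI2 share the formula
#' R800/R670; MCARI, TVI and MCAVI carry unusual coefficient structures;
#' NDSI uses R756 in the numerator but R746 in the denominator; SAVI1's
#' "R80" is read as R800). \code{literatureForms = TRUE} substitutes the
#' canonical literature versions of MCARI, TVI, MCAVI and NDSI instead.
#'
#' @param literatureForms use canonical literature formulas for the four
#'   indices whose published transcription deviates from them.
#' @return Named list; each element has \code{name}, \code{wavelengths}
#'   and \code{fun(R)} where \code{R} is a list keyed by wavelength.
#' @export
viDefinitions <- function(literatureForms = FALSE) {
  vi <- function(wl, fun) list(wavelengths = wl, fun = fun)
  defs <- list(
    SR1 = vi(c(810, 560), function(R) R$`810` / R$`560`),
    SR2 = vi(c(750, 710), function(R) R$`750` / R$`710`),
    RVI1 = vi(c(800, 670), function(R) R$`800` / R$`670`),
    RVI2 = vi(c(800, 670), function(R) R$`800` / R$`670`),
    NDVI = vi(c(800, 680), function(R) {
      (R$`800` - R$`680`) / (R$`800` + R$`680`)
    }),
    GNDVI = vi(c(800, 550), function(R) {
      (R$`800` - R$`550`) / (R$`800` + R$`550`)
    }),
    NDRE = vi(c(790, 720), function(R) {
      (R$`790` - R$`720`) / (R$`790` + R$`720`)
    }),
    EVI2 = vi(c(800, 680), function(R) {
      2.5 * (R$`800` - R$`680`) / (1 + R$`800` + 2.4 * R$`680`)
    }),
    CIgreen = vi(c(780, 550), function(R) R$`780` / R$`550` - 1),
    CIrededge = vi(c(780, 710), function(R) R$`780` / R$`710` - 1),
    MTCI = vi(c(750, 710, 680), function(R) {
      (R$`750` - R$`710`) / (R$`710` - R$`680`)
    }),
    mND705 = vi(c(750, 705, 445), function(R) {
      (R$`750` - R$`705`) / (R$`750` + R$`705` - 2 * R$`445`)
    }),
    OSAVI = vi(c(800, 670), function(R) {
      1.16 * (R$`800` - R$`670`) / (R$`800` + R$`670` + 0.16)
    }),
    MCARI = vi(c(780, 550, 800), function(R) {
      1.2 * (120 * (R$`780` - R$`550`) - 200 * (R$`800` - R$`550`))
    }),
    TVI = vi(c(780, 550, 670), function(R) {
      0.5 * (120 * (R$`780` - R$`550`) - 200 * (R$`670` - R$`550`))
    }),
    MSR = vi(c(800, 670), function(R) {
      (R$`800` / R$`670` - 1) / sqrt(R$`800` / R$`670` + 1)
    }),
    MCAVI = vi(c(800, 670), function(R) {
      0.2 * (2 * R$`800` + 1 - sqrt(2 * R$`800` + 1) * 2 -
        8 * (R$`800` - R$`670`))
    }),
    SAVI1 = vi(c(800, 670), function(R) {
      1.5 * (R$`800` - R$`670`) / (R$`800` + R$`670` + 0.5)
    }),
    SAVI2 = vi(c(825, 735), function(R) {
      0.92 * (R$`825` - R$`735`) / (R$`825` + R$`735` - 0.08)
    }),
    Ndchi = vi(c(925, 710), function(R) {
      (R$`925` - R$`710`) / (R$`925` + R$`710`)
    }),
    NDSI = vi(c(788, 756, 746), function(R) {
      (R$`788` - R$`756`) / (R$`788` + R$`746`)
    }),
    Mrer = vi(c(759, 419, 742), function(R) {
      (R$`759` - 1.8 * R$`419`) / (R$`742` - 1.8 * R$`419`)
    }),
    REP = vi(c(670, 780, 700, 740), function(R) {
      700 + 40 * ((R$`670` + R$`780`) / 2 - R$`700`) / (R$`740` - R$`700`)
    }),
    DDN = vi(c(710, 660, 760), function(R) {
      2 * R$`710` - R$`660` - R$`760`
    })
  )
  if (literatureForms) {
    defs$MCARI <- vi(c(700, 670, 550), function(R) {
      ((R$`700` - R$`670`) - 0.2 * (R$`700` - R$`550`)) *
        (R$`700` / R$`670`)
    })
    defs$TVI <- vi(c(750, 550, 670), function(R) {
      0.5 * (120 * (R$`750` - R$`550`) - 200 * (R$`670` - R$`550`))
    })
    defs$MCAVI <- vi(c(800, 670), function(R) { # MSAVI2 closed form
      0.5 * (2 * R$`800` + 1 - sqrt((2 * R$`800` + 1)^2 -
        8 * (R$`800` - R$`670`)))
    })
    defs$NDSI <- vi(c(788, 756), function(R) {
      (R$`788` - R$`756`) / (R$`788` + R$`756`)
    })
  }
  for (nm in names(defs)) defs[[nm]]$name <- nm
  defs
}

#' Compute the vegetation-index value table
#'
#' Evaluates all indices on a spectra set, resolving each named
#' wavelength to the nearest grid band (\code{\link{nearestBand}}).
#' Samples hitting a zero denominator are set NA and flagged.
#'
#' @param s a \linkS4class{SpectraSet} whose grid covers 419-925 nm.
#' @param tolerance wavelength-resolution tolerance (nm); defaults to one
#'   grid step.
#' @param literatureForms see \code{\link{viDefinitions}}.
#' @return Numeric matrix n_samples x 24 with an attribute
#'   \code{"undefined"} (logical matrix of flagged cells).
#' @export
computeVITable <- function(s, tolerance = NULL, literatureForms = FALSE) {
  stopifnot(methods::is(s, "SpectraSet"))
  defs <- viDefinitions(literatureForms)
  X <- reflectance(s)
  wl <- wavelengths(s)
  out <- matrix(NA_real_, nrow(X), length(defs),
    dimnames = list(rownames(X), names(defs)))
  for (nm in names(defs)) {
    d <- defs[[nm]]
    R <- list()
    for (w in d$wavelengths) {
      idx <- tryCatch(nearestBand(wl, w, tolerance),
        error = function(e) {
          stop(sprintf("grid does not cover %g nm required by %s", w, nm))
        })
      R[[as.character(w)]] <- X[, idx]
    }
    v <- d$fun(R)
    v[!is.finite(v)] <- NA_real_
    out[, nm] <- v
  }
  attr(out, "undefined") <- is.na(out)
  out
}

## ---- mutual information (KSG k-NN estimator) -----------------------------

# Kraskov-Stoegbauer-Grassberger estimator (algorithm 1) for two
# continuous scalars; k = 3 neighbours, max-norm in the joint space.
# A tiny seeded jitter breaks ties from duplicated values.
.ksgMI <- function(x, y, k = 3L, seed = 0L) {
  n <- length(x)
  set.seed(seed)
  x <- x + stats::rnorm(n, 0, max(stats::sd(x), 1e-10) * 1e-10)
  y <- y + stats::rnorm(n, 0, max(stats::sd(y), 1e-10) * 1e-10)
  dx <- abs(outer(x, x, "-"))
  dy <- abs(outer(y, y, "-"))
  dj <- pmax(dx, dy)
  diag(dj) <- Inf
  eps <- apply(dj, 1, function(row) sort(row)[k])
  nx <- rowSums(dx < eps) - 1L
  ny <- rowSums(dy < eps) - 1L
  mi <- digamma(k) + digamma(n) - mean(digamma(nx + 1) + digamma(ny + 1))
  max(mi, 0)
}

## ---- rank matrix ---------------------------------------------------------

#' Rank the vegetation indices by seven criteria
#'
#' Scores every index against nitrogen by |Pearson r|, |Spearman rho|,
#' the univariate F statistic, a continuous k-NN mutual-information
#' estimate, and impurity-based importances from seeded random-forest,
#' GBDT and XGBoost regressors (each averaged over \code{nRepeats}
#' seeds), then converts scores to ranks (1 = best) per criterion.
#'
#' @param viTable matrix from \code{\link{computeVITable}}.
#' @param nitrogen numeric response (mg/g), not constant; >= 10 samples.
#' @param seed base seed for the estimators.
#' @param nRepeats seeded repetitions of the tree-ensemble importances.
#' @return Integer matrix n_indices x 7 (columns Pearson, Spearman,
#'   Ftest, MutualInformation, RF, GBDT, XGB); each column is a
#'   permutation of 1..n.
#' @export
buildRankMatrix <- function(viTable, nitrogen, seed = 1L, nRepeats = 10L) {
  vt <- as.matrix(viTable)
  if (nrow(vt) < 10) stop("need at least 10 samples to rank indices")
  if (stats::sd(nitrogen) == 0) stop("nitrogen is constant; ranks undefined")
  if (anyNA(vt)) { # undefined VI cells: median-impute for scoring
    warning("undefined VI values median-imputed for ranking")
    for (j in seq_len(ncol(vt))) {
      vt[is.na(vt[, j]), j] <- stats::median(vt[, j], na.rm = TRUE)
    }
  }
  n <- nrow(vt)
  rP <- abs(as.numeric(stats::cor(vt, nitrogen)))
  rS <- abs(as.numeric(stats::cor(vt, nitrogen, method = "spearman")))
  r2 <- pmin(rP^2, 1 - 1e-15)
  fStat <- (n - 2) * r2 / (1 - r2)
  mi <- vapply(seq_len(ncol(vt)), function(j) {
    .ksgMI(vt[, j], nitrogen, k = 3L, seed = seed)
  }, numeric(1))
  treeImp <- function(kind) {
    acc <- numeric(ncol(vt))
    for (rep in seq_len(nRepeats)) {
      sd_ <- seed + rep
      if (kind == "rf") {
        fit <- ranger::ranger(
          y = nitrogen, x = data.frame(vt, check.names = FALSE),
          num.trees = 200L, importance = "impurity", seed = sd_,
          num.threads = 1L)
        imp <- fit$variable.importance[colnames(vt)]
      } else {
        obj <- .fitLearner(kind, vt, nitrogen,
          params = list(nrounds = 100L), seed = sd_)
        it <- xgboost::xgb.importance(model = obj$fit)
        imp <- stats::setNames(rep(0, ncol(vt)), colnames(vt))
        imp[it$Feature] <- it$Gain
      }
      acc <- acc + imp
    }
    acc / nRepeats
  }
  scores <- cbind(
    Pearson = rP, Spearman = rS, Ftest = fStat, MutualInformation = mi,
    RF = treeImp("rf"), GBDT = treeImp("gbdt"), XGB = treeImp("xgb")
  )
  rm <- apply(scores, 2, function(sc) rank(-sc, ties.method = "first"))
  rownames(rm) <- colnames(vt)
  storage.mode(rm) <- "integer"
  rm
}

## ---- ODCA ----------------------------------------------------------------

#' ODCA rank aggregation
#'
#' Overall difference combination assessment: each criterion's ranks are
#' normalized to [0, 1] via (r - 1)/(J - 1), the comprehensive score of
#' an index is the mean of its normalized ranks, and the final ranking
#' orders scores ascending (best = 1). Score ties are broken by the
#' smaller best single-criterion rank, then by input row order.
#'
#' @param rankMatrix integer matrix, indices x criteria; every column a
#'   permutation of 1..J.
#' @param k size of the selected top subset (default 10).
#' @return data.frame with columns \code{index}, \code{score},
#'   \code{finalRank}, \code{selected}, ordered as the input rows; the
#'   top-k names are in \code{attr(, "topk")}.
#' @examples
#' rm <- cbind(A = c(1, 2, 3), B = c(2, 1, 3))
#' odcaRank(rm, k = 2)
#' @export
odcaRank <- function(rankMatrix, k = 10L) {
  rm <- as.matrix(rankMatrix)
  J <- nrow(rm)
  if (k > J) stop("k exceeds the number of indices")
  for (j in seq_len(ncol(rm))) {
    if (!setequal(rm[, j], seq_len(J))) {
      stop("column ", j, " is not a permutation of 1..", J)
    }
  }
  norm <- (rm - 1) / (J - 1)
  score <- rowMeans(norm)
  bestSingle <- apply(rm, 1, min)
  # ordering on the integer rank sums (same ordering as the normalized
  # mean, but exact where floating summation could split a tie)
  ord <- order(rowSums(rm), bestSingle, seq_len(J))
  finalRank <- integer(J)
  finalRank[ord] <- seq_len(J)
  out <- data.frame(
    index = rownames(rm) %||% paste0("VI", seq_len(J)),
    score = score, finalRank = finalRank,
    selected = finalRank <= k,
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(out, "topk") <- out$index[order(out$finalRank)][seq_len(k)]
  out
}

#' The published 24 x 7 vegetation-index rank table
#'
#' The per-criterion importance ranks of the 24 vegetation indices as
#' printed in the source study, shipped with the package so the ODCA
#' aggregation can be reproduced without the (undeposited) raw data.
#' The \code{FinalRankPublished} column is the printed consensus ranking.
#'
#' @return list with \code{ranks} (integer matrix 24 x 7, rownames = index
#'   names) and \code{finalPublished} (named integer vector).
#' @export
publishedRankTable <- function() {
  path <- system.file("extdata", "vi_rank_table.csv", package = "canopyn",
    mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  rm <- as.matrix(df[, c("Pearson", "Spearman", "Ftest",
    "MutualInformation", "RF", "GBDT", "XGB")])
  rownames(rm) <- df$index
  storage.mode(rm) <- "integer"
  list(ranks = rm,
    finalPublished = stats::setNames(as.integer(df$FinalRankPublished),
      df$index))
}
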