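## One-call orchestration: simulate (or load) -> FOD correlations ->
## band selection -> VI ranking -> spectral-index search -> stacked
## modeling on the fused feature set -> Shapley fusion, with artifacts
## and a reproducibility manifest written per stage. A single global
## seed fans out to fixed per-stage seeds, so stages are independently
## reproducible.

#' Pipeline configuration
#'
#' @param outDir output directory for stage artifacts.
#' @param inputCsv optional reflectance CSV (with nitrogen column); when
#'   NULL the synthetic generator provides the data.
#' @param synthetic a \code{\link{syntheticConfig}}.
#' @param seed global seed, fanned out per stage.
#' @param orders fractional-order grid.
#' @param selectionMethod \code{"gaspa"}, \code{"ga"} or \code{"spa"}.
#' @param ga a \code{\link{gaConfig}} (its seed is overridden by the
#'   stage seed).
#' @param kMin,kMax SPA subset-size range.
#' @param viTopK screened vegetation indices to keep.
#' @param siStride band stride of the exhaustive index search.
#' @param models model names for the final evaluation (any of the six;
#'   default stacking only).
#' @param featureSets feature sets to evaluate (default the full
#'   fusion).
#' @param stacking a \code{\link{stackingSpec}}.
#' @return list of class \code{PipelineConfig}.
#' @export
pipelineConfig <- function(outDir = tempfile("canopyn_run_"),
                           inputCsv = NULL,
                           synthetic = syntheticConfig(),
                           seed = 42L,
                           orders = fractionalOrderGrid(),
                           selectionMethod = c("gaspa", "ga", "spa"),
                           ga = gaConfig(populationSize = 30L,
                             generations = 30L),
                           kMin = 5L, kMax = 20L,
                           viTopK = 10L, siStride = 2L,
                           models = "stacking",
                           featureSets = "Spectra-VIs-SIs",
                           stacking = stackingSpec()) {
  structure(list(
    outDir = outDir, inputCsv = inputCsv, synthetic = synthetic,
    seed = as.integer(seed), orders = orders,
    selectionMethod = match.arg(selectionMethod), ga = ga,
    kMin = as.integer(kMin), kMax = as.integer(kMax),
    viTopK = as.integer(viTopK), siStride = as.integer(siStride),
    models = models, featureSets = featureSets, stacking = stacking
  ), class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields of \code{\link{pipelineConfig}} plus nested
#' \code{synthetic:} and \code{ga:} blocks mirroring their constructors.
#'
#' @param path YAML file.
#' @return list of class \code{PipelineConfig}.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  syn <- do.call(syntheticConfig, y$synthetic %||% list())
  ga <- do.call(gaConfig, y$ga %||% list())
  args <- y[setdiff(names(y), c("synthetic", "ga"))]
  do.call(pipelineConfig, c(args, list(synthetic = syn, ga = ga)))
}

.stageLog <- function(stage, msg) {
  message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), stage, msg))
}

.writeJson <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  path
}

#' Run the full estimation pipeline
#'
#' Executes every stage in order, writing each stage's artifact into
#' \code{cfg$outDir}: \code{spectra.csv} / \code{truth.csv},
#' \code{fod_correlations.csv}, \code{selection.json},
#' \code{vi_table.csv} + \code{rank_matrix.csv} + \code{odca.json},
#' \code{si_search.csv}, \code{metrics.json},
#' \code{fused_importance.csv} and \code{manifest.json}. With
#' \code{resume = TRUE}, stages whose artifact already exists are loaded
#' instead of recomputed, so deleting one artifact regenerates it and
#' everything downstream of it.
#'
#' @param cfg a \code{\link{pipelineConfig}}.
#' @param resume reuse existing stage artifacts.
#' @return Invisibly, a list with the per-stage results (spectra,
#'   selection, viRank, siSearch, metrics, fused, manifest).
#' @export
runPipeline <- function(cfg = pipelineConfig(), resume = FALSE) {
  stopifnot(inherits(cfg, "PipelineConfig"))
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  art <- function(f) file.path(cfg$outDir, f)
  dirty <- FALSE # once a stage recomputes, everything downstream must
  stage <- function(name, file, compute, load, save) {
    if (resume && !dirty && file.exists(art(file))) {
      .stageLog(name, paste("resume <-", file))
      return(load(art(file)))
    }
    dirty <<- TRUE
    t0 <- Sys.time()
    x <- tryCatch(compute(), error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
        call. = FALSE)
    })
    save(x, art(file))
    .stageLog(name, sprintf("-> %s (%.1fs)", file,
      as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    x
  }

  ## 1. data
  spectra <- stage("simulate", "spectra.csv",
    compute = function() {
      if (!is.null(cfg$inputCsv)) return(readSpectraCSV(cfg$inputCsv))
      syn <- cfg$synthetic
      syn$seed <- .stageSeed(cfg$seed, "simulate")
      sim <- simulateCanopy(syn)
      utils::write.csv(sim$truth$table, art("truth.csv"),
        row.names = FALSE)
      sim$spectra
    },
    load = readSpectraCSV,
    save = function(x, p) writeSpectraCSV(x, p))
  nit <- .getNitrogen(spectra)

  ## 2. FOD band correlations across the order grid
  fodCor <- stage("fod", "fod_correlations.csv",
    compute = function() {
      do.call(rbind, lapply(cfg$orders, function(a) {
        bc <- bandCorrelations(fodTransform(spectra, a), nit)
        cbind(alpha = a, bc)
      }))
    },
    load = function(p) utils::read.csv(p),
    save = function(x, p) utils::write.csv(x, p, row.names = FALSE))

  ## 3. band selection
  selection <- stage("selection", "selection.json",
    compute = function() {
      ga <- cfg$ga
      ga$seed <- .stageSeed(cfg$seed, "selection")
      switch(cfg$selectionMethod,
        ga = gaSelect(spectra, ga),
        spa = spaSelect(spectra, cfg$kMin, cfg$kMax),
        gaspa = gaSpaSelect(spectra, ga, cfg$kMin, cfg$kMax))
    },
    load = function(p) {
      j <- jsonlite::read_json(p, simplifyVector = TRUE)
      methods::new("SelectionResult", method = j$method,
        indices = as.integer(j$indices), wavelengths = j$wavelengths,
        trace = as.numeric(j$trace), cvRmse = j$cvRmse,
        seed = as.integer(j$seed), config = as.list(j$config))
    },
    save = function(x, p) .writeJson(list(
      method = x@method, indices = x@indices, wavelengths = x@wavelengths,
      trace = x@trace, cvRmse = x@cvRmse, seed = x@seed,
      config = x@config), p))

  ## 4. VI screening
  viRank <- stage("vi", "odca.json",
    compute = function() {
      vt <- computeVITable(spectra)
      utils::write.csv(vt, art("vi_table.csv"), row.names = FALSE)
      rm <- buildRankMatrix(vt, nit, seed = .stageSeed(cfg$seed, "vi"))
      utils::write.csv(cbind(index = rownames(rm), as.data.frame(rm)),
        art("rank_matrix.csv"), row.names = FALSE)
      od <- odcaRank(rm, k = cfg$viTopK)
      list(odca = od, topk = attr(od, "topk"))
    },
    load = function(p) jsonlite::read_json(p, simplifyVector = TRUE),
    save = function(x, p) .writeJson(x, p))

  ## 5. spectral-index search over the order grid
  siSearch <- stage("search", "si_search.csv",
    compute = function() {
      res <- searchOverOrders(spectra, orders = cfg$orders,
        stride = cfg$siStride)
      best <- attr(res, "bestPerFormula")
      utils::write.csv(best, art("si_best.csv"), row.names = FALSE)
      res
    },
    load = function(p) {
      res <- utils::read.csv(p, stringsAsFactors = FALSE)
      best <- utils::read.csv(art("si_best.csv"),
        stringsAsFactors = FALSE)
      attr(res, "bestPerFormula") <- best
      res
    },
    save = function(x, p) utils::write.csv(x, p, row.names = FALSE))

  ## 6. modeling on the requested feature sets
  recipe <- featureRecipe(selection = selection,
    viNames = viRank$topk,
    siBest = attr(siSearch, "bestPerFormula"))
  modelSeed <- .stageSeed(cfg$seed, "model")
  split <- splitDataset(nit, 0.7, modelSeed)
  fitsEnv <- new.env()
  metrics <- stage("model", "metrics.json",
    compute = function() {
      g <- evaluateFeatureSets(spectra, recipe, models = cfg$models,
        featureSets = cfg$featureSets, split = split,
        stacking = cfg$stacking, seed = modelSeed, returnFits = TRUE)
      fitsEnv$fits <- attr(g, "fits")
      attr(g, "fits") <- NULL
      g
    },
    load = function(p) jsonlite::read_json(p, simplifyVector = TRUE),
    save = function(x, p) .writeJson(x, p))

  ## 7. interpretation (needs a fitted stack; recompute if resumed away)
  fused <- stage("interpret", "fused_importance.csv",
    compute = function() {
      if (!"stacking" %in% cfg$models) return(data.frame())
      fs <- cfg$featureSets[length(cfg$featureSets)]
      key <- paste(fs, "stacking", sep = ":")
      fit <- fitsEnv$fits[[key]]
      if (is.null(fit)) { # metrics were resumed; refit the stack
        X <- buildFeatures(spectra, recipe, .featureSetDefs[[fs]])
        fit <- fitStacking(X, nit, split, cfg$stacking, modelSeed)
      }
      X <- buildFeatures(spectra, recipe, .featureSetDefs[[fs]])
      fuseImportance(fit, X[split$train, , drop = FALSE])
    },
    load = function(p) utils::read.csv(p, stringsAsFactors = FALSE),
    save = function(x, p) utils::write.csv(x, p, row.names = FALSE))

  ## manifest: config + seed fully determine every artifact
  cfgFile <- art("config.yaml")
  yaml::write_yaml(.configAsYaml(cfg), cfgFile)
  manifest <- list(
    package = "canopyn",
    version = as.character(utils::packageVersion("canopyn")),
    seed = cfg$seed,
    configHash = unname(tools::md5sum(cfgFile)),
    artifacts = list.files(cfg$outDir),
    rVersion = R.version.string
  )
  .writeJson(manifest, art("manifest.json"))
  invisible(list(spectra = spectra, fodCorrelations = fodCor,
    selection = selection, viRank = viRank, siSearch = siSearch,
    recipe = recipe, split = split, metrics = metrics, fused = fused,
    manifest = manifest))
}

.configAsYaml <- function(cfg) {
  list(
    seed = cfg$seed, orders = cfg$orders,
    selectionMethod = cfg$selectionMethod,
    kMin = cfg$kMin, kMax = cfg$kMax, viTopK = cfg$viTopK,
    siStride = cfg$siStride, models = cfg$models,
    featureSets = cfg$featureSets,
    synthetic = unclass(cfg$synthetic)[
      c("nPerTreatment", "treatmentMeans", "treatmentSds", "noiseSd",
        "seed")],
    ga = unclass(cfg$ga)
  )
}
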