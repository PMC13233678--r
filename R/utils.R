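## small internal helpers

.getNitrogen <- function(x) {
  n <- SummarizedExperiment::colData(x)$nitrogen
  if (is.null(n)) NULL else as.numeric(n)
}

# Fan a single pipeline seed out to per-stage seeds via a fixed affine
# hash, keeping every derived seed a valid 32-bit integer.
.stageSeed <- function(seed, stage) {
  stages <- c("simulate", "fod", "selection", "vi", "search", "model",
    "interpret")
  k <- match(stage, stages)
  if (is.na(k)) stop("unknown stage: ", stage)
  as.integer((as.numeric(seed) * 7 + k * 1009) %% .Machine$integer.max)
}
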