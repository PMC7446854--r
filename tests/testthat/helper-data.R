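## Shared fixtures. Everything is generated in code from fixed seeds; the
## expensive calibrated benchmark objects are cached per test run.

tinyConfig <- function(seed = 303) {
  simulationConfig(datasetId = 1, n = 80, m = 30, nSignal = 4,
                   concentration = 40, sigmaLog = 1.2,
                   totalReadsRange = c(2000, 6000), masterSeed = seed)
}

## small ready-made table + covariates pair
tinyData <- function(seed = 303, replicate = 0) {
  generateDataset(tinyConfig(seed), replicate)
}

.cache <- new.env(parent = emptyenv())

dataPairT <- function(d, idx) {
  list(table = subsetSamples(d$table, idx),
       covs = subsetSamples(d$covs, idx))
}

## calibrated dataset-1 configuration (anchors: majority prevalence 0.6,
## oracle test ER 0.04), computed once per test session
calibratedConfig <- function() {
  if (is.null(.cache$cal)) {
    cfg <- simulationConfig(datasetId = 1, masterSeed = 2024)
    .cache$cal <- calibrateSignal(cfg, reps = 4, seed = 71)
  }
  .cache$cal
}

## cached calibrated replicates with their 80/20 splits
calibratedReplicate <- function(r) {
  key <- paste0("rep", r)
  if (is.null(.cache[[key]])) {
    cal <- calibratedConfig()
    d <- generateDataset(cal, r)
    sp <- splitTrainTest(phenotype(d$covs), 0.8,
                         seed = derivedSeed(2024, r, "split"))
    d$train <- list(table = subsetSamples(d$table, sp$train),
                    covs = subsetSamples(d$covs, sp$train))
    d$test <- list(table = subsetSamples(d$table, sp$test),
                   covs = subsetSamples(d$covs, sp$test))
    .cache[[key]] <- d
  }
  .cache[[key]]
}

## cached full-data screening on a calibrated replicate
calibratedScreen <- function(r, model) {
  key <- paste0("scr", r, model)
  if (is.null(.cache[[key]])) {
    d <- calibratedReplicate(r)
    .cache[[key]] <- screenOtus(d$table, d$covs, model = model,
                                includeRandom = TRUE)
  }
  .cache[[key]]
}

## cached train-only screening (for the prediction strategies)
calibratedTrainScreen <- function(r, model = "tpnb") {
  key <- paste0("trscr", r, model)
  if (is.null(.cache[[key]])) {
    d <- calibratedReplicate(r)
    .cache[[key]] <- screenOtus(d$train$table, d$train$covs, model = model,
                                includeRandom = TRUE)
  }
  .cache[[key]]
}
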