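## Simulation-study driver and deterministic fixture generation.

#' @useDynLib zimbPredict, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

screeningPowerRow <- function(screening, truth, qCutoff = 0.05) {
  tab <- screenTable(screening)
  sig <- truth$signal_indices
  hit <- tab$q_value[sig] <= qCutoff
  testable <- tab$regime[sig] != "dropped"
  c(n_selected_signals = sum(hit),
    n_selected_total = sum(tab$q_value <= qCutoff),
    power_raw = mean(hit),
    power_testable = if (any(testable)) sum(hit & testable) / sum(testable)
                     else NA_real_,
    n_testable_signals = sum(testable))
}

#' Run a reduced simulation study
#'
#' Per replicate: generate a benchmark dataset, screen the full replicate
#' with each count model (screening table: signal recovery and power at
#' q <= 0.05, under both denominator conventions - over all 20 signal taxa
#' and over the non-dropped signal taxa), then evaluate the oracle and the
#' requested strategies on a stratified 80/20 split, with all selection and
#' tuning on the training portion only. Means and SDs over replicates are
#' returned in long-format tables.
#'
#' @param config a (calibrated) \code{simulationConfig}.
#' @param reps number of replicates (>= 2).
#' @param models screening models for the screening table and the
#'   screening-based strategies.
#' @param transforms transforms to evaluate ("asin", "binary").
#' @param strategies subset of c("lasso", "screen_glm", "screen_lasso").
#' @param includeRandom logical; use random-factor dummies/intercepts.
#' @param qCutoff screening q-value threshold.
#' @param seed seed controlling splits and fold assignment.
#' @return list(screening = data.frame, prediction = data.frame,
#'   per_replicate = list).
#' @export
runSimulationStudy <- function(config, reps = 2, models = "tpnb",
                               transforms = "asin",
                               strategies = c("lasso", "screen_glm",
                                              "screen_lasso"),
                               includeRandom = TRUE, qCutoff = 0.05,
                               seed = 1) {
  stopifnot(reps >= 2)
  scrRows <- list(); predRows <- list(); perRep <- list()
  for (r in seq_len(reps)) {
    d <- generateDataset(config, r)
    sp <- splitTrainTest(phenotype(d$covs), 0.8,
                         seed = derivedSeed(seed, r, "split"))
    tr <- dataPair(d, sp$train); te <- dataPair(d, sp$test)

    repRec <- list()
    for (mod in models) {
      scrFull <- tryCatch(
        screenOtus(d$table, d$covs, model = mod,
                   includeRandom = includeRandom),
        error = function(e) NULL)
      if (!is.null(scrFull))
        scrRows[[paste(mod, r)]] <-
          data.frame(model = mod, replicate = r,
                     t(screeningPowerRow(scrFull, d$truth, qCutoff)))
    }
    ## training-data screening, shared by the screening strategies and
    ## both transforms
    scrTrain <- list()
    needScreen <- any(c("screen_glm", "screen_lasso") %in% strategies)
    if (needScreen)
      for (mod in models)
        scrTrain[[mod]] <- tryCatch(
          screenOtus(tr$table, tr$covs, model = mod,
                     includeRandom = includeRandom),
          error = function(e) NULL)

    evalOne <- function(res, method, transform) {
      mr <- metricsReport(res$proba, res$y)
      data.frame(method = method, transform = transform, replicate = r,
                 er = mr$er, auc = mr$auc, auprc = mr$auprc,
                 n_selected = length(res$selected),
                 n_true_selected =
                   sum(res$selected %in% d$truth$signal_indices))
    }
    k <- paste0("r", r)
    orc <- oracleBenchmark(tr, te, d$truth, includeRandom = includeRandom)
    predRows[[paste("oracle", r)]] <- evalOne(orc, "oracle", "asin")
    for (tf in transforms) {
      if ("lasso" %in% strategies) {
        res <- strategyLasso(tr, te, transform = tf,
                             includeRandom = includeRandom,
                             seed = derivedSeed(seed, r, "cv"))
        predRows[[paste("lasso", tf, r)]] <- evalOne(res, "lasso", tf)
      }
      for (mod in models) {
        if ("screen_glm" %in% strategies && !is.null(scrTrain[[mod]])) {
          res <- strategyScreenGlm(tr, te, model = mod, qCutoff = qCutoff,
                                   transform = tf,
                                   includeRandom = includeRandom,
                                   screening = scrTrain[[mod]])
          predRows[[paste(mod, "glm", tf, r)]] <-
            evalOne(res, paste0(mod, "+glm"), tf)
        }
        if ("screen_lasso" %in% strategies && !is.null(scrTrain[[mod]])) {
          res <- strategyScreenLasso(tr, te, model = mod, qCutoff = qCutoff,
                                     transform = tf,
                                     includeRandom = includeRandom,
                                     seed = derivedSeed(seed, r, "cv"),
                                     screening = scrTrain[[mod]])
          predRows[[paste(mod, "lasso", tf, r)]] <-
            evalOne(res, paste0(mod, "+lasso"), tf)
        }
      }
    }
    perRep[[k]] <- repRec
  }
  agg <- function(df, keys, vars) {
    if (length(df) == 0) return(data.frame())
    sp <- split(df, df[keys], drop = TRUE)
    do.call(rbind, lapply(sp, function(g) {
      out <- g[1, keys, drop = FALSE]
      for (v in vars) {
        out[[paste0(v, "_mean")]] <- mean(g[[v]], na.rm = TRUE)
        out[[paste0(v, "_sd")]] <- stats::sd(g[[v]], na.rm = TRUE)
      }
      out
    }))
  }
  scrDf <- if (length(scrRows)) do.call(rbind, scrRows) else data.frame()
  predDf <- if (length(predRows)) do.call(rbind, predRows) else data.frame()
  list(screening = agg(scrDf, "model",
                       c("n_selected_signals", "n_selected_total",
                         "power_raw", "power_testable")),
       prediction = agg(predDf, c("method", "transform"),
                        c("er", "auc", "auprc", "n_true_selected")),
       screening_replicates = scrDf, prediction_replicates = predDf)
}

#' Write small deterministic fixtures
#'
#' Emits a toy counts TSV, a matching metadata TSV, and a small simulation
#' config, all deterministic in the seed. Used by the test suite; no
#' network, no randomness beyond the seed.
#'
#' @param outDir writable directory.
#' @param seed RNG seed.
#' @return paths of the written files, invisibly.
#' @export
makeFixtures <- function(outDir, seed = 42) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  cfg <- simulationConfig(datasetId = 1, n = 60, m = 25,
                          nSignal = 4, concentration = 40,
                          totalReadsRange = c(500, 2000),
                          masterSeed = seed)
  d <- generateDataset(cfg, 0)
  countsPath <- file.path(outDir, "toy_counts.tsv")
  writeCounts(d$table, countsPath)
  md <- data.frame(sample_id = sampleIDs(d$table),
                   phenotype = as.character(phenotype(d$covs)),
                   fixedFactors(d$covs),
                   W = as.character(randomFactors(d$covs)$W))
  mdPath <- file.path(outDir, "toy_metadata.tsv")
  utils::write.table(md, mdPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cfgPath <- file.path(outDir, "toy_config.txt")
  writeSimulationConfig(cfg, cfgPath)
  invisible(c(countsPath, mdPath, cfgPath))
}
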