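test_that("stratified splits are disjoint, exhaustive and balanced", {
  y <- factor(rep(c("0", "1"), c(300, 200)))
  sp <- splitTrainTest(y, 0.8, seed = 2)
  expect_length(sp$train, 400)
  expect_length(sp$test, 100)
  expect_identical(sort(c(sp$train, sp$test)), seq_along(y))
  expect_length(intersect(sp$train, sp$test), 0)
  ## per-class proportions within one sample of the overall fraction
  for (lev in levels(y)) {
    nTr <- sum(y[sp$train] == lev)
    expect_lte(abs(nTr - 0.8 * sum(y == lev)), 1)
  }
  expect_error(splitTrainTest(factor(c("a", "b", "b")), 0.8, 1),
               "at least 2")
})

test_that("strategies fall back to covariates-only on empty selection", {
  d <- calibratedReplicate(1)
  m <- ncol(counts(d$table))
  emptyScr <- new("ScreeningResult",
                  table = data.frame(taxon_id = taxonIDs(d$table),
                                     regime = "dropped", zero_prop = 1,
                                     statistic = NA_real_, df = NA_real_,
                                     p_value = 1, q_value = 1,
                                     converged = FALSE),
                  model = "tpnb", includeRandom = TRUE)
  g <- strategyScreenGlm(d$train, d$test, screening = emptyScr)
  expect_length(g$selected, 0)
  expect_true(all(is.finite(g$proba)))
  expect_equal(nrow(g$proba), length(d$test$covs@sampleIDs))
  l <- strategyScreenLasso(d$train, d$test, screening = emptyScr, seed = 3)
  expect_length(l$selected, 0)
  expect_true(all(abs(rowSums(l$proba) - 1) < 1e-8))
})

test_that("screen+LASSO with full selection reduces to plain LASSO", {
  d <- calibratedReplicate(1)
  m <- ncol(counts(d$table))
  fullScr <- new("ScreeningResult",
                 table = data.frame(taxon_id = taxonIDs(d$table),
                                    regime = "nb", zero_prop = 0,
                                    statistic = 1, df = 1,
                                    p_value = 0.001, q_value = 0.001,
                                    converged = TRUE),
                 model = "tpnb", includeRandom = TRUE)
  a <- strategyLasso(d$train, d$test, "asin", TRUE, seed = 11)
  b <- strategyScreenLasso(d$train, d$test, transform = "asin",
                           includeRandom = TRUE, screening = fullScr,
                           seed = 11)
  expect_equal(a$lambda, b$lambda)
  expect_equal(a$proba, b$proba, tolerance = 1e-10)
})

test_that("external CV predicts every sample exactly once, deterministically", {
  d <- tinyData(23)
  strat <- function(train, test, foldSeed)
    strategyLasso(train, test, "asin", TRUE,
                  cvSpec = list(type = "kfold", k = 4), nLambda = 25,
                  seed = foldSeed)
  r1 <- externalCV(d$table, d$covs, strat,
                   scheme = list(type = "kfold", k = 5), seed = 13)
  expect_equal(sum(!is.na(r1$yhat)), length(r1$y))
  expect_equal(r1$failures, 0)
  expect_true(all(abs(rowSums(r1$proba) - 1) < 1e-8))
  r2 <- externalCV(d$table, d$covs, strat,
                   scheme = list(type = "kfold", k = 5), seed = 13)
  expect_identical(r1$proba, r2$proba)
  expect_identical(r1$yhat, r2$yhat)
  ## loocv: one held-out prediction per sample
  small <- tinyData(24)
  keep <- seq_len(30)
  tb <- subsetSamples(small$table, keep)
  cv <- subsetSamples(small$covs, keep)
  rl <- externalCV(tb, cv, function(train, test, foldSeed)
    strategyLasso(train, test, "asin", FALSE,
                  cvSpec = list(type = "kfold", k = 3), nLambda = 15,
                  seed = foldSeed),
    scheme = list(type = "loocv"))
  expect_equal(sum(!is.na(rl$yhat)), 30)
})

test_that("the study driver emits finite tables with the expected schema", {
  cfg <- tinyConfig(404)
  out <- runSimulationStudy(cfg, reps = 2, models = "nb",
                            transforms = "asin",
                            strategies = c("lasso", "screen_glm"),
                            includeRandom = TRUE, seed = 6)
  expect_true(all(c("model", "power_raw_mean", "power_testable_mean",
                    "n_selected_signals_mean") %in% names(out$screening)))
  expect_true(all(c("method", "transform", "er_mean", "er_sd", "auc_mean")
                  %in% names(out$prediction)))
  expect_true(all(is.finite(out$prediction$er_mean)))
  expect_setequal(unique(out$prediction_replicates$method),
                  c("oracle", "lasso", "nb+glm"))
  expect_true(all(out$prediction_replicates$er >= 0 &
                  out$prediction_replicates$er <= 1))
})

test_that("oracle benchmark degrades when the group effect is withheld", {
  ers <- vapply(1:4, function(r) {
    d <- calibratedReplicate(r)
    withW <- oracleBenchmark(d$train, d$test, d$truth, includeRandom = TRUE)
    noW <- oracleBenchmark(d$train, d$test, d$truth, includeRandom = FALSE)
    errorRate(noW$yhat, noW$y) - errorRate(withW$yhat, withW$y)
  }, 0)
  ## the group effect carries real information; allow Monte-Carlo slack
  expect_gte(mean(ers), -0.01)
})
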