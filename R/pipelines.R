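## The three predictive strategies, the oracle benchmark, and the
## leakage-safe evaluation protocols (80/20 split; external CV with
## per-fold re-screening).

#' Stratified train/test split
#'
#' @param y phenotype labels (stratification variable).
#' @param trainFrac training fraction in (0, 1).
#' @param seed RNG seed.
#' @return list(train=, test=) of disjoint, exhaustive index vectors.
#' @export
splitTrainTest <- function(y, trainFrac = 0.8, seed = 1) {
  stopifnot(trainFrac > 0, trainFrac < 1)
  y <- as.factor(y)
  if (any(table(y) < 2)) stop("every class needs at least 2 members")
  set.seed(seed)
  train <- integer(0)
  for (lev in levels(y)) {
    idx <- which(y == lev)
    nTr <- round(trainFrac * length(idx))
    nTr <- min(max(nTr, 1), length(idx) - 1)
    train <- c(train, sample(idx, nTr))
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(y), train))
}

## internal: wrap data pieces
dataPair <- function(d, idx) {
  list(table = subsetSamples(d$table, idx),
       covs = subsetSamples(d$covs, idx))
}

newPredictionResult <- function(proba, y, yhat, strategy, lambda = NA,
                                selected = integer(0), coef = NULL) {
  structure(list(proba = proba, y = y, yhat = yhat, strategy = strategy,
                 lambda = lambda, selected = selected, coef = coef),
            class = "predictionResult")
}

#' @export
print.predictionResult <- function(x, ...) {
  cat("predictionResult [", x$strategy, "]:", length(x$y), "samples; ER =",
      signif(errorRate(x$yhat, x$y), 3), "\n")
  invisible(x)
}

## selected OTU rows of a coefficient matrix (any class nonzero)
selectedOtuRows <- function(coef, design) {
  roles <- design$column_roles       # includes intercept first
  otuRows <- which(roles == "otu")   # rows of coef align with columns
  nz <- rowSums(abs(coef[otuRows, , drop = FALSE]) > 1e-10) > 0
  which(nz)                          # indices into the OTU block
}

#' Strategy 1: LASSO on all transformed taxa
#'
#' Builds the training design from all transformed taxa plus the fixed
#' factors (and random-factor dummies when \code{includeRandom}), selects
#' lambda by cross-validated error rate on the training data only, refits at
#' the chosen lambda, and predicts the test samples with training-derived
#' standardisation statistics.
#'
#' @param train,test list(table=, covs=) pairs.
#' @param transform "asin" or "binary".
#' @param includeRandom add random-factor dummies to the design?
#' @param cvSpec CV scheme for lambda (default 10-fold).
#' @param nLambda lambda-grid size (default 200).
#' @param seed RNG seed (folds).
#' @return A \code{predictionResult} with out-of-sample probabilities, the
#'   selected lambda and the selected taxa.
#' @export
strategyLasso <- function(train, test, transform = "asin",
                          includeRandom = TRUE,
                          cvSpec = list(type = "kfold", k = 10),
                          nLambda = 200, seed = 1) {
  y <- droplevels(phenotype(train$covs))
  trT <- transformCounts(train$table, transform)
  design <- buildDesign(trT, train$covs, includeRandom, standardize = TRUE)
  if (sum(design$column_roles == "otu") == 0 &&
      sum(design$column_roles != "intercept") == 0)
    stop("design has no predictors")
  grid <- lambdaGrid(design, y, nLambda = nLambda)
  cv <- cvSelectLambda(design, y, grid, scheme = cvSpec, seed = seed)
  coef <- fitLassoMlr(design, y, cv$lambda)
  teX <- applyDesign(design, transformCounts(test$table, transform),
                     test$covs)
  proba <- predictProba(coef, teX)
  maj <- names(which.max(table(y)))
  newPredictionResult(proba, phenotype(test$covs),
                      argmaxPredict(proba, maj),
                      strategy = paste0("lasso-", transform),
                      lambda = cv$lambda,
                      selected = selectedOtuRows(coef, design), coef = coef)
}

#' Strategy 2: screening + GLM
#'
#' Screens taxa on the training data only (\code{\link{screenOtus}}),
#' selects those with q <= \code{qCutoff}, and fits a multinomial logistic
#' GLM (tiny ridge 1e-6 against separation) on the selected transformed
#' taxa plus covariates. An empty selection falls back to the
#' covariates-only GLM.
#'
#' @inheritParams strategyLasso
#' @param model screening count model ("tpnb", "nb", "zinb").
#' @param qCutoff q-value selection threshold.
#' @param screening optional precomputed training-data
#'   \linkS4class{ScreeningResult} (it must come from the training samples
#'   only; pass NULL to screen here).
#' @return A \code{predictionResult}; \code{selected} holds the screened
#'   taxon indices.
#' @export
strategyScreenGlm <- function(train, test, model = "tpnb", qCutoff = 0.05,
                              transform = "asin", includeRandom = TRUE,
                              screening = NULL) {
  if (is.null(screening))
    screening <- screenOtus(train$table, train$covs, model = model,
                            includeRandom = includeRandom)
  sel <- selectOtus(screening, qCutoff)
  y <- droplevels(phenotype(train$covs))
  trT <- transformCounts(train$table, transform)[, sel, drop = FALSE]
  design <- buildDesign(trT, train$covs, includeRandom, standardize = TRUE)
  coef <- fitGlmRidge(design, y)
  teT <- transformCounts(test$table, transform)[, sel, drop = FALSE]
  teX <- applyDesign(design, teT, test$covs)
  proba <- predictProba(coef, teX)
  maj <- names(which.max(table(y)))
  newPredictionResult(proba, phenotype(test$covs),
                      argmaxPredict(proba, maj),
                      strategy = paste0(model, "+glm-", transform),
                      selected = sel, coef = coef)
}

#' Strategy 3: screening + LASSO
#'
#' As \code{\link{strategyScreenGlm}} but the model on the selected subset
#' is the penalised multinomial fit with CV-selected lambda. An empty
#' selection falls back to a covariates-only penalised fit.
#'
#' @inheritParams strategyScreenGlm
#' @param cvSpec,nLambda,seed lambda-selection controls.
#' @return A \code{predictionResult}.
#' @export
strategyScreenLasso <- function(train, test, model = "tpnb", qCutoff = 0.05,
                                transform = "asin", includeRandom = TRUE,
                                cvSpec = list(type = "kfold", k = 10),
                                nLambda = 200, seed = 1,
                                screening = NULL) {
  if (is.null(screening))
    screening <- screenOtus(train$table, train$covs, model = model,
                            includeRandom = includeRandom)
  sel <- selectOtus(screening, qCutoff)
  y <- droplevels(phenotype(train$covs))
  trT <- transformCounts(train$table, transform)[, sel, drop = FALSE]
  design <- buildDesign(trT, train$covs, includeRandom, standardize = TRUE)
  grid <- lambdaGrid(design, y, nLambda = nLambda)
  cv <- cvSelectLambda(design, y, grid, scheme = cvSpec, seed = seed)
  coef <- fitLassoMlr(design, y, cv$lambda)
  teT <- transformCounts(test$table, transform)[, sel, drop = FALSE]
  teX <- applyDesign(design, teT, test$covs)
  proba <- predictProba(coef, teX)
  maj <- names(which.max(table(y)))
  keptWithin <- selectedOtuRows(coef, design)
  newPredictionResult(proba, phenotype(test$covs),
                      argmaxPredict(proba, maj),
                      strategy = paste0(model, "+lasso-", transform),
                      lambda = cv$lambda,
                      selected = sel[keptWithin], coef = coef)
}

#' Oracle benchmark
#'
#' Fits the classifier on exactly the true signal taxa (transformed) plus
#' X1, X2 (and W dummies when \code{includeRandom}) - the upper bound on
#' achievable accuracy in the simulation designs.
#'
#' @inheritParams strategyLasso
#' @param truth simulation truth (signal_indices).
#' @return A \code{predictionResult}.
#' @export
oracleBenchmark <- function(train, test, truth, includeRandom = TRUE,
                            transform = "asin") {
  sel <- truth$signal_indices
  y <- droplevels(phenotype(train$covs))
  trT <- transformCounts(train$table, transform)[, sel, drop = FALSE]
  design <- buildDesign(trT, train$covs, includeRandom, standardize = TRUE)
  coef <- fitGlmRidge(design, y)
  teT <- transformCounts(test$table, transform)[, sel, drop = FALSE]
  teX <- applyDesign(design, teT, test$covs)
  proba <- predictProba(coef, teX)
  maj <- names(which.max(table(y)))
  newPredictionResult(proba, phenotype(test$covs),
                      argmaxPredict(proba, maj),
                      strategy = "oracle", selected = sel, coef = coef)
}

#' External cross-validation with per-fold re-selection
#'
#' Runs the entire strategy - screening, lambda selection, fitting - inside
#' each training fold and assembles the out-of-fold predictions, so no
#' data-dependent selection ever sees a held-out sample. With
#' \code{scheme = list(type="loocv")} each sample is predicted from a model
#' trained on all others.
#'
#' @param table an \linkS4class{OTUTable}.
#' @param covs matching \linkS4class{SampleCovariates}.
#' @param strategyFun closure(train, test, foldSeed) returning a
#'   \code{predictionResult}.
#' @param scheme list(type="kfold", k=) or list(type="loocv").
#' @param seed RNG seed for fold assignment.
#' @return A \code{predictionResult} over all samples, with per-fold
#'   selections in \code{fold_selected} and failed folds counted in
#'   \code{failures}.
#' @export
externalCV <- function(table, covs, strategyFun,
                       scheme = list(type = "loocv"), seed = 1) {
  y <- droplevels(phenotype(covs))
  n <- length(y)
  if (identical(scheme$type, "loocv")) {
    fold <- seq_len(n)
  } else {
    stopifnot(scheme$k <= n)
    fold <- stratifiedFolds(y, scheme$k, seed)
  }
  proba <- NULL
  yhat <- rep(NA_character_, n)
  foldSel <- list()
  failures <- 0L
  d <- list(table = table, covs = covs)
  for (f in sort(unique(fold))) {
    te <- which(fold == f); tr <- which(fold != f)
    res <- tryCatch(
      strategyFun(dataPair(d, tr), dataPair(d, te),
                  foldSeed = derivedSeed(seed, f, "fold")),
      error = function(e) NULL)
    if (is.null(res)) { failures <- failures + 1L; next }
    if (is.null(proba))
      proba <- matrix(NA_real_, n, ncol(res$proba),
                      dimnames = list(NULL, colnames(res$proba)))
    proba[te, ] <- res$proba
    yhat[te] <- as.character(res$yhat)
    foldSel[[as.character(f)]] <- res$selected
  }
  out <- newPredictionResult(proba, y, yhat, strategy = "external-cv")
  out$fold_selected <- foldSel
  out$failures <- failures
  out
}
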