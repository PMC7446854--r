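# zimbPredict

Predictive analysis of zero-inflated microbiome count data.

16S rRNA surveys yield OTU count tables that are over-dispersed, full of
zeros, compositional (each sample is a draw of `T_i` total reads), and often
grouped (sites, families, countries). The common workflow — test each taxon
with a count model, threshold q-values — measures statistical association,
not predictivity. This package implements and evaluates the complementary
predictive workflow for a categorical phenotype `Y`:

1. **LASSO** — fit an L1-penalised multinomial logistic regression
   (soft-max likelihood, symmetric parameterisation, intercept unpenalised)

   `P(y_i = k | x_i) = exp(beta_k' x_i) / sum_l exp(beta_l' x_i)`

   to *all* taxa after a transform — the variance-stabilising
   `arcsin(sqrt(Z/T))` or the presence indicator `I(Z > 0)` — plus fixed
   and group covariates, with the penalty weight chosen by stratified
   cross-validated error rate over a 200-point geometric grid.
2. **screening+GLM** — first screen taxa with per-taxon count GLMMs
   (negative binomial, zero-inflated NB, or a two-part NB whose regime is
   chosen by the taxon's zero proportion), testing the phenotype by a
   likelihood-ratio test (`T_n = 2(logL1 - logL0)`, chi-square with
   `K-1` or `2(K-1)` df) with Benjamini–Hochberg q-values; then fit an
   (separation-guarded) unpenalised logistic model on the q ≤ 0.05 taxa.
3. **screening+LASSO** — the same screen followed by the penalised fit on
   the selected subset.

Random intercepts in the screen are integrated out by a Laplace
approximation with analytic gradients (validated against adaptive
Gauss–Hermite quadrature and glmmTMB). Evaluation uses error rate, the
baseline error rate `1 - max_k f_k`, the relative reduction `R²_ER`,
rank-based AUC and step-interpolated AUPRC. `externalCV()` re-runs the
entire strategy — screening included — inside every fold, so held-out
samples never inform selection.

A Dirichlet-multinomial simulator (`generateDataset()`) reproduces the
benchmark designs the methods were characterised on: 587 taxa, 20 signal
taxa with effects ±Unif(1.5, 2), two fixed factors, a 5-group random
factor, logistic phenotype with noise variance 10, and sequencing depths
Unif(10⁴, 3·10⁵); `calibrateSignal()` pins the generator to its two
anchors (majority-class prevalence 0.6, oracle test error 0.04).

## Worked example

```r
library(zimbPredict)

## a calibrated benchmark replicate: 500 samples x 587 taxa
cfg <- simulationConfig(datasetId = 1, masterSeed = 2024)
cal <- calibrateSignal(cfg, reps = 4, seed = 71)
d   <- generateDataset(cal, replicate = 1)
d$table
#> OTUTable: 500 samples x 587 taxa
#>   total reads: 10938-299086; overall zero fraction: 0.375

sp <- splitTrainTest(phenotype(d$covs), 0.8, seed = 1)
train <- list(table = subsetSamples(d$table, sp$train),
              covs  = subsetSamples(d$covs,  sp$train))
test  <- list(table = subsetSamples(d$table, sp$test),
              covs  = subsetSamples(d$covs,  sp$test))

## strategy 1: LASSO on all arcsin-sqrt taxa + covariates
fit <- strategyLasso(train, test, transform = "asin",
                     includeRandom = TRUE, seed = 1)
mr <- metricsReport(fit$proba, fit$y)
round(unlist(mr[c("er", "er0", "rer2", "auc", "auprc")]), 3)
#>    er   er0  rer2   auc auprc
#> 0.060 0.400 0.850 0.979 0.987
sum(fit$selected %in% d$truth$signal_indices)   # signal taxa recovered
#> 20

## strategy 2/3: two-part NB screen on the training data only
scr <- screenOtus(train$table, train$covs, model = "tpnb",
                  includeRandom = TRUE)
scr
#> ScreeningResult (tpnb, random intercepts): 587 taxa
#>   regimes: dropped 38; hurdle 311; logistic 44; nb 194
#>   q <= 0.05: 7 taxa
sg <- strategyScreenGlm(train, test, screening = scr)
errorRate(sg$yhat, sg$y)
#> [1] 0.24
```

The test error of 0.06 against a baseline of 0.40 (`R²_ER = 0.85`) shows
the phenotype is predictable from microbial composition plus covariates;
the selected-coefficient overlap shows the penalised model recovered all
20 true signal taxa of this replicate.

For a user-supplied dataset, read the TSVs, apply quality control, and use
leakage-safe external CV:

```r
tb <- readCounts("counts.tsv")
tb <- filterMinReads(tb, minReads = 10000)$table
tb <- filterPrevalence(tb, minPrevalence = 0.2)
cv <- readMetadata("metadata.tsv", tb, phenotypeCol = "status",
                   fixedCols = c("age", "sex"), randomCols = "site")
res <- externalCV(tb, cv, function(train, test, foldSeed)
  strategyScreenLasso(train, test, model = "zinb", transform = "binary",
                      seed = foldSeed),
  scheme = list(type = "loocv"))
metricsReport(res$proba, res$y)
```

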