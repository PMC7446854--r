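test_that("derived seeds are deterministic, distinct, and in range", {
  s1 <- derivedSeed(7, 3, "counts")
  expect_identical(s1, derivedSeed(7, 3, "counts"))
  expect_true(s1 >= 1 && s1 < 2^31)
  expect_false(s1 == derivedSeed(7, 3, "noise"))
  expect_false(s1 == derivedSeed(7, 4, "counts"))
  expect_false(s1 == derivedSeed(8, 3, "counts"))
})

test_that("stand-in alpha is a normalised heavy-tailed concentration", {
  expect_equal(makeStandinAlpha(2, concentration = 2,
                                weights = c(1, 1)), c(1, 1))
  a <- makeStandinAlpha(587, 300, 1.5, shapeSeed = 4)
  expect_length(a, 587)
  expect_true(all(a > 0))
  expect_equal(sum(a), 300)
  expect_error(makeStandinAlpha(10, concentration = -1), "positive")
  ## the sorted profile is invariant to relabelling by a different
  ## permutation of identical weights
  w <- exp(rnorm(50))
  a1 <- makeStandinAlpha(50, 10, weights = w)
  a2 <- makeStandinAlpha(50, 10, weights = w[c(2:50, 1)])
  expect_equal(sort(a1), sort(a2))
})

test_that("DM counts conserve totals and match the closed-form moments", {
  a <- c(1e9, 1e-9)
  cnt <- sampleDmCounts(a, rep(1000, 20), seed = 1)
  expect_true(all(cnt[, 1] == 1000))             # degenerate Dirichlet
  alpha <- c(2, 5, 13)
  tot <- rep(500, 4000)
  cnt <- sampleDmCounts(alpha, tot, seed = 2)
  expect_equal(rowSums(cnt), tot)                # conservation
  ## E[Z/T] = alpha / sum(alpha) within 3 MC standard errors
  A <- sum(alpha)
  pbar <- colMeans(cnt / 500)
  pexp <- alpha / A
  ## DM variance of the proportion: p(1-p)/T * (T+A)/(1+A)
  vexp <- pexp * (1 - pexp) / 500 * (500 + A) / (1 + A)
  se <- sqrt(vexp / 4000)
  expect_true(all(abs(pbar - pexp) < 3.5 * se))
  ## empirical variance shows the DM inflation factor (T+A)/(1+A) ~ 24.8,
  ## far above the multinomial variance
  vemp <- apply(cnt / 500, 2, var)
  expect_true(all(vemp / (pexp * (1 - pexp) / 500) > 15))
  expect_equal(vemp, vexp, tolerance = 0.1)
})

test_that("default generator produces genuine zero-inflation", {
  a <- makeStandinAlpha(587, shapeSeed = 9)
  cnt <- sampleDmCounts(a, rep(10000, 120), seed = 10)
  zp <- colMeans(cnt == 0)
  expect_gte(median(zp), 0.30)
})

test_that("sampled totals are discrete uniform over the stated range", {
  t1 <- sampleTotals(2000, c(10000, 300000), seed = 3)
  expect_true(all(t1 >= 10000 & t1 <= 300000))
  expect_identical(sampleTotals(5, c(7, 7), seed = 1), rep(7L, 5))
  t2 <- sampleTotals(1e5, c(100, 200), seed = 4)
  expect_lt(abs(mean(t2) - 150), 3 * sqrt(101^2 / 12 / 1e5) + 0.5)
})

test_that("covariates follow the stated designs", {
  cv <- generateCovariates(500, seed = 5)
  expect_true(all(cv$X1 >= 20 & cv$X1 <= 50))
  expect_identical(as.integer(table(cv$W)), rep(100L, 5)) # balanced groups
  cv2 <- generateCovariates(262, seed = 6)
  expect_identical(sort(as.integer(table(cv2$W)), decreasing = TRUE),
                   c(53L, 53L, 52L, 52L, 52L))
  ## X2 classes equiprobable
  big <- generateCovariates(60000, seed = 7)
  expect_true(all(abs(table(big$X2) / 60000 - 1 / 3) < 0.01))
})

test_that("the phenotype model matches its closed forms and conventions", {
  cfg <- tinyConfig()
  cfg$betaX1 <- 0; cfg$betaX2 <- c(0, 0); cfg$betaW <- rep(0, 5)
  cfg$epsilonVar <- 0; cfg$signalMultiplier <- 0
  d0 <- tinyData()
  cl <- list(X1 = fixedFactors(d0$covs)$X1, X2 = fixedFactors(d0$covs)$X2,
             W = randomFactors(d0$covs)$W)
  truth <- d0$truth
  ph <- generatePhenotype(counts(d0$table), totals(d0$table), cl, truth,
                          cfg, seed = 1)
  ## all coefficients zero, beta0 = 1: p = 1/(1+e) everywhere
  expect_equal(ph$p, rep(1 / (1 + exp(1)), cfg$n))
  ## the printed sign convention: large eta favours class "0"
  cfg$beta0 <- 50
  expect_equal(generatePhenotype(counts(d0$table), totals(d0$table), cl,
                                 truth, cfg, seed = 1)$p,
               rep(0, cfg$n), tolerance = 1e-12)
  cfg$beta0 <- -50
  expect_equal(generatePhenotype(counts(d0$table), totals(d0$table), cl,
                                 truth, cfg, seed = 1)$p, rep(1, cfg$n))
})

test_that("phenotypes are invariant to lockstep taxon permutation", {
  cfg <- tinyConfig()
  d <- tinyData()
  cl <- list(X1 = fixedFactors(d$covs)$X1, X2 = fixedFactors(d$covs)$X2,
             W = randomFactors(d$covs)$W)
  perm <- sample(ncol(counts(d$table)))
  truthP <- d$truth
  truthP$signal_indices <- match(d$truth$signal_indices, perm)
  p1 <- generatePhenotype(counts(d$table), totals(d$table), cl, d$truth,
                          cfg, seed = 2)
  p2 <- generatePhenotype(counts(d$table)[, perm], totals(d$table), cl,
                          truthP, cfg, seed = 2)
  expect_equal(p1$eta, p2$eta)
  expect_identical(p1$y, p2$y)
})

test_that("generateDataset is deterministic and honours the design table", {
  cfg <- tinyConfig(77)
  d1 <- generateDataset(cfg, 2)
  d2 <- generateDataset(cfg, 2)
  expect_identical(counts(d1$table), counts(d2$table))
  expect_identical(phenotype(d1$covs), phenotype(d2$covs))
  expect_identical(d1$truth$signal_betas, d2$truth$signal_betas)
  dOther <- generateDataset(cfg, 3)
  expect_false(identical(counts(d1$table), counts(dOther$table)))
  ## design 3 sample size; half positive / half negative signal effects
  cfg3 <- simulationConfig(datasetId = 3, m = 40, nSignal = 6,
                           concentration = 40,
                           totalReadsRange = c(2000, 6000), masterSeed = 5)
  d3 <- generateDataset(cfg3, 0)
  expect_equal(nrow(counts(d3$table)), 262)
  expect_equal(sum(d3$truth$signal_betas > 0), 3)
  expect_equal(sum(d3$truth$signal_betas < 0), 3)
  expect_true(all(abs(d3$truth$signal_betas) >= 1.5 &
                  abs(d3$truth$signal_betas) <= 2))
  ## full-size design: exactly 10 positive and 10 negative
  cal <- simulationConfig(datasetId = 1, masterSeed = 8)
  dFull <- generateDataset(cal, 0)
  expect_equal(sum(dFull$truth$signal_betas > 0), 10)
  expect_equal(sum(dFull$truth$signal_betas < 0), 10)
})

test_that("configs persist through the plain-text round trip", {
  cfg <- tinyConfig()
  cfg$beta0Offset <- -12.345
  cfg$signalMultiplier <- 28.57
  f <- withr::local_tempfile(fileext = ".txt")
  writeSimulationConfig(cfg, f)
  back <- readSimulationConfig(f)
  for (nm in names(cfg)) expect_equal(back[[nm]], cfg[[nm]], label = nm)
})

test_that("fixtures regenerate bit-identically and pass the IO round trip", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  f1 <- makeFixtures(d1, seed = 99)
  f2 <- makeFixtures(d2, seed = 99)
  for (i in seq_along(f1))
    expect_identical(readLines(f1[i]), readLines(f2[i]))
  tb <- readCounts(f1[1])
  expect_s4_class(tb, "OTUTable")
})
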