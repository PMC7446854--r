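test_that("nbLogPmf matches its closed forms and normalises", {
  ## z = 0: theta * (log theta - log(theta + mu))
  expect_equal(nbLogPmf(0, mu = 3, theta = 2), 2 * (log(2) - log(5)))
  ## normalisation over the support
  p <- sum(exp(nbLogPmf(0:4000, mu = 3, theta = 2)))
  expect_equal(p, 1, tolerance = 1e-10)
  ## agreement with the reference pmf
  expect_equal(nbLogPmf(0:50, mu = 7.3, theta = 0.8),
               dnbinom(0:50, size = 0.8, mu = 7.3, log = TRUE))
})

test_that("fitCountGlmm recovers trivial maximum-likelihood fits", {
  ## constant response, intercept only: MLE of the mean is the sample mean
  f <- fitCountGlmm(c(3, 3, 3, 3), X = matrix(1, 4, 1),
                    offset = rep(0, 4), family = "nb")
  expect_equal(unname(f$beta[1]), log(3), tolerance = 1e-4)
  ## a single group is confounded with the intercept: the marginal loglik
  ## equals the fixed-effects GLM loglik (sigma2 -> 0 branch)
  set.seed(31)
  z <- rnbinom(80, size = 2, mu = 9)
  X <- matrix(1, 80, 1)
  f1 <- fitCountGlmm(z, X, rep(0, 80), groups = factor(rep("g1", 80)),
                     family = "nb")
  f0 <- fitCountGlmm(z, X, rep(0, 80), groups = NULL, family = "nb")
  expect_equal(f1$loglik, f0$loglik, tolerance = 1e-5)
})

test_that("Laplace marginal log-likelihood matches glmmTMB across families", {
  set.seed(2)
  n <- 300; g <- factor(rep(1:5, each = 60))
  b <- rnorm(5, 0, 0.7); x <- rnorm(n)
  mu <- exp(0.5 + 0.4 * x + b[as.integer(g)])
  z <- ifelse(runif(n) < plogis(-0.7), 0, MASS::rnegbin(n, mu, theta = 1.5))
  X <- cbind(1, x)
  dd <- data.frame(z = z, x = x, g = g)
  fz <- fitCountGlmm(z, X, rep(0, n), g, family = "zinb")
  tmb <- glmmTMB::glmmTMB(z ~ x + (1 | g), ziformula = ~1,
                          family = glmmTMB::nbinom2, data = dd)
  expect_equal(fz$loglik, as.numeric(logLik(tmb)), tolerance = 1e-4)
  expect_equal(unname(fz$beta), unname(glmmTMB::fixef(tmb)$cond),
               tolerance = 1e-3)
  fh <- fitCountGlmm(z, X, rep(0, n), g, family = "hurdle")
  tmb2 <- glmmTMB::glmmTMB(z ~ x + (1 | g), ziformula = ~x + (1 | g),
                           family = glmmTMB::truncated_nbinom2, data = dd)
  expect_equal(fh$loglik, as.numeric(logLik(tmb2)), tolerance = 1e-4)
})

test_that("tpnbDispatch maps zero proportions to the printed regimes", {
  expect_identical(tpnbDispatch(0.05), "nb")
  expect_identical(tpnbDispatch(0.10), "nb")      # boundary to lower rule
  expect_identical(tpnbDispatch(0.50), "hurdle")
  expect_identical(tpnbDispatch(0.80), "hurdle")  # boundary to lower rule
  expect_identical(tpnbDispatch(0.85), "logistic")
  expect_identical(tpnbDispatch(0.90), "dropped")
  expect_identical(tpnbDispatch(0.95), "dropped")
  expect_identical(tpnbDispatch(c(0, 1)), c("nb", "dropped"))
})

test_that("the LRT p-value follows the chi-square reference", {
  mk <- function(ll) structure(list(loglik = ll, converged = TRUE),
                               class = "glmmFit")
  expect_equal(lrtPvalue(mk(-10), mk(-10), 1)$p_value, 1)
  expect_equal(lrtPvalue(mk(-10), mk(-10 + 3.8415 / 2), 1)$p_value, 0.05,
               tolerance = 1e-3)
  expect_equal(lrtPvalue(mk(-10), mk(-10 + 5.9915 / 2), 2)$p_value, 0.05,
               tolerance = 1e-3)
  ## numerically negative statistic clips to zero
  expect_equal(lrtPvalue(mk(-10), mk(-10.001), 1)$p_value, 1)
  expect_error(lrtPvalue(mk(-10), mk(-9), 0), "df")
  ## non-convergence is conservative
  bad <- structure(list(loglik = -8, converged = FALSE), class = "glmmFit")
  expect_equal(lrtPvalue(mk(-10), bad, 1)$p_value, 1)
})
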