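## small worked classification fixture
lassoToy <- function(seed = 55, n = 20, p = 3, K = 2) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, dimnames = list(NULL, paste0("x", 1:p)))
  bTrue <- rep(0, p); bTrue[1] <- 1.2; if (p >= 2) bTrue[2] <- -0.8
  eta <- X %*% bTrue
  y <- factor(ifelse(eta + rnorm(n) > 0, "b", "a"), levels = c("a", "b"))
  if (length(unique(y)) < 2) y[1:2] <- c("a", "b")
  list(V = cbind(`(Intercept)` = 1, X), y = y)
}

test_that("lambdaGrid is geometric from a verified lambda_max", {
  toy <- lassoToy()
  g <- lambdaGrid(toy$V, toy$y, nLambda = 2, ratio = 1e-4)
  expect_length(g, 2)
  expect_equal(g[2], 1e-4 * g[1])
  g200 <- lambdaGrid(toy$V, toy$y, nLambda = 200)
  expect_length(g200, 200)
  expect_true(all(diff(g200) < 0))
  ## log-spacing is uniform (geometric grid)
  expect_equal(sd(diff(log(g200))), 0, tolerance = 1e-12)
  ## fitting exactly at lambda_max leaves every penalised coefficient zero
  cf <- fitLassoMlr(toy$V, toy$y, g200[1])
  expect_true(all(abs(cf[-1, ]) < 1e-8))
  ## and the fitted probabilities are the class frequencies
  pr <- predictProba(cf, toy$V)
  expect_equal(unname(pr[1, ]), unname(as.vector(table(toy$y) / 20)),
               tolerance = 1e-4)
  ## just below lambda_max at least one coefficient activates
  cf2 <- fitLassoMlr(toy$V, toy$y, g200[1] * 0.9)
  expect_true(any(abs(cf2[-1, ]) > 1e-8))
  expect_error(lambdaGrid(toy$V, factor(rep("a", 20))), "classes")
})

test_that("the penalised objective matches an independent proximal solver", {
  for (seed in c(55, 56)) {
    toy <- lassoToy(seed)
    lam <- 2.5
    cf <- fitLassoMlr(toy$V, toy$y, lam)
    ref <- proxLassoMlr(toy$V, toy$y, lam)
    o1 <- lassoObjective(cf, toy$V, toy$y, lam)
    o2 <- lassoObjective(ref, toy$V, toy$y, lam)
    expect_lt(abs(o1 - o2), 1e-5)
  }
  ## K = 3 classes
  set.seed(57)
  X <- matrix(rnorm(60 * 3), 60)
  colnames(X) <- paste0("x", 1:3)
  y <- factor(sample(c("a", "b", "c"), 60, TRUE, prob = c(.5, .3, .2)))
  V <- cbind(`(Intercept)` = 1, X)
  lam <- 3
  o1 <- lassoObjective(fitLassoMlr(V, y, lam), V, y, lam)
  o2 <- lassoObjective(proxLassoMlr(V, y, lam), V, y, lam)
  expect_lt(abs(o1 - o2), 1e-5)
})

test_that("KKT conditions hold at the returned solution", {
  toy <- lassoToy(58, n = 40, p = 5)
  lam <- 1.5
  cf <- fitLassoMlr(toy$V, toy$y, lam)
  K <- nlevels(toy$y)
  ind <- outer(as.integer(toy$y), seq_len(K), function(a, b) (a == b) + 0)
  eta <- toy$V %*% cf
  P <- exp(eta - apply(eta, 1, max)); P <- P / rowSums(P)
  grad <- crossprod(toy$V, P - ind)         # d(-loglik)/d(coef)
  tol <- 1e-3
  pen <- grad[-1, , drop = FALSE]
  act <- abs(cf[-1, ]) > 1e-8
  expect_true(all(abs(pen[!act]) <= lam + tol))
  expect_true(all(abs(pen[act] + lam * sign(cf[-1, ][act])) < tol))
  ## intercept rows are unpenalised stationary points
  expect_true(all(abs(grad[1, ]) < tol))
})

test_that("duplicated predictors split mass without changing the fit", {
  toy <- lassoToy(59, n = 40, p = 3)
  V2 <- cbind(toy$V, x1dup = toy$V[, "x1"])
  lam <- 1.2
  cf1 <- fitLassoMlr(toy$V, toy$y, lam)
  cf2 <- fitLassoMlr(V2, toy$y, lam)
  o1 <- lassoObjective(cf1, toy$V, toy$y, lam)
  ## evaluate the duplicated fit under the same objective
  o2 <- lassoObjective(cf2, V2, toy$y, lam)
  expect_lt(abs(o1 - o2), 1e-4)
  expect_equal(predictProba(cf2, V2), predictProba(cf1, toy$V),
               tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("predictProba is a stabilised soft-max", {
  cf <- matrix(0, 3, 4, dimnames = list(c("(Intercept)", "a", "b"),
                                        paste0("k", 1:4)))
  V <- cbind(1, matrix(rnorm(10), 5, 2))
  expect_equal(unname(predictProba(cf, V)), matrix(0.25, 5, 4))
  ## soft-max shift invariance
  cf2 <- matrix(rnorm(12), 3, 4); cf3 <- cf2 + 7
  expect_equal(predictProba(cf2, V), predictProba(cf3, V))
  ## direct Eq evaluation on a worked 3x3 instance
  cfW <- matrix(c(0.5, 1, -1, 0, 0.3, 0.2, -0.5, -1.3, 1.1), 3, 3)
  VW <- cbind(1, matrix(c(1, 2, 0, -1, 0.5, 3), 3, 2))
  ref <- t(apply(VW %*% cfW, 1, function(e) exp(e) / sum(exp(e))))
  expect_equal(unname(predictProba(cfW, VW)), ref)
  ## rows sum to one even with extreme linear predictors
  cfE <- matrix(c(0, 500, -500, 0, 0, 0), 3, 2)
  expect_equal(unname(rowSums(predictProba(cfE, V))), rep(1, 5))
})

test_that("cvSelectLambda picks the sparsest of tied minima", {
  toy <- lassoToy(60, n = 60, p = 4)
  g <- lambdaGrid(toy$V, toy$y, nLambda = 30)
  ## single-candidate grid returns it untouched
  expect_equal(cvSelectLambda(toy$V, toy$y, g[5])$lambda, g[5])
  cv <- cvSelectLambda(toy$V, toy$y, g, scheme = list(type = "kfold", k = 5),
                       seed = 4)
  expect_length(cv$cv_error, 30)
  tied <- which(cv$cv_error == min(cv$cv_error))
  expect_equal(cv$lambda, g[tied[1]])            # largest lambda among ties
  expect_true(cv$lambda >= g[max(tied)])
})

test_that("pure-noise designs cross-validate to the baseline error rate", {
  set.seed(61)
  n <- 120
  X <- matrix(rnorm(n * 30), n)
  colnames(X) <- paste0("x", 1:30)
  y <- factor(sample(c("a", "b"), n, TRUE, prob = c(0.65, 0.35)))
  V <- cbind(`(Intercept)` = 1, X)
  cv <- cvSelectLambda(V, y, lambdaGrid(V, y, nLambda = 40),
                       scheme = list(type = "kfold", k = 5), seed = 8)
  expect_lt(abs(min(cv$cv_error) - baselineErrorRate(y)), 0.1)
})
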