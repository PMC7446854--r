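test_that("error rates match hand counts and closed forms", {
  y <- c("a", "a", "b", "b", "a", "b", "a", "a", "b", "a")
  yh <- c("a", "b", "b", "a", "a", "b", "b", "a", "b", "a")
  expect_equal(errorRate(yh, y), 3 / 10)        # hand-counted mismatches
  expect_equal(errorRate(y, y), 0)
  expect_equal(errorRate(rev(sort(y)), sort(y)), 1 - mean(sort(y) == rev(sort(y))))
  expect_error(errorRate(character(0), character(0)), "empty")

  expect_equal(baselineErrorRate(rep(c("x", "y"), c(60, 40))), 0.4)
  expect_equal(baselineErrorRate(rep(c("pd", "ctrl"), c(61, 39))), 0.39)
  expect_equal(baselineErrorRate(rep("x", 5)), 0)

  expect_equal(rer2(0.21, 0.4), 0.475)
  expect_equal(rer2(0.4, 0.4), 0)
  expect_equal(rer2(0, 0.4), 1)
  expect_lt(rer2(0.5, 0.4), 0)
  expect_error(rer2(0.1, 0), "positive")
})

test_that("AUC equals brute-force pair counting", {
  y <- factor(c("n", "n", "n", "p", "p", "p"))
  s <- c(0.1, 0.4, 0.35, 0.8, 0.65, 0.4)       # includes a cross-class tie
  expect_equal(aucScore(s, y, positive = "p"), bruteAuc(s, y, "p"))
  ## perfect and degenerate rankings
  expect_equal(aucScore(c(1, 2, 3, 4, 5, 6), y, "p"), 1)
  expect_equal(aucScore(rep(0.5, 6), y, "p"), 0.5)
  ## random fixtures
  set.seed(77)
  for (i in 1:20) {
    yy <- factor(sample(c("n", "p"), 30, TRUE))
    if (nlevels(droplevels(yy)) < 2) next
    ss <- round(runif(30), 2)
    expect_equal(aucScore(ss, yy, "p"), bruteAuc(ss, yy, "p"))
  }
  ## invariance to strictly monotone transforms; score-negation symmetry
  yy <- factor(rep(c("n", "p"), 15)); ss <- runif(30)
  expect_equal(aucScore(ss, yy, "p"), aucScore(qlogis(ss), yy, "p"))
  expect_equal(aucScore(ss, yy, "p") + aucScore(-ss, yy, "p"), 1)
  expect_error(aucScore(ss, factor(rep("p", 30)), "p"), "both classes")
})

test_that("AUPRC equals threshold enumeration and its null baseline", {
  y <- factor(c("n", "n", "n", "p", "p", "p"))
  s <- c(0.1, 0.4, 0.35, 0.8, 0.65, 0.4)
  expect_equal(auprcScore(s, y, positive = "p"), bruteAuprc(s, y, "p"))
  expect_equal(auprcScore(c(1, 2, 3, 9, 8, 7), y, "p"), 1)
  set.seed(78)
  for (i in 1:20) {
    yy <- factor(sample(c("n", "p"), 25, TRUE, prob = c(0.6, 0.4)))
    if (sum(yy == "p") == 0) next
    ss <- round(runif(25), 2)
    expect_equal(auprcScore(ss, yy, "p"), bruteAuprc(ss, yy, "p"))
  }
  ## uninformative scores average to the prevalence
  set.seed(79)
  vals <- replicate(200, {
    yy <- factor(rep(c("n", "p"), c(210, 90)))
    auprcScore(runif(300), yy, "p")
  })
  expect_lt(abs(mean(vals) - 0.3), 0.03)
  expect_error(auprcScore(runif(5), factor(rep("n", 5)), "p"), "no positive")
})

test_that("metricsReport assembles consistent binary metrics", {
  set.seed(80)
  y <- factor(rep(c("0", "1"), c(40, 60)))
  p1 <- plogis(rnorm(100, ifelse(y == "1", 1.2, -1.2)))
  proba <- cbind(`0` = 1 - p1, `1` = p1)
  mr <- metricsReport(proba, y)
  expect_equal(mr$er, mean((p1 > 0.5) != (y == "1")))
  expect_equal(mr$er0, 0.4)
  expect_equal(mr$rer2, (0.4 - mr$er) / 0.4)
  expect_equal(mr$auc, aucScore(p1, y, "1"))
  expect_equal(mr$recall, mr$sensitivity)
  ## K = 2: the argmax rule equals thresholding at 0.5
  expect_equal(mr$er, errorRate(ifelse(p1 >= 0.5, "1", "0"), y))
})

test_that("argmax ties break toward the majority training class", {
  proba <- matrix(0.5, 2, 2, dimnames = list(NULL, c("a", "b")))
  expect_identical(zimbPredict:::argmaxPredict(proba, trainMajority = "b"),
                   c("b", "b"))
  expect_identical(zimbPredict:::argmaxPredict(proba, trainMajority = "a"),
                   c("a", "a"))
})
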