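## Independent oracles used by the tests. These deliberately avoid the
## package's own computational paths: quadrature instead of Laplace, direct
## enumeration instead of rank formulas, a generic proximal solver instead
## of coordinate descent.

## Gauss-Hermite nodes/weights by Golub-Welsch (eigen of the Jacobi matrix).
gaussHermite <- function(k) {
  J <- matrix(0, k, k)
  off <- sqrt(seq_len(k - 1) / 2)
  J[cbind(seq_len(k - 1), seq_len(k - 1) + 1)] <- off
  J[cbind(seq_len(k - 1) + 1, seq_len(k - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = sqrt(pi) * e$vectors[1, ]^2)
}

## Adaptive Gauss-Hermite marginal log-likelihood of an NB random-intercept
## model, per group: centered at the joint mode, scaled by the curvature.
aghNbMarginal <- function(z, X, offset, groups, beta, theta, sigma2,
                          nNodes = 64) {
  gh <- gaussHermite(nNodes)
  eta0 <- drop(X %*% beta) + offset
  total <- 0
  for (g in levels(factor(groups))) {
    idx <- which(groups == g)
    joint <- function(b)
      sum(stats::dnbinom(z[idx], size = theta,
                         mu = exp(eta0[idx] + b), log = TRUE)) +
        stats::dnorm(b, 0, sqrt(sigma2), log = TRUE)
    opt <- stats::optimize(joint, c(-30, 30), maximum = TRUE)
    bhat <- opt$maximum
    h <- 1e-4
    curv <- -(joint(bhat + h) - 2 * joint(bhat) + joint(bhat - h)) / h^2
    curv <- max(curv, 1e-8)
    s <- 1 / sqrt(curv)
    bs <- bhat + sqrt(2) * s * gh$nodes
    lv <- vapply(bs, joint, 0) + gh$nodes^2 + log(sqrt(2) * s) +
      log(gh$weights)
    mx <- max(lv)
    total <- total + mx + log(sum(exp(lv - mx)))
  }
  total
}

## Eq-style penalised multinomial objective: unscaled negative
## log-likelihood plus lambda * sum of |penalised coefficients|
## (intercept row excluded).
lassoObjective <- function(coef, V, y, lam) {
  eta <- V %*% coef
  eta <- eta - apply(eta, 1, max)
  ll <- sum(eta[cbind(seq_along(y), as.integer(y))]) -
    sum(log(rowSums(exp(eta))))
  -ll + lam * sum(abs(coef[-1, ]))
}

## FISTA proximal-gradient solver for the same objective; V carries the
## intercept in column 1 (unpenalised).
proxLassoMlr <- function(V, y, lam, iters = 4000) {
  y <- droplevels(as.factor(y))
  K <- nlevels(y); p <- ncol(V)
  ind <- outer(as.integer(y), seq_len(K), function(a, b) (a == b) + 0)
  L <- 0.5 * norm(V, "2")^2
  coef <- matrix(0, p, K)
  zc <- coef; t0 <- 1
  obj <- function(cf) lassoObjective(cf, V, y, lam)
  best <- obj(coef)
  for (it in seq_len(iters)) {
    eta <- V %*% zc
    eta <- eta - apply(eta, 1, max)
    P <- exp(eta); P <- P / rowSums(P)
    grad <- crossprod(V, P - ind)
    cand <- zc - grad / L
    cand[-1, ] <- sign(cand[-1, ]) * pmax(abs(cand[-1, ]) - lam / L, 0)
    t1 <- (1 + sqrt(1 + 4 * t0^2)) / 2
    zc <- cand + ((t0 - 1) / t1) * (cand - coef)
    coef <- cand; t0 <- t1
  }
  colnames(coef) <- levels(y)
  coef
}

## brute-force AUC: all positive/negative pairs, ties counted one half
bruteAuc <- function(scores, y, positive) {
  pos <- scores[y == positive]; neg <- scores[y != positive]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

## brute-force AUPRC: enumerate every distinct threshold, step-wise area
bruteAuprc <- function(scores, y, positive) {
  yv <- as.numeric(y == positive)
  th <- sort(unique(scores), decreasing = TRUE)
  prevRec <- 0; area <- 0
  for (t in th) {
    sel <- scores >= t
    prec <- sum(yv[sel]) / sum(sel)
    rec <- sum(yv[sel]) / sum(yv)
    area <- area + (rec - prevRec) * prec
    prevRec <- rec
  }
  area
}
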