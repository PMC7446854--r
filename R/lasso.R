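## L1-penalised multinomial logistic regression: symmetric (all-K)
## parameterisation, a 200-point geometric lambda path anchored at the
## data-driven lambda_max, and cross-validated lambda selection by error
## rate. Coordinate-descent fitting is delegated to glmnet; the penalised
## objective here is the unscaled negative log-likelihood plus
## lambda * sum_k ||beta_k||_1 (intercepts unpenalised), so glmnet's
## per-observation lambda equals ours divided by n.

## Strip the intercept column: glmnet fits its own unpenalised intercepts.
designX <- function(design) {
  v <- if (is.list(design)) design$values else design
  v[, -1, drop = FALSE]
}

#' Lambda grid for the penalised multinomial fit
#'
#' Geometric grid of \code{nLambda} values from \eqn{\lambda_{max}} (the
#' smallest penalty at which every penalised coefficient is exactly zero,
#' computed from the gradient of the unpenalised log-likelihood at the
#' intercept-only model) down to \code{ratio} times it.
#'
#' @param design a \code{designMatrix} (or plain matrix with an intercept
#'   first column).
#' @param y class factor.
#' @param nLambda grid size (default 200).
#' @param ratio smallest/largest lambda (default 1e-4).
#' @return Strictly decreasing positive vector.
#' @export
lambdaGrid <- function(design, y, nLambda = 200, ratio = 1e-4) {
  stopifnot(nLambda >= 2)
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2) stop("response has fewer than 2 classes")
  X <- designX(design)
  f <- as.vector(table(y)) / length(y)
  ind <- outer(y, levels(y), "==") + 0
  resid <- sweep(ind, 2, f)                  # I(y=k) - f_k
  g <- crossprod(X, resid)                   # p x K score components
  lmax <- max(abs(g))
  if (lmax <= 0) lmax <- 1e-3
  exp(seq(log(lmax), log(ratio * lmax), length.out = nLambda))
}

## glmnet requires >= 2 predictor columns; pad with a zero column when a
## degenerate (covariates-only) design gets that small.
padX <- function(X) {
  if (ncol(X) >= 2) return(X)
  cbind(X, `..pad` = numeric(nrow(X)))
}

dropPad <- function(cf) cf[rownames(cf) != "..pad", , drop = FALSE]

lassoGlmnet <- function(X, y, lambdaSeq, ...) {
  n <- nrow(X)
  glmnet::glmnet(padX(X), y, family = "multinomial",
                 lambda = lambdaSeq / n, standardize = FALSE,
                 thresh = 1e-9, maxit = 1e6, ...)
}

## coefficient array ((p+1) x K, intercept first) at one lambda
coefAt <- function(fit, lam, n) {
  cf <- glmnet::coef.glmnet(fit, s = lam / n, exact = FALSE)
  do.call(cbind, lapply(cf, function(m) as.matrix(m)[, 1]))
}

#' Fit the L1-penalised multinomial logistic model at one penalty
#'
#' Minimises the penalised negative log-likelihood
#' \eqn{-\sum_i \log P(y_i|x_i,\beta) + \lambda \sum_k \|\beta_k\|_1}
#' with the soft-max likelihood in the symmetric all-classes
#' parameterisation, intercepts unpenalised; the L1 penalty resolves the
#' soft-max identifiability. A short warm-start path down to \code{lam} is
#' used for stability.
#'
#' @param design \code{designMatrix} or matrix (intercept first column).
#' @param y class factor.
#' @param lam penalty (objective scale: unscaled log-likelihood sum).
#' @return A (p+1) x K coefficient matrix (rows: intercept then predictors;
#'   columns: classes), with attributes \code{lambda} and \code{classes}.
#' @export
fitLassoMlr <- function(design, y, lam) {
  y <- droplevels(as.factor(y))
  X <- designX(design)
  lmax <- max(lambdaGrid(design, y, nLambda = 2)[1], lam * 1.01)
  path <- exp(seq(log(lmax), log(max(lam, 1e-10)), length.out = 20))
  fit <- lassoGlmnet(X, y, path)
  cf <- coefAt(fit, lam, nrow(X))
  rownames(cf) <- c("(Intercept)", colnames(padX(X)))
  cf <- dropPad(cf)
  colnames(cf) <- levels(y)
  attr(cf, "lambda") <- lam
  attr(cf, "classes") <- levels(y)
  cf
}

#' Class probabilities of a multinomial logistic coefficient set
#'
#' Direct soft-max evaluation with log-sum-exp stabilisation; rows sum to 1.
#'
#' @param coefSet (p+1) x K coefficient matrix (intercept row first).
#' @param design \code{designMatrix} or matrix whose first column is the
#'   intercept.
#' @return n x K probability matrix.
#' @export
predictProba <- function(coefSet, design) {
  V <- if (is.list(design)) design$values else design
  eta <- V %*% coefSet
  eta <- eta - apply(eta, 1, max)
  w <- exp(eta)
  p <- w / rowSums(w)
  colnames(p) <- colnames(coefSet)
  p
}

stratifiedFolds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (lev in levels(y)) {
    idx <- sample(which(y == lev))
    fold[idx] <- rep_len(sample(k), length(idx))
  }
  fold
}

#' Select lambda by cross-validated error rate
#'
#' Stratified k-fold (or leave-one-out) assignment; for each fold the path
#' is refitted on the remaining folds and held-out points are predicted by
#' the argmax rule. The lambda with the smallest CV error rate wins; ties
#' break toward the largest lambda (the sparser model). A fold losing a
#' class triggers refolding with a new seed (up to 10 attempts).
#'
#' @param design \code{designMatrix} or matrix (intercept first column).
#' @param y class factor.
#' @param grid decreasing lambda grid (default \code{\link{lambdaGrid}}).
#' @param scheme list(type="kfold", k=10) or list(type="loocv").
#' @param seed RNG seed for fold assignment.
#' @return list(lambda=, cv_error=, grid=).
#' @export
cvSelectLambda <- function(design, y, grid = NULL,
                           scheme = list(type = "kfold", k = 10), seed = 1) {
  y <- droplevels(as.factor(y))
  X <- designX(design)
  n <- nrow(X)
  if (is.null(grid)) grid <- lambdaGrid(design, y)
  if (length(grid) == 1) {
    return(list(lambda = grid, cv_error = NA_real_, grid = grid))
  }
  k <- if (identical(scheme$type, "loocv")) n else scheme$k
  stopifnot(k <= n)
  loo <- k == n
  fold <- NULL
  if (loo) {
    fold <- seq_len(n)
  } else {
    for (att in seq_len(10)) {
      cand <- stratifiedFolds(y, k, seed + 1000 * (att - 1))
      ok <- all(vapply(seq_len(k), function(f)
        nlevels(droplevels(y[cand != f])) == nlevels(y), TRUE))
      if (ok) { fold <- cand; break }
    }
    if (is.null(fold)) stop("could not build folds containing every class")
  }
  miss <- matrix(NA, n, length(grid))
  for (f in sort(unique(fold))) {
    tr <- fold != f
    fit <- lassoGlmnet(X[tr, , drop = FALSE], y[tr], grid)
    pr <- predict(fit, newx = padX(X[!tr, , drop = FALSE]),
                  s = grid / sum(tr), type = "class")
    miss[!tr, ] <- pr != as.character(y[!tr])
  }
  cvER <- colMeans(miss)
  best <- which(cvER == min(cvER))[1]   # grid decreasing: first = largest
  list(lambda = grid[best], cv_error = cvER, grid = grid)
}

## Ridge-stabilised (lambda_2 = ridge) multinomial logistic fit used where an
## unpenalised GLM is called for; the tiny ridge guards against separation.
fitGlmRidge <- function(design, y, ridge = 1e-6) {
  y <- droplevels(as.factor(y))
  X <- designX(design)
  n <- nrow(X)
  path <- c(1, 0.1, 0.01, ridge) / n
  fit <- glmnet::glmnet(padX(X), y, family = "multinomial", alpha = 0,
                        lambda = path, standardize = FALSE,
                        thresh = 1e-7, maxit = 1e6)
  cf <- coefAt(fit, ridge, n)
  rownames(cf) <- c("(Intercept)", colnames(padX(X)))
  cf <- dropPad(cf)
  colnames(cf) <- levels(y)
  attr(cf, "classes") <- levels(y)
  cf
}
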