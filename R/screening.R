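## Per-taxon likelihood-ratio screening and q-value multiple-testing control.

## Fixed-covariate design for the screening models (intercept + fixed
## factors; categorical fixed factors dummy-coded).
screenFixedDesign <- function(covs, extraFixed = NULL) {
  n <- length(sampleIDs(covs))
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  fx <- fixedFactors(covs)
  use <- if (is.null(extraFixed)) names(fx) else extraFixed
  for (nm in use) {
    v <- fx[[nm]]
    if (is.numeric(v)) {
      X <- cbind(X, matrix(v, ncol = 1, dimnames = list(NULL, nm)))
    } else {
      lev <- sort(levels(as.factor(v)))
      if (length(lev) >= 2) {
        d <- vapply(lev[-1], function(l) as.numeric(v == l), numeric(n))
        colnames(d) <- paste0(nm, "=", lev[-1])
        X <- cbind(X, d)
      }
    }
  }
  X
}

phenotypeDummies <- function(y) {
  lev <- levels(y)
  d <- vapply(lev[-1], function(l) as.numeric(y == l), numeric(length(y)))
  if (is.null(dim(d))) d <- matrix(d, nrow = length(y))
  colnames(d) <- paste0("Y=", lev[-1])
  d
}

#' Likelihood-ratio screen of every taxon
#'
#' For each taxon, fits the chosen count model with and without the
#' phenotype and converts the likelihood-ratio statistic to a p-value.
#' Under \code{model = "tpnb"} the taxon's zero proportion selects the
#' regime (\code{\link{tpnbDispatch}}); taxa with >= 90\% zeros are dropped
#' with p = 1, as are taxa whose fits do not converge. Degrees of freedom
#' follow the parameter-count difference: K-1 when the phenotype enters only
#' the mean (NB regime, logistic regime), 2(K-1) when it enters both the
#' mean and the zero component (ZINB, hurdle). Under \code{model = "zinb"}
#' the phenotype is added to both the mean and the zero-probability model of
#' the alternative; the null zero model is intercept-only. q-values are
#' computed by the conservative Benjamini-Hochberg step-up.
#'
#' @param table an \linkS4class{OTUTable}.
#' @param covs matching \linkS4class{SampleCovariates}.
#' @param model "nb", "zinb" or "tpnb".
#' @param includeRandom model the random factors as random intercepts?
#' @param extraFixed optional subset of fixed-factor names to adjust for
#'   (default: all).
#' @param zpDrop zero-proportion drop threshold applied to every model
#'   (default 0.9).
#' @return A \linkS4class{ScreeningResult}.
#' @export
screenOtus <- function(table, covs, model = c("tpnb", "nb", "zinb"),
                       includeRandom = TRUE, extraFixed = NULL,
                       zpDrop = 0.9) {
  model <- match.arg(model)
  cts <- counts(table)
  off <- log(totals(table))
  y <- droplevels(phenotype(covs))
  K <- nlevels(y)
  stopifnot(K >= 2)
  X0 <- screenFixedDesign(covs, extraFixed)
  Yd <- phenotypeDummies(y)
  X1 <- cbind(X0, Yd)
  rnd <- randomFactors(covs)
  groups <- if (includeRandom && ncol(rnd) > 0) rnd[[1]] else NULL

  m <- ncol(cts)
  regime <- character(m); stat <- rep(NA_real_, m); df <- rep(NA_real_, m)
  pv <- rep(1, m); conv <- logical(m); zp <- numeric(m)

  zeroX0 <- matrix(1, nrow(cts), 1)
  zeroX1 <- cbind(zeroX0, Yd)
  hasRE <- !is.null(groups) && nlevels(factor(groups)) > 1
  nY <- ncol(Yd)

  ## warm start for an alternative fit from its null fit (adds the Y columns);
  ## the trailing log-sigma2 slot is present iff the null fit estimated one.
  warmFrom <- function(f0, hasTheta, q0 = 0) {
    if (is.null(f0$beta) || !isTRUE(f0$converged)) return(NULL)
    p <- length(f0$beta)
    re <- f0$npar > p + hasTheta + q0
    c(f0$beta, rep(0, nY),
      if (hasTheta > 0) log(max(f0$theta, 1e-3)),
      if (q0 > 0) c(f0$gamma, rep(0, nY)),
      if (re) log(max(f0$sigma2_b[1], 1e-4)))
  }

  for (j in seq_len(m)) {
    z <- cts[, j]
    zp[j] <- mean(z == 0)
    reg <- if (model == "tpnb") tpnbDispatch(zp[j]) else model
    if (zp[j] >= zpDrop) reg <- "dropped"
    if (length(unique(z)) < 2) reg <- "dropped"
    regime[j] <- reg
    if (reg == "dropped") next
    res <- switch(reg,
      nb = {
        f0 <- fitCountGlmm(z, X0, off, groups, "nb")
        f1 <- fitCountGlmm(z, X1, off, groups, "nb",
                           start = warmFrom(f0, hasTheta = 1))
        lrtPvalue(f0, f1, df = K - 1)
      },
      zinb = {
        f0 <- fitCountGlmm(z, X0, off, groups, "zinb", zeroX = zeroX0)
        f1 <- fitCountGlmm(z, X1, off, groups, "zinb", zeroX = zeroX1,
                           start = warmFrom(f0, hasTheta = 1, q0 = 1))
        lrtPvalue(f0, f1, df = 2 * (K - 1))
      },
      hurdle = {
        f0 <- fitCountGlmm(z, X0, off, groups, "hurdle")
        f1 <- fitCountGlmm(z, X1, off, groups, "hurdle",
                           start = list(
                             presence = warmFrom(f0$presence, hasTheta = 0),
                             count = warmFrom(f0$count, hasTheta = 1)))
        lrtPvalue(f0, f1, df = 2 * (K - 1))
      },
      logistic = {
        zb <- as.numeric(z > 0)
        f0 <- fitCountGlmm(zb, X0, offset = rep(0, length(z)), groups,
                           "bernoulli")
        f1 <- fitCountGlmm(zb, X1, offset = rep(0, length(z)), groups,
                           "bernoulli", start = warmFrom(f0, hasTheta = 0))
        lrtPvalue(f0, f1, df = K - 1)
      })
    stat[j] <- res$statistic; df[j] <- res$df
    pv[j] <- res$p_value; conv[j] <- res$converged
  }
  qv <- computeQvalues(pv, method = "bh")
  tab <- data.frame(taxon_id = colnames(cts), regime = regime,
                    zero_prop = zp, statistic = stat, df = df,
                    p_value = pv, q_value = qv, converged = conv,
                    stringsAsFactors = FALSE)
  new("ScreeningResult", table = tab, model = model,
      includeRandom = isTRUE(includeRandom) && !is.null(groups))
}

#' q-values from p-values
#'
#' The step-up q-value \eqn{q(p_{(j)}) = \min_{t \ge p_{(j)}}
#' \hat{FDR}(t)} with \eqn{\hat{FDR}(t) = m \hat\pi_0 t / \#\{p \le t\}}.
#' Method "bh" is the conservative Benjamini-Hochberg choice
#' (\eqn{\hat\pi_0 = 1}); "storey" estimates \eqn{\hat\pi_0(\zeta) =
#' \#\{p \ge \zeta\} / (m(1-\zeta))}, capped at 1.
#'
#' @param pvalues vector of p-values in [0, 1].
#' @param method "bh" or "storey".
#' @param zeta tuning point of the Storey estimator (default 0.5).
#' @return q-values in input order (monotone in p-value rank).
#' @export
computeQvalues <- function(pvalues, method = c("bh", "storey"), zeta = 0.5) {
  method <- match.arg(method)
  m <- length(pvalues)
  if (m == 0) return(numeric(0))
  stopifnot(all(pvalues >= 0 & pvalues <= 1))
  pi0 <- if (method == "bh") 1 else
    min(1, max(sum(pvalues >= zeta) / (m * (1 - zeta)), 1 / m))
  o <- order(pvalues)
  ranked <- pvalues[o]
  q <- pi0 * m * ranked / seq_len(m)
  q <- rev(cummin(rev(q)))           # min over t >= p_(j)
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

#' Select taxa by q-value threshold
#'
#' @param screening a \linkS4class{ScreeningResult}.
#' @param qCutoff selection threshold in (0, 1) (default 0.05).
#' @return Integer indices (original column order) with q <= cutoff.
#' @export
selectOtus <- function(screening, qCutoff = 0.05) {
  stopifnot(qCutoff > 0, qCutoff < 1)
  which(screenTable(screening)$q_value <= qCutoff)
}
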