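## Count GLMMs for per-taxon screening: NB, ZINB, and two-part (hurdle) NB
## with a single random intercept integrated out by a Laplace approximation
## (inner Newton over the group modes in compiled code, outer quasi-Newton
## over the fixed parameters).

#' Negative binomial log-pmf
#'
#' Log of the NB probability mass in its mean/inverse-dispersion
#' parameterisation, computed through log-gamma for stability:
#' \deqn{f(z;\mu,\theta)=\frac{\Gamma(z+\theta)}{\Gamma(\theta)\Gamma(z+1)}
#'   \left(\frac{\theta}{\theta+\mu}\right)^{\theta}
#'   \left(\frac{\mu}{\theta+\mu}\right)^{z}.}
#' As \eqn{\theta \to \infty} this approaches the Poisson log-pmf.
#'
#' @param z non-negative integer counts (vectorised).
#' @param mu positive mean.
#' @param theta positive inverse dispersion.
#' @return log-probabilities.
#' @export
nbLogPmf <- function(z, mu, theta) {
  stopifnot(all(z >= 0), all(mu > 0), all(theta > 0))
  lgamma(z + theta) - lgamma(theta) - lgamma(z + 1) +
    theta * (log(theta) - log(theta + mu)) +
    ifelse(z > 0, z * (log(mu) - log(theta + mu)), 0)
}

#' Zero-proportion dispatch for the two-part NB screen
#'
#' Maps a taxon's zero proportion to the model regime: plain NB when zeros
#' are rare (<= 10\%), an NB hurdle for the broad middle (up to 80\%),
#' presence/absence logistic regression when only occurrence is informative
#' (up to 90\%), and dropped beyond that (the taxon's p-value is set to 1).
#' Boundaries resolve to the lower-numbered rule.
#'
#' @param zeroProportion fraction of zero counts in [0, 1].
#' @return one of "nb", "hurdle", "logistic", "dropped".
#' @export
tpnbDispatch <- function(zeroProportion) {
  stopifnot(all(zeroProportion >= 0), all(zeroProportion <= 1))
  out <- character(length(zeroProportion))
  out[zeroProportion <= 0.10] <- "nb"
  out[zeroProportion > 0.10 & zeroProportion <= 0.80] <- "hurdle"
  out[zeroProportion > 0.80 & zeroProportion < 0.90] <- "logistic"
  out[zeroProportion >= 0.90] <- "dropped"
  out
}

famCode <- function(family) {
  match(family, c("nb", "bernoulli", "truncated_nb", "zinb")) - 1L
}

## Few IRLS sweeps of a Poisson (log link, offset) or logistic GLM: cheap,
## robust starting values for the fixed effects.
irlsStart <- function(z, X, offset, binary = FALSE, iters = 4L) {
  p <- ncol(X)
  beta <- rep(0, p)
  beta[1] <- if (binary) stats::qlogis(min(max(mean(z > 0.5), 0.02), 0.98))
             else log(mean(pmax(z, 0.1) / exp(offset)))
  for (it in seq_len(iters)) {
    eta <- drop(X %*% beta) + if (binary) 0 else offset
    eta <- pmin(pmax(eta, -30), 30)
    if (binary) {
      mu <- stats::plogis(eta); w <- pmax(mu * (1 - mu), 1e-6)
      zz <- eta + (z - mu) / w
    } else {
      mu <- exp(eta); w <- pmax(mu, 1e-6)
      zz <- eta - offset + (z - mu) / w
    }
    fit <- tryCatch(stats::lm.wfit(X, zz, w = w)$coefficients,
                    error = function(e) NULL)
    if (is.null(fit) || anyNA(fit)) break
    beta <- fit
  }
  beta[!is.finite(beta)] <- 0
  beta
}

## Single-component fit: maximise the (Laplace) marginal likelihood over
## beta, log theta (count families), gamma (zinb zero model) and log sigma2.
fitGlmmComponent <- function(z, X, offset, groups = NULL,
                             family = "nb", zeroX = NULL, start = NULL) {
  fam <- famCode(family)
  n <- length(z)
  X <- as.matrix(X)
  if (is.null(zeroX)) zeroX <- matrix(1, n, if (fam == 3L) 1 else 0)
  hasRE <- !is.null(groups) && nlevels(factor(groups)) > 1
  grp <- if (hasRE) as.integer(factor(groups)) - 1L else integer(0)
  ngroups <- if (hasRE) max(grp) + 1L else 0L
  hasTheta <- fam %in% c(0L, 2L, 3L)
  p <- ncol(X); q <- if (fam == 3L) ncol(zeroX) else 0L

  fn <- function(par) .glmmNll(par, z, X, offset, grp, ngroups, fam, zeroX)
  gr <- function(par) .glmmGrad(par, z, X, offset, grp, ngroups, fam, zeroX)
  if (is.null(start)) {
    beta0 <- irlsStart(z, X, offset, binary = fam == 1L)
    start <- c(beta0,
               if (hasTheta) 0,
               if (q > 0) c(stats::qlogis(min(max(mean(z == 0) / 2, 0.02),
                                              0.9)), rep(0, q - 1)),
               if (hasRE) 0)
    ## dispersion is the touchiest direction: profile a coarse log-theta
    ## grid at the IRLS fixed effects and start from the best point
    if (hasTheta) {
      lts <- c(-3, -1.5, 0, 1.5, 3)
      vals <- vapply(lts, function(lt) {
        s <- start; s[p + 1] <- lt; fn(s)
      }, 0)
      start[p + 1] <- lts[which.min(vals)]
    }
  }
  .glmmWarmReset()
  opt <- stats::optim(start, fn, gr, method = "BFGS",
                      control = list(maxit = 400, reltol = 1e-9))
  ## a fit stuck against the dispersion floor is a symptom of a flat-trap
  ## local optimum; restart once from moderate dispersion
  if (hasTheta && opt$par[p + 1] < -8) {
    s2 <- opt$par; s2[p + 1] <- 0
    .glmmWarmReset()
    opt2 <- stats::optim(s2, fn, gr, method = "BFGS",
                         control = list(maxit = 400, reltol = 1e-9))
    if (opt2$value < opt$value) opt <- opt2
  }
  ## sigma^2 boundary: compare against the fixed-effects-only profile
  if (hasRE) {
    par0 <- opt$par
    idx <- length(par0)
    par0[idx] <- -14
    nll0 <- fn(par0)
    if (nll0 < opt$value) { opt$par <- par0; opt$value <- nll0 }
  }
  par <- opt$par
  pos <- p
  theta <- if (hasTheta) exp(par[pos + 1]) else NA_real_
  if (hasTheta) pos <- pos + 1
  gamma <- if (q > 0) par[pos + seq_len(q)] else numeric(0)
  pos <- pos + q
  sigma2 <- if (hasRE) exp(par[pos + 1]) else 0
  if (hasRE && sigma2 < 1e-6) sigma2 <- 0
  b <- if (hasRE) .glmmModes(par, z, X, offset, grp, ngroups, fam, zeroX)
       else numeric(0)
  structure(list(family = family, beta = stats::setNames(par[seq_len(p)],
                                                         colnames(X)),
                 theta = max(theta, 1e-3), gamma = gamma, sigma2_b = sigma2,
                 b_modes = b, loglik = -opt$value,
                 converged = opt$convergence == 0 && is.finite(opt$value),
                 npar = length(par)),
            class = "glmmFit")
}

#' Fit a count GLMM for one taxon
#'
#' Maximises the marginal likelihood of an NB, ZINB, hurdle (logistic
#' presence + zero-truncated NB) or Bernoulli model with log link and offset
#' \eqn{\log T_i}; random intercepts \eqn{b \sim N(0, \sigma^2_b)} are
#' integrated out by a Laplace approximation. With no grouping factor the
#' fit is an exact (fixed-effects) maximum-likelihood GLM. The dispersion
#' \eqn{\theta} is estimated jointly and bounded below at \eqn{10^{-3}}.
#' Non-convergence is reported through the \code{converged} flag, never an
#' exception. For the hurdle family the two parts are fitted separately and
#' the log-likelihood is their sum.
#'
#' @param z count vector for one taxon.
#' @param X fixed-effect design matrix (first column the intercept).
#' @param offset per-sample offset (log total reads; 0 for bernoulli).
#' @param groups random-factor labels, or NULL for no random intercept.
#' @param family "nb", "zinb", "hurdle" or "bernoulli".
#' @param zeroX design for the ZINB zero-probability model (default
#'   intercept-only).
#' @param start optional start values (component families only).
#' @return A \code{glmmFit} list: beta, theta, gamma, sigma2_b, b_modes,
#'   loglik, converged. Hurdle fits carry the two component fits.
#' @export
fitCountGlmm <- function(z, X, offset = rep(0, length(z)), groups = NULL,
                         family = c("nb", "zinb", "hurdle", "bernoulli"),
                         zeroX = NULL, start = NULL) {
  family <- match.arg(family)
  tryCatch({
    if (family == "hurdle") {
      if (!is.list(start)) start <- list()
      pres <- as.numeric(z > 0)
      fitP <- fitGlmmComponent(pres, X, offset = rep(0, length(z)),
                               groups = groups, family = "bernoulli",
                               start = start$presence)
      pos <- z > 0
      grpPos <- if (!is.null(groups)) droplevels(factor(groups)[pos]) else NULL
      fitC <- fitGlmmComponent(z[pos], X[pos, , drop = FALSE], offset[pos],
                               groups = grpPos, family = "truncated_nb",
                               start = start$count)
      structure(list(family = "hurdle", presence = fitP, count = fitC,
                     beta = fitC$beta, gamma = fitP$beta, theta = fitC$theta,
                     sigma2_b = c(presence = fitP$sigma2_b,
                                  count = fitC$sigma2_b),
                     b_modes = list(presence = fitP$b_modes,
                                    count = fitC$b_modes),
                     loglik = fitP$loglik + fitC$loglik,
                     converged = fitP$converged && fitC$converged,
                     npar = fitP$npar + fitC$npar),
                class = "glmmFit")
    } else {
      fitGlmmComponent(z, X, offset, groups, family, zeroX, start)
    }
  }, error = function(e) {
    structure(list(family = family, beta = NULL, loglik = -Inf,
                   converged = FALSE, npar = NA_integer_),
              class = "glmmFit")
  })
}

#' @export
logLik.glmmFit <- function(object, ...) {
  structure(object$loglik, df = object$npar, class = "logLik")
}

#' @export
print.glmmFit <- function(x, ...) {
  cat("glmmFit [", x$family, "] logLik:", format(x$loglik), "\n")
  if (!is.null(x$beta)) {
    cat("  beta:", paste(signif(x$beta, 4), collapse = " "), "\n")
    if (!is.null(x$theta) && is.finite(x$theta))
      cat("  theta:", signif(x$theta, 4), "\n")
  }
  if (!x$converged) cat("  (not converged)\n")
  invisible(x)
}

#' Likelihood ratio test of nested GLMM fits
#'
#' \eqn{T_n = 2(\log L_1 - \log L_0)} referred to a chi-square with the
#' given degrees of freedom; numerically negative statistics are clipped to
#' zero. If either fit failed to converge the p-value is 1 (conservative).
#'
#' @param fit0 null-model \code{glmmFit}.
#' @param fit1 alternative-model \code{glmmFit} (nested above fit0).
#' @param df positive integer degrees of freedom.
#' @return list(statistic=, df=, p_value=, converged=).
#' @export
lrtPvalue <- function(fit0, fit1, df) {
  stopifnot(df > 0)
  ok <- isTRUE(fit0$converged) && isTRUE(fit1$converged) &&
        is.finite(fit0$loglik) && is.finite(fit1$loglik)
  tn <- max(2 * (fit1$loglik - fit0$loglik), 0)
  p <- if (ok) stats::pchisq(tn, df = df, lower.tail = FALSE) else 1
  list(statistic = if (ok) tn else NA_real_, df = df, p_value = p,
       converged = ok)
}
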