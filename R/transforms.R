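## OTU-count transformations and predictor-matrix assembly.

#' Arcsine-square-root transform of relative abundances
#'
#' The variance-stabilising transform for proportions:
#' \eqn{\tilde Z_{ij} = \arcsin\sqrt{Z_{ij}/T_i}}, in \eqn{[0, \pi/2]}.
#'
#' @param table an \linkS4class{OTUTable}.
#' @return A numeric matrix the same shape as the counts.
#' @export
arcsinSqrtTransform <- function(table) {
  cts <- counts(table)
  ratio <- cts / totals(table)
  if (any(ratio > 1 + 1e-12)) stop("count exceeds total reads")
  asin(sqrt(pmin(ratio, 1)))
}

#' Presence/absence transform
#'
#' \eqn{\tilde Z_{ij} = I(Z_{ij} > 0)}: keeps only occurrence information,
#' discarding abundance (useful when over-dispersion is adversarial).
#'
#' @param table an \linkS4class{OTUTable}.
#' @return A 0/1 matrix the same shape as the counts.
#' @export
binaryTransform <- function(table) {
  (counts(table) > 0) + 0
}

#' Apply a named transform
#' @param table an \linkS4class{OTUTable}.
#' @param transform "asin" or "binary".
#' @return transformed matrix.
#' @export
transformCounts <- function(table, transform = c("asin", "binary")) {
  switch(match.arg(transform),
         asin = arcsinSqrtTransform(table),
         binary = binaryTransform(table))
}

#' Assemble the predictor matrix for the classifiers
#'
#' Columns are: an intercept of ones, the transformed OTU features, the
#' fixed factors (categorical factors dummy-coded with k-1 columns, reference
#' = first level in sorted order) and, optionally, dummy columns for the
#' random-factor groups (which enter the predictive models as ordinary
#' covariates). With \code{standardize = TRUE} all non-intercept columns are
#' centred and scaled by training-set statistics stored in the object, so a
#' test matrix built via \code{\link{applyDesign}} reuses them (no leakage);
#' constant columns are left unscaled and flagged.
#'
#' @param transformed n x m matrix of transformed OTU features.
#' @param covs \linkS4class{SampleCovariates} aligned with the rows.
#' @param includeRandom add random-factor dummies?
#' @param standardize centre/scale non-intercept columns?
#' @return A \code{designMatrix} object (list with values, roles, and the
#'   standardisation statistics).
#' @export
buildDesign <- function(transformed, covs, includeRandom = TRUE,
                        standardize = TRUE) {
  n <- nrow(transformed)
  stopifnot(length(sampleIDs(covs)) == n)
  otu <- as.matrix(transformed)
  if (ncol(otu) > 0 && is.null(colnames(otu)))
    colnames(otu) <- paste0("otu", seq_len(ncol(otu)))
  blocks <- list(otu)
  roles <- list(rep("otu", ncol(otu)))
  levelMap <- list()

  expandFactor <- function(x, nm) {
    lev <- sort(levels(x))
    x <- factor(x, levels = lev)
    if (length(lev) < 2) {
      m <- matrix(numeric(length(x)), ncol = 0)
      return(list(m = m, lev = lev))
    }
    m <- vapply(lev[-1], function(l) as.numeric(x == l), numeric(length(x)))
    if (is.null(dim(m))) m <- matrix(m, nrow = length(x))
    colnames(m) <- paste0(nm, "=", lev[-1])
    list(m = m, lev = lev)
  }

  fx <- fixedFactors(covs)
  for (nm in names(fx)) {
    v <- fx[[nm]]
    if (is.numeric(v)) {
      m <- matrix(v, ncol = 1, dimnames = list(NULL, nm))
      blocks <- c(blocks, list(m)); roles <- c(roles, list("fixed"))
    } else {
      e <- expandFactor(as.factor(v), nm)
      levelMap[[nm]] <- e$lev
      blocks <- c(blocks, list(e$m))
      roles <- c(roles, list(rep("fixed", ncol(e$m))))
    }
  }
  if (includeRandom) {
    rx <- randomFactors(covs)
    for (nm in names(rx)) {
      e <- expandFactor(rx[[nm]], nm)
      levelMap[[nm]] <- e$lev
      blocks <- c(blocks, list(e$m))
      roles <- c(roles, list(rep("random-dummy", ncol(e$m))))
    }
  }
  X <- do.call(cbind, blocks)
  roles <- unlist(roles)
  center <- rep(0, ncol(X)); scale_ <- rep(1, ncol(X))
  flagged <- logical(ncol(X))
  if (standardize && ncol(X) > 0) {
    center <- colMeans(X)
    scale_ <- apply(X, 2, stats::sd)
    flagged <- !is.finite(scale_) | scale_ < 1e-12
    scale_[flagged] <- 1
    center[flagged] <- 0
    X <- sweep(sweep(X, 2, center), 2, scale_, "/")
  }
  values <- cbind(`(Intercept)` = 1, X)
  structure(list(values = values,
                 column_roles = c("intercept", roles),
                 center = center, scale = scale_,
                 constant_flag = flagged,
                 standardize = standardize,
                 includeRandom = includeRandom,
                 levelMap = levelMap),
            class = "designMatrix")
}

#' Build a test-set predictor matrix with training statistics
#'
#' Reconstructs the columns of a training \code{designMatrix} for new data,
#' reusing the training factor levels, centres and scales.
#'
#' @param design a \code{designMatrix} from \code{\link{buildDesign}}.
#' @param transformed transformed OTU matrix for the new samples (same
#'   taxa/columns as in training).
#' @param covs \linkS4class{SampleCovariates} for the new samples.
#' @return The n_new x p numeric matrix, columns aligned with the training
#'   design.
#' @export
applyDesign <- function(design, transformed, covs) {
  otu <- as.matrix(transformed)
  if (ncol(otu) > 0 && is.null(colnames(otu)))
    colnames(otu) <- paste0("otu", seq_len(ncol(otu)))
  blocks <- list(otu)
  expandWith <- function(x, nm, lev) {
    x <- factor(as.character(x), levels = lev)
    if (length(lev) < 2) return(matrix(numeric(length(x)), ncol = 0))
    m <- vapply(lev[-1], function(l) as.numeric(x == l), numeric(length(x)))
    if (is.null(dim(m))) m <- matrix(m, nrow = length(x))
    colnames(m) <- paste0(nm, "=", lev[-1])
    m
  }
  fx <- fixedFactors(covs)
  for (nm in names(fx)) {
    v <- fx[[nm]]
    if (is.numeric(v)) {
      blocks <- c(blocks, list(matrix(v, ncol = 1, dimnames = list(NULL, nm))))
    } else {
      blocks <- c(blocks, list(expandWith(v, nm, design$levelMap[[nm]])))
    }
  }
  if (design$includeRandom) {
    rx <- randomFactors(covs)
    for (nm in names(rx))
      blocks <- c(blocks, list(expandWith(rx[[nm]], nm, design$levelMap[[nm]])))
  }
  X <- do.call(cbind, blocks)
  if (design$standardize && ncol(X) > 0)
    X <- sweep(sweep(X, 2, design$center), 2, design$scale, "/")
  cbind(`(Intercept)` = 1, X)
}
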