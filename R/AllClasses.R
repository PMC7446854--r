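#' @import methods
NULL

#' OTUTable: a samples-by-taxa count matrix with sequencing depths
#'
#' Container for a microbiome count table. Rows are samples, columns are
#' operational taxonomic units (OTUs, or taxa grouped at any rank). Each
#' sample carries its total read count \eqn{T_i}, which serves as the offset
#' of relative-abundance models; after taxa are filtered, the totals are
#' deliberately \emph{not} recomputed, so \eqn{T_i} may exceed the row sum.
#'
#' @slot counts non-negative integer matrix, samples x taxa, with unique
#'   dimnames.
#' @slot totals positive integer vector of per-sample total reads, at least
#'   the row sums of \code{counts}.
#' @export
setClass("OTUTable",
  slots = c(counts = "matrix", totals = "numeric"))

setValidity("OTUTable", function(object) {
  cts <- object@counts
  msg <- character()
  if (is.null(rownames(cts)) || is.null(colnames(cts)))
    msg <- c(msg, "counts must have sample (row) and taxon (column) names")
  else {
    if (anyDuplicated(rownames(cts))) msg <- c(msg, "duplicate sample ids")
    if (anyDuplicated(colnames(cts))) msg <- c(msg, "duplicate taxon ids")
  }
  if (any(cts < 0) || any(cts != round(cts)))
    msg <- c(msg, "counts must be non-negative integers")
  if (length(object@totals) != nrow(cts))
    msg <- c(msg, "totals length must equal number of samples")
  else if (any(object@totals < rowSums(cts) - 1e-8))
    msg <- c(msg, "totals must be >= per-sample count sums")
  if (length(msg)) msg else TRUE
})

#' SampleCovariates: phenotype, fixed factors and random-factor labels
#'
#' Per-sample covariates aligned (by position) with an \linkS4class{OTUTable}.
#' The phenotype is a factor with K >= 2 levels; fixed factors may be
#' continuous or categorical; random factors are categorical group labels
#' (e.g. collection site) modelled as random intercepts during screening and
#' as dummy covariates in the predictive models.
#'
#' @slot phenotype factor of length n with K >= 2 levels.
#' @slot fixed data.frame of fixed factors (may have zero columns).
#' @slot random data.frame of factor columns giving group identities.
#' @slot sampleIDs character vector aligned with the OTUTable rows.
#' @export
setClass("SampleCovariates",
  slots = c(phenotype = "factor", fixed = "data.frame",
            random = "data.frame", sampleIDs = "character"))

setValidity("SampleCovariates", function(object) {
  n <- length(object@sampleIDs)
  msg <- character()
  if (length(object@phenotype) != n)
    msg <- c(msg, "phenotype length must equal number of samples")
  ## note: a degenerate single-level phenotype is representable (it can
  ## arise in intermediate simulated objects); the modelling functions
  ## require K >= 2 at their entry points.
  if (nrow(object@fixed) != n || nrow(object@random) != n)
    msg <- c(msg, "covariate tables must have one row per sample")
  if (ncol(object@random) > 0 && !all(vapply(object@random, is.factor, TRUE)))
    msg <- c(msg, "random-factor columns must be factors")
  if (anyDuplicated(object@sampleIDs)) msg <- c(msg, "duplicate sample ids")
  if (length(msg)) msg else TRUE
})

#' ScreeningResult: per-taxon likelihood-ratio screen
#'
#' One row per taxon: the dispatch regime, LRT statistic, its chi-square
#' degrees of freedom, p-value and q-value. Taxa whose fits did not converge,
#' or that were dropped by the zero-proportion rule, carry p = 1.
#'
#' @slot table data.frame with columns taxon_id, regime, zero_prop,
#'   statistic, df, p_value, q_value, converged.
#' @slot model character: the count model used ("nb", "zinb" or "tpnb").
#' @slot includeRandom logical: were random intercepts in the screen.
#' @export
setClass("ScreeningResult",
  slots = c(table = "data.frame", model = "character",
            includeRandom = "logical"))

setValidity("ScreeningResult", function(object) {
  need <- c("taxon_id", "regime", "zero_prop", "statistic", "df",
            "p_value", "q_value", "converged")
  if (!all(need %in% names(object@table)))
    return("screening table is missing required columns")
  p <- object@table$p_value
  if (any(p < 0 | p > 1, na.rm = TRUE)) return("p-values outside [0,1]")
  TRUE
})

## ---- constructors ----

#' Construct an OTUTable
#'
#' @param counts samples x taxa matrix of non-negative integers with
#'   dimnames, or coercible to one.
#' @param totals per-sample total reads; defaults to the row sums.
#' @return An \linkS4class{OTUTable}.
#' @export
OTUTable <- function(counts, totals = rowSums(counts)) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  new("OTUTable", counts = counts, totals = as.numeric(totals))
}

#' Construct a SampleCovariates object
#'
#' @param phenotype factor (or vector coerced to factor) of phenotype labels.
#' @param fixed data.frame of fixed factors (default: none).
#' @param random data.frame of random-factor labels (default: none);
#'   character columns are coerced to factors.
#' @param sampleIDs sample identifiers aligned with the OTUTable rows.
#' @return A \linkS4class{SampleCovariates}.
#' @export
SampleCovariates <- function(phenotype, fixed = NULL, random = NULL,
                             sampleIDs) {
  n <- length(sampleIDs)
  if (is.null(fixed)) fixed <- data.frame(row.names = seq_len(n))
  if (is.null(random)) random <- data.frame(row.names = seq_len(n))
  random[] <- lapply(random, function(x) if (is.factor(x)) x else factor(x))
  new("SampleCovariates", phenotype = as.factor(phenotype),
      fixed = as.data.frame(fixed), random = as.data.frame(random),
      sampleIDs = as.character(sampleIDs))
}

## ---- accessors ----

#' @describeIn OTUTable-accessors the count matrix
#' @export
setGeneric("counts", function(object) standardGeneric("counts"))

#' Accessors for OTUTable and SampleCovariates
#'
#' @param object an \linkS4class{OTUTable} or
#'   \linkS4class{SampleCovariates}.
#' @name OTUTable-accessors
#' @aliases counts totals sampleIDs taxonIDs phenotype fixedFactors
#'   randomFactors
NULL

#' @rdname OTUTable-accessors
#' @export
setMethod("counts", "OTUTable", function(object) object@counts)

#' @rdname OTUTable-accessors
#' @export
setGeneric("totals", function(object) standardGeneric("totals"))
setMethod("totals", "OTUTable", function(object) object@totals)

#' @rdname OTUTable-accessors
#' @export
setGeneric("sampleIDs", function(object) standardGeneric("sampleIDs"))
setMethod("sampleIDs", "OTUTable", function(object) rownames(object@counts))
setMethod("sampleIDs", "SampleCovariates", function(object) object@sampleIDs)

#' @rdname OTUTable-accessors
#' @export
setGeneric("taxonIDs", function(object) standardGeneric("taxonIDs"))
setMethod("taxonIDs", "OTUTable", function(object) colnames(object@counts))

#' @rdname OTUTable-accessors
#' @export
setGeneric("phenotype", function(object) standardGeneric("phenotype"))
setMethod("phenotype", "SampleCovariates", function(object) object@phenotype)

#' @rdname OTUTable-accessors
#' @export
setGeneric("fixedFactors", function(object) standardGeneric("fixedFactors"))
setMethod("fixedFactors", "SampleCovariates", function(object) object@fixed)

#' @rdname OTUTable-accessors
#' @export
setGeneric("randomFactors", function(object) standardGeneric("randomFactors"))
setMethod("randomFactors", "SampleCovariates", function(object) object@random)

#' Subset samples of an OTUTable / SampleCovariates pair
#'
#' @param object the object to subset.
#' @param i sample indices (logical or integer).
#' @return An object of the same class restricted to the chosen samples.
#' @export
setGeneric("subsetSamples", function(object, i) standardGeneric("subsetSamples"))
setMethod("subsetSamples", "OTUTable", function(object, i) {
  new("OTUTable", counts = object@counts[i, , drop = FALSE],
      totals = object@totals[i])
})
setMethod("subsetSamples", "SampleCovariates", function(object, i) {
  rnd <- object@random[i, , drop = FALSE]
  rnd[] <- lapply(rnd, droplevels)
  new("SampleCovariates", phenotype = droplevels(object@phenotype[i]),
      fixed = object@fixed[i, , drop = FALSE], random = rnd,
      sampleIDs = object@sampleIDs[i])
})

#' Results table of a screen
#'
#' @param object a \linkS4class{ScreeningResult}.
#' @return The per-taxon data.frame.
#' @export
setGeneric("screenTable", function(object) standardGeneric("screenTable"))
setMethod("screenTable", "ScreeningResult", function(object) object@table)

## ---- show methods ----

setMethod("show", "OTUTable", function(object) {
  cat("OTUTable:", nrow(object@counts), "samples x",
      ncol(object@counts), "taxa\n")
  cat("  total reads: ", paste(range(object@totals), collapse = "-"),
      "; overall zero fraction: ",
      signif(mean(object@counts == 0), 3), "\n", sep = "")
})

setMethod("show", "SampleCovariates", function(object) {
  cat("SampleCovariates:", length(object@sampleIDs), "samples;",
      "phenotype levels:", paste(levels(object@phenotype), collapse = "/"),
      "\n")
  cat("  fixed factors:", paste(names(object@fixed), collapse = ", "),
      "| random factors:", paste(names(object@random), collapse = ", "), "\n")
})

setMethod("show", "ScreeningResult", function(object) {
  tab <- object@table
  cat("ScreeningResult (", object@model,
      if (object@includeRandom) ", random intercepts" else "", "): ",
      nrow(tab), " taxa\n", sep = "")
  cat("  regimes:", paste(names(table(tab$regime)),
      table(tab$regime), collapse = "; "), "\n")
  cat("  q <= 0.05:", sum(tab$q_value <= 0.05), "taxa\n")
})
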