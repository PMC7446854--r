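## TSV readers/writers and quality-control filters for count tables.

#' Read an OTU count table from TSV
#'
#' Expects a UTF-8 tab-separated file with samples as rows: a header line of
#' taxon ids, a first column named \code{sample_id}, and integer cells. An
#' optional \code{total_reads} column supplies sequencing depths; otherwise
#' totals are the row sums.
#'
#' @param path path to the TSV file.
#' @return An \linkS4class{OTUTable}.
#' @export
readCounts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = NA, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("no samples in ", path)
  if (names(df)[1] != "sample_id") stop("first column must be 'sample_id'")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) stop("duplicate sample ids in ", path)
  tot <- NULL
  if ("total_reads" %in% names(df)) {
    tot <- as.numeric(df[["total_reads"]])
    df[["total_reads"]] <- NULL
  }
  cnt <- df[, -1, drop = FALSE]
  if (ncol(cnt) == 0L) stop("no taxa in ", path)
  if (anyDuplicated(names(cnt))) stop("duplicate taxon ids in ", path)
  for (j in seq_along(cnt)) {
    v <- cnt[[j]]
    if (!is.numeric(v) || any(is.na(v)) || any(v < 0) || any(v != round(v))) {
      bad <- which(!is.finite(suppressWarnings(as.numeric(v))) |
                   suppressWarnings(as.numeric(v)) < 0 |
                   suppressWarnings(as.numeric(v)) != round(suppressWarnings(as.numeric(v))))
      stop(sprintf("non-integer or negative count at row %d, column '%s'",
                   if (length(bad)) bad[1] else NA_integer_, names(cnt)[j]))
    }
  }
  m <- as.matrix(cnt)
  rownames(m) <- ids
  if (is.null(tot)) tot <- rowSums(m)
  OTUTable(m, tot)
}

#' Write an OTU count table to TSV
#'
#' Inverse of \code{\link{readCounts}}: round-trips bit-exactly. The
#' \code{total_reads} column is emitted only when totals differ from row sums.
#'
#' @param table an \linkS4class{OTUTable}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeCounts <- function(table, path) {
  cts <- counts(table)
  df <- data.frame(sample_id = rownames(cts), check.names = FALSE)
  if (any(totals(table) != rowSums(cts)))
    df$total_reads <- format(totals(table), scientific = FALSE, trim = TRUE)
  df <- cbind(df, as.data.frame(cts, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata from TSV
#'
#' Strict inner join on \code{sample_id} against an \linkS4class{OTUTable}:
#' every table sample must appear in the metadata (unmatched samples are an
#' error, not a silent drop). Factor typing is declared, not inferred.
#'
#' @param path metadata TSV with a \code{sample_id} column.
#' @param table the \linkS4class{OTUTable} the metadata describes.
#' @param phenotypeCol name of the phenotype column.
#' @param fixedCols names of fixed-factor columns (continuous columns stay
#'   numeric; others are coerced to factor).
#' @param randomCols names of random-factor columns (coerced to factor).
#' @return A \linkS4class{SampleCovariates} row-aligned with \code{table}.
#' @export
readMetadata <- function(path, table, phenotypeCol,
                         fixedCols = character(), randomCols = character()) {
  md <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(md)) stop("metadata must have 'sample_id'")
  ids <- sampleIDs(table)
  idx <- match(ids, as.character(md$sample_id))
  if (anyNA(idx))
    stop("samples missing from metadata: ",
         paste(utils::head(ids[is.na(idx)], 5), collapse = ", "))
  md <- md[idx, , drop = FALSE]
  fixed <- md[, fixedCols, drop = FALSE]
  fixed[] <- lapply(fixed, function(x) if (is.numeric(x)) x else factor(x))
  random <- md[, randomCols, drop = FALSE]
  SampleCovariates(phenotype = factor(md[[phenotypeCol]]),
                   fixed = fixed, random = random, sampleIDs = ids)
}

#' Remove samples with low sequencing depth
#'
#' Quality-control step retaining exactly the samples whose total reads are
#' at least \code{minReads}; covariates are subset in lockstep. The canonical
#' filter order is depth first, then taxon prevalence
#' (\code{\link{filterPrevalence}}).
#'
#' @param table an \linkS4class{OTUTable}.
#' @param covs matching \linkS4class{SampleCovariates}, or NULL.
#' @param minReads minimum total reads (default 10000, a common 16S cutoff).
#' @return list(table=, covs=) with surviving samples.
#' @export
filterMinReads <- function(table, covs = NULL, minReads = 10000) {
  stopifnot(minReads >= 1)
  keep <- totals(table) >= minReads
  if (!any(keep)) stop("empty dataset after filtering")
  list(table = subsetSamples(table, keep),
       covs = if (!is.null(covs)) subsetSamples(covs, keep) else NULL)
}

#' Remove rare taxa by prevalence
#'
#' Retains exactly the taxa present (count > 0) in at least
#' \code{minPrevalence} of samples (>= comparison at the boundary). Totals
#' are total sequencing reads and are left untouched: the relative-abundance
#' offset refers to the full depth, not the post-filter sum.
#'
#' @param table an \linkS4class{OTUTable}.
#' @param minPrevalence required fraction of samples in (0, 1].
#' @return The filtered \linkS4class{OTUTable}.
#' @export
filterPrevalence <- function(table, minPrevalence = 0.2) {
  stopifnot(minPrevalence > 0, minPrevalence <= 1)
  cts <- counts(table)
  prev <- colMeans(cts > 0)
  keep <- prev >= minPrevalence
  if (!any(keep)) stop("empty dataset after filtering")
  new("OTUTable", counts = cts[, keep, drop = FALSE], totals = totals(table))
}
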