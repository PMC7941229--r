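# ExpressionCohort container and scale conversions.
#
# A cohort is a gene x sample numeric matrix with unique identifiers and an
# explicit scale flag ("linear" for FPKM-like non-negative values, "log2" for
# log2(x+1)-transformed values). Scale conversion is always an explicit
# operation: single-sample enrichment is rank-based and scale-invariant, but
# differential-expression fold-changes are not.

#' Construct an expression cohort
#'
#' @param values Numeric gene x sample matrix with rownames (genes) and
#'   colnames (samples).
#' @param scale `"linear"` (non-negative, FPKM-like) or `"log2"`.
#' @param metadata Optional data.frame of per-sample annotations with a
#'   `sample` column matching `colnames(values)`.
#' @return An object of class `expression_cohort`.
#' @export
expression_cohort <- function(values, scale = c("linear", "log2"),
                              metadata = NULL) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    tme_format_error("values must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    tme_format_error("values must carry gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    tme_format_error(sprintf(
      "duplicate gene identifier(s): %s",
      paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", ")))
  if (anyDuplicated(colnames(values)))
    tme_format_error(sprintf(
      "duplicate sample identifier(s): %s",
      paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", ")))
  if (anyNA(values) || any(!is.finite(values)))
    tme_format_error("values must be finite and non-missing")
  if (scale == "linear" && any(values < 0))
    tme_format_error("linear-scale cohort has negative entries")
  if (!is.null(metadata)) {
    if (!is.data.frame(metadata) || is.null(metadata$sample))
      tme_format_error("metadata must be a data.frame with a 'sample' column")
    if (!all(colnames(values) %in% metadata$sample))
      tme_format_error("metadata is missing samples present in the matrix")
  }
  structure(list(values = values, scale = scale, metadata = metadata),
            class = "expression_cohort")
}

#' @export
print.expression_cohort <- function(x, ...) {
  cat(sprintf("expression_cohort: %d genes x %d samples (%s scale)\n",
              nrow(x$values), ncol(x$values), x$scale))
  invisible(x)
}

#' @export
dim.expression_cohort <- function(x) dim(x$values)

#' Gene identifiers of a cohort
#' @param cohort An `expression_cohort`.
#' @return Character vector of gene identifiers.
#' @export
genes <- function(cohort) rownames(cohort$values)

#' Sample identifiers of a cohort
#' @param cohort An `expression_cohort`.
#' @return Character vector of sample identifiers.
#' @export
samples <- function(cohort) colnames(cohort$values)

#' Convert a linear-scale cohort to log2(x + 1)
#' @param cohort An `expression_cohort` on linear scale.
#' @return The cohort on log2 scale.
#' @export
to_log2 <- function(cohort) {
  if (cohort$scale == "log2") return(cohort)
  expression_cohort(log2(cohort$values + 1), scale = "log2",
                    metadata = cohort$metadata)
}

#' Convert a log2(x + 1) cohort back to linear scale
#' @param cohort An `expression_cohort` on log2 scale.
#' @return The cohort on linear scale.
#' @export
to_linear <- function(cohort) {
  if (cohort$scale == "linear") return(cohort)
  vals <- pmax(2^cohort$values - 1, 0)
  expression_cohort(vals, scale = "linear", metadata = cohort$metadata)
}

#' Subset a cohort by genes and/or samples
#' @param cohort An `expression_cohort`.
#' @param genes,samples Optional identifier vectors to keep (order respected).
#' @return The subset cohort.
#' @export
subset_cohort <- function(cohort, genes = NULL, samples = NULL) {
  v <- cohort$values
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(v))
    if (length(missing))
      tme_format_error(sprintf("genes absent from cohort: %s",
                               paste(utils::head(missing, 5), collapse = ", ")))
    v <- v[genes, , drop = FALSE]
  }
  if (!is.null(samples)) {
    missing <- setdiff(samples, colnames(v))
    if (length(missing))
      tme_format_error(sprintf("samples absent from cohort: %s",
                               paste(utils::head(missing, 5), collapse = ", ")))
    v <- v[, samples, drop = FALSE]
  }
  md <- cohort$metadata
  if (!is.null(md) && !is.null(samples))
    md <- md[match(samples, md$sample), , drop = FALSE]
  expression_cohort(v, scale = cohort$scale, metadata = md)
}

#' Remove genes expressed in too few samples
#'
#' Low-expression noise filter: keeps genes with a positive value in at least
#' `min_frac` of samples (default: expressed in >= 10\% of samples).
#'
#' @param cohort A linear-scale `expression_cohort`.
#' @param min_frac Minimum fraction of samples with expression > 0.
#' @return The filtered cohort.
#' @export
filter_low_expression <- function(cohort, min_frac = 0.1) {
  frac_pos <- rowMeans(cohort$values > 0)
  keep <- frac_pos >= min_frac
  expression_cohort(cohort$values[keep, , drop = FALSE], scale = cohort$scale,
                    metadata = cohort$metadata)
}
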