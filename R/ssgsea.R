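# Single-sample gene-set enrichment (ssGSEA) and the scores built on it:
# immune/stromal enrichment (IES/SES), pathway scores, marker-mean cell-type
# abundance, the M1/M2 macrophage ratio and cytolytic activity.
#
# ssGSEA walks each sample's expression-ranked gene list and accumulates the
# difference between the weighted in-set and unweighted out-of-set empirical
# distributions; the enrichment score is the sum of that running difference.
# Being rank-based, scores are invariant to any strictly monotone transform
# of a sample's expression.

#' Single-sample gene-set enrichment scores
#'
#' Per sample, genes are ranked descending by expression (average ranks on
#' ties). For a set, `P_in(i)` is the cumulative sum of `rank^alpha` over
#' in-set genes (normalized by its total) along the ordered list, `P_out(i)`
#' the cumulative count of out-of-set genes (normalized by its total), and
#' `ES = sum(P_in - P_out)`. With `normalize = TRUE` the whole score matrix
#' is divided by its range (max - min).
#'
#' @param cohort An [expression_cohort()] (any monotone scale).
#' @param gene_sets Named list of gene identifier vectors (e.g. from
#'   [read_gmt()]).
#' @param alpha Rank-weight exponent (default 0.25).
#' @param normalize Divide scores by the global score range.
#' @return Sample x signature matrix of enrichment scores. Sets overlapping
#'   the cohort in fewer than 2 genes are skipped with a warning.
#' @export
ssgsea <- function(cohort, gene_sets, alpha = 0.25, normalize = TRUE) {
  X <- cohort$values
  gene_ids <- rownames(X)
  n_genes <- nrow(X)
  keep <- vapply(gene_sets, function(s) sum(s %in% gene_ids) >= 2, logical(1))
  if (any(!keep))
    warning("skipping gene set(s) with < 2 overlapping genes: ",
            paste(names(gene_sets)[!keep], collapse = ", "))
  gene_sets <- gene_sets[keep]
  if (!length(gene_sets)) tme_config_error("no scorable gene sets")
  in_set <- lapply(gene_sets, function(s) gene_ids %in% s)

  scores <- matrix(NA_real_, ncol(X), length(gene_sets),
                   dimnames = list(colnames(X), names(gene_sets)))
  for (j in seq_len(ncol(X))) {
    x <- X[, j]
    r <- rank(x, ties.method = "average")      # top gene has rank n_genes
    ord <- order(x, decreasing = TRUE)
    w <- r[ord]^alpha
    for (s in seq_along(in_set)) {
      ins <- in_set[[s]][ord]
      p_in <- cumsum(w * ins) / sum(w[ins])
      p_out <- cumsum(!ins) / sum(!ins)
      scores[j, s] <- sum(p_in - p_out)
    }
  }
  if (normalize) {
    rng <- max(scores) - min(scores)
    if (rng > 0) scores <- scores / rng
  }
  scores
}

#' Immune and stromal enrichment scores (IES / SES)
#'
#' ssGSEA scores of an immune and a stromal gene signature; used to label
#' NMF factors as immune vs non-immune and to split CAFs from activated
#' factors.
#'
#' @param cohort An [expression_cohort()].
#' @param immune_set,stromal_set Gene identifier vectors.
#' @param alpha ssGSEA exponent.
#' @return List with named per-sample vectors `ies` and `ses`.
#' @export
estimate_ies_ses <- function(cohort, immune_set, stromal_set, alpha = 0.25) {
  sc <- ssgsea(cohort, list(IES = immune_set, SES = stromal_set),
               alpha = alpha, normalize = TRUE)
  list(ies = sc[, "IES"], ses = sc[, "SES"])
}

#' Marker-mean cell-type abundance scores
#'
#' Abundance of a cell population is the arithmetic mean of log2(x + 1)
#' expression over its marker genes present in the cohort (a marker-mean
#' approximation in the MCPcounter spirit, without ported coefficient
#' tables).
#'
#' @param cohort An [expression_cohort()].
#' @param marker_sets Named list of marker gene vectors per population.
#' @return Sample x population score matrix; populations with no overlapping
#'   markers are skipped with a warning.
#' @export
score_cell_types <- function(cohort, marker_sets) {
  lg <- to_log2(cohort)$values
  keep <- vapply(marker_sets, function(s) any(s %in% rownames(lg)), logical(1))
  if (any(!keep))
    warning("skipping population(s) with no overlapping markers: ",
            paste(names(marker_sets)[!keep], collapse = ", "))
  marker_sets <- marker_sets[keep]
  if (!length(marker_sets)) tme_config_error("no scorable marker sets")
  out <- vapply(marker_sets, function(s) {
    colMeans(lg[intersect(s, rownames(lg)), , drop = FALSE])
  }, numeric(ncol(lg)))
  rownames(out) <- colnames(lg)
  out
}

#' M1/M2 macrophage polarization ratio
#'
#' @param cell_scores Sample x population matrix containing `M1` and `M2`
#'   columns (e.g. from [score_cell_types()]).
#' @param eps Stabilizing offset (default 1e-6).
#' @return Named per-sample ratio `(M1 + eps) / (M2 + eps)`.
#' @export
m1_m2_ratio <- function(cell_scores, eps = 1e-6) {
  if (!all(c("M1", "M2") %in% colnames(cell_scores)))
    tme_config_error("cell_scores must contain M1 and M2 columns")
  (cell_scores[, "M1"] + eps) / (cell_scores[, "M2"] + eps)
}

#' Cytolytic activity score (CYT)
#'
#' Geometric mean of linear-scale expression (plus 0.01) of the two
#' cytolytic effector genes, by convention GZMA and PRF1.
#'
#' @param cohort An [expression_cohort()].
#' @param genes Character pair of effector genes.
#' @return Named per-sample CYT vector.
#' @export
cytolytic_activity <- function(cohort, genes = c("GZMA", "PRF1")) {
  lin <- to_linear(cohort)$values
  missing <- setdiff(genes, rownames(lin))
  if (length(missing))
    tme_error(sprintf("cytolytic effector gene(s) absent: %s",
                      paste(missing, collapse = ", ")), "tme_format_error")
  sqrt((lin[genes[1], ] + 0.01) * (lin[genes[2], ] + 0.01))
}
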