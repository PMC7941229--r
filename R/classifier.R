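# Differential expression, derivation of the subtype marker-gene classifier,
# nearest-template prediction (NTP) into new cohorts, and cross-cohort
# subclass mapping.

#' Two-group differential expression by rank-sum test
#'
#' Two-sided Mann-Whitney test per gene on log2-scale expression with
#' Benjamini-Hochberg correction over all tested genes. A gene is
#' significant iff `q < q_threshold` and `|log2FC| > fc_threshold`.
#'
#' @param cohort A log2-scale [expression_cohort()].
#' @param group_a,group_b Disjoint sample identifier vectors (>= 3 each).
#' @param fc_threshold,q_threshold Significance thresholds (defaults 1,
#'   0.05).
#' @return Data.frame per gene: `gene`, `mean_a`, `mean_b`, `log2fc`
#'   (a minus b), `p`, `q`, `direction` ("up" = higher in a), `significant`.
#' @export
differential_expression <- function(cohort, group_a, group_b,
                                    fc_threshold = 1, q_threshold = 0.05) {
  if (cohort$scale != "log2")
    tme_config_error("differential expression expects a log2-scale cohort; use to_log2()")
  if (length(intersect(group_a, group_b)))
    tme_error("groups overlap", "tme_label_error")
  if (length(group_a) < 3 || length(group_b) < 3)
    tme_config_error("each group needs >= 3 samples")
  A <- cohort$values[, group_a, drop = FALSE]
  B <- cohort$values[, group_b, drop = FALSE]
  p <- vapply(seq_len(nrow(A)), function(i) {
    if (all(A[i, ] == A[i, 1]) && all(B[i, ] == A[i, 1])) return(1)
    stats::wilcox.test(A[i, ], B[i, ], exact = FALSE)$p.value
  }, numeric(1))
  mean_a <- rowMeans(A); mean_b <- rowMeans(B)
  lfc <- mean_a - mean_b
  q <- stats::p.adjust(p, method = "BH")
  data.frame(gene = rownames(A), mean_a = mean_a, mean_b = mean_b,
             log2fc = lfc, p = p, q = q,
             direction = ifelse(lfc >= 0, "up", "down"),
             significant = q < q_threshold & abs(lfc) > fc_threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Derive subtype-specific marker templates by pairwise comparison
#'
#' A gene is a marker of subtype s iff it is significantly over-expressed in
#' s versus each of the other two subtypes separately (both pairwise
#' comparisons pass), which makes the marker lists pairwise disjoint by
#' construction. Lists are ordered by descending minimum pairwise
#' fold-change.
#'
#' @param cohort A linear- or log2-scale [expression_cohort()] (converted to
#'   log2 internally).
#' @param labels Named character vector of subtype per sample (values among
#'   activated/CAFs/inactivated), or a `subtype_labels` object.
#' @param fc_threshold,q_threshold Passed to [differential_expression()].
#' @return A `classifier_template`: named list of ordered marker-gene
#'   vectors per subtype.
#' @export
derive_templates <- function(cohort, labels, fc_threshold = 0.4,
                             q_threshold = 0.05) {
  labels <- as_subtype_vector(labels)
  lg <- to_log2(cohort)
  subtypes <- unique(labels)
  if (length(subtypes) < 3)
    tme_config_error("all three subtypes must be present to derive templates")
  templates <- lapply(subtypes, function(s) {
    others <- setdiff(subtypes, s)
    per_pair <- lapply(others, function(o) {
      de <- differential_expression(lg, names(labels)[labels == s],
                                    names(labels)[labels == o],
                                    fc_threshold, q_threshold)
      de[de$significant & de$direction == "up", c("gene", "log2fc")]
    })
    shared <- Reduce(intersect, lapply(per_pair, `[[`, "gene"))
    if (!length(shared)) return(character(0))
    min_fc <- do.call(pmin, lapply(per_pair, function(d)
      d$log2fc[match(shared, d$gene)]))
    shared[order(min_fc, decreasing = TRUE)]
  })
  names(templates) <- subtypes
  empty <- names(templates)[lengths(templates) == 0]
  if (length(empty))
    tme_error(sprintf(
      "no markers found for subtype(s) %s; consider relaxing fc/q thresholds",
      paste(empty, collapse = ", ")), "tme_config_error")
  structure(templates, class = "classifier_template")
}

as_subtype_vector <- function(labels) {
  if (inherits(labels, "subtype_labels"))
    return(stats::setNames(labels$labels$subtype, labels$labels$sample))
  if (is.null(names(labels)))
    tme_config_error("labels must be named by sample")
  labels
}

cosine_distance <- function(v, tmpl) {
  denom <- sqrt(sum(v^2)) * sqrt(sum(tmpl^2))
  if (denom == 0) return(1)
  1 - sum(v * tmpl) / denom
}

#' Nearest-template prediction of subtype membership
#'
#' Expression is standardized per gene (z-score across samples). Each
#' subtype's template is the 0/1 indicator of its marker genes over the
#' union of all template genes present in the cohort; a sample is predicted
#' as the subtype with the smallest cosine distance. Significance comes from
#' `n_resample` random size-matched gene-set draws: p is the fraction of
#' random templates at least as close as the observed one (add-one
#' corrected), BH-adjusted over samples.
#'
#' @param cohort An [expression_cohort()].
#' @param templates A `classifier_template` (or named list of marker
#'   vectors).
#' @param n_resample Number of random draws (default 1000).
#' @param seed Integer seed.
#' @return Data.frame per sample: `sample`, `prediction`, one
#'   `dist_<subtype>` column per template, `p`, `fdr`.
#' @export
ntp_classify <- function(cohort, templates, n_resample = 1000L, seed = 1L) {
  X <- to_log2(cohort)$values
  gene_ids <- rownames(X)
  present <- lapply(templates, intersect, x = gene_ids)
  few <- names(present)[lengths(present) < 5]
  if (length(few))
    tme_error(sprintf(
      "fewer than 5 template genes present for subtype(s): %s (overlaps: %s)",
      paste(few, collapse = ", "),
      paste(lengths(present)[few], collapse = ", ")), "tme_config_error")
  # per-gene z-score; constant genes carry no signal and z = 0
  sds <- apply(X, 1, stats::sd)
  Z <- (X - rowMeans(X)) / ifelse(sds == 0, 1, sds)
  Z[sds == 0, ] <- 0

  union_genes <- unique(unlist(present))
  sizes <- lengths(present)
  n_sub <- length(present)
  Zu <- Z[union_genes, , drop = FALSE]
  denom_u <- sqrt(colSums(Zu^2))
  dist_to <- function(zmat, marker_rows, denom) {
    num <- colSums(zmat[marker_rows, , drop = FALSE])
    d <- 1 - num / (denom * sqrt(length(marker_rows)))
    d[denom == 0] <- 1
    d
  }
  obs <- vapply(names(present), function(s)
    dist_to(Zu, match(present[[s]], union_genes), denom_u),
    numeric(ncol(Z)))
  if (is.null(dim(obs))) obs <- matrix(obs, nrow = 1,
                                       dimnames = list(NULL, names(present)))
  pred_idx <- apply(obs, 1, which.min)
  prediction <- names(present)[pred_idx]
  obs_dist <- obs[cbind(seq_len(nrow(obs)), pred_idx)]

  set.seed(derive_seed(seed, "ntp"))
  hits <- numeric(ncol(Z))
  n_union <- length(union_genes)
  for (r in seq_len(n_resample)) {
    rand_union <- sample(gene_ids, n_union)
    Zr <- Z[rand_union, , drop = FALSE]
    denom_r <- sqrt(colSums(Zr^2))
    offset <- 0L
    rand_d <- matrix(NA_real_, ncol(Z), n_sub)
    for (s in seq_len(n_sub)) {
      rows <- offset + seq_len(sizes[s])
      rand_d[, s] <- dist_to(Zr, rows, denom_r)
      offset <- offset + sizes[s]
    }
    hits <- hits + (rand_d[cbind(seq_len(ncol(Z)), pred_idx)] <= obs_dist)
  }
  p <- (1 + hits) / (1 + n_resample)
  out <- data.frame(sample = colnames(Z), prediction = prediction,
                    stringsAsFactors = FALSE)
  for (s in names(present)) out[[paste0("dist_", s)]] <- obs[, s]
  out$p <- p
  out$fdr <- stats::p.adjust(p, method = "BH")
  out
}

#' Subclass mapping between two labelled cohorts
#'
#' Association between subtype s in cohort A and subtype t in cohort B is
#' the Spearman correlation between the subtype centroids (mean per-gene
#' z-scored expression) across the shared gene space. The null permutes
#' sample labels within each cohort; `p = (1 + #null >= observed) /
#' (1 + n_perm)`, Bonferroni-corrected over the subtype-pair grid.
#'
#' @param cohort_a,cohort_b [expression_cohort()]s.
#' @param labels_a,labels_b Named subtype vectors (or `subtype_labels`).
#' @param n_perm Number of label permutations (default 1000).
#' @param seed Integer seed.
#' @return List: `statistic`, `p`, `p_bonferroni` (subtype x subtype
#'   matrices) and `significant` (Bonferroni p < 0.05). Subtypes absent from
#'   a cohort appear as NA rows/columns.
#' @export
subclass_map <- function(cohort_a, labels_a, cohort_b, labels_b,
                         n_perm = 1000L, seed = 1L) {
  labels_a <- as_subtype_vector(labels_a)
  labels_b <- as_subtype_vector(labels_b)
  shared <- intersect(rownames(cohort_a$values), rownames(cohort_b$values))
  if (length(shared) < 100)
    tme_config_error("subclass mapping needs >= 100 shared genes")
  za <- zscore_genes(to_log2(cohort_a)$values[shared, names(labels_a)])
  zb <- zscore_genes(to_log2(cohort_b)$values[shared, names(labels_b)])
  subtypes <- sort(unique(c(labels_a, labels_b)))

  centroids <- function(z, lab) {
    vapply(subtypes, function(s) {
      if (!sum(lab == s)) return(rep(NA_real_, nrow(z)))
      rowMeans(z[, lab == s, drop = FALSE])
    }, numeric(nrow(z)))
  }
  rank_cols <- function(m) apply(m, 2, function(col)
    if (anyNA(col)) col else rank(col))
  obs <- stats::cor(rank_cols(centroids(za, labels_a)),
                    rank_cols(centroids(zb, labels_b)))

  set.seed(derive_seed(seed, "subclass_map"))
  exceed <- matrix(0, length(subtypes), length(subtypes),
                   dimnames = dimnames(obs))
  for (r in seq_len(n_perm)) {
    pa <- sample(labels_a); pb <- sample(labels_b)
    null_cor <- stats::cor(rank_cols(centroids(za, pa)),
                           rank_cols(centroids(zb, pb)))
    exceed <- exceed + (null_cor >= obs)
  }
  p <- (1 + exceed) / (1 + n_perm)
  p[is.na(obs)] <- NA
  n_tests <- sum(!is.na(obs))
  p_bonf <- pmin(p * n_tests, 1)
  list(statistic = obs, p = p, p_bonferroni = p_bonf,
       significant = !is.na(p_bonf) & p_bonf < 0.05)
}

zscore_genes <- function(X) {
  sds <- apply(X, 1, stats::sd)
  Z <- (X - rowMeans(X)) / ifelse(sds == 0, 1, sds)
  Z[sds == 0, ] <- 0
  Z
}
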