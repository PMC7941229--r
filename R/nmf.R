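# Consensus non-negative matrix factorization ("virtual microdissection"),
# BIC rank selection, and the factor -> class -> subtype assignment.
#
# NMF minimizes ||X - WH||_F^2 by multiplicative updates (Lee-Seung), which
# keep all entries non-negative and never increase the objective. Consensus
# over random restarts measures assignment stability; the factorization rank
# is chosen by a Gaussian-residual BIC. Factors are grouped into immune vs
# non-immune classes by their members' immune enrichment scores and the
# immune class is split into activated vs CAFs subtypes by stromal
# enrichment.

#' Standardize genes for NMF input
#'
#' Scales each gene row of a linear-scale cohort to unit maximum, taming the
#' FPKM dynamic range while keeping non-negativity. Genes with all-zero rows
#' are removed.
#'
#' @param cohort A linear-scale [expression_cohort()].
#' @return A non-negative matrix ready for [nmf_factorize()].
#' @export
prepare_nmf_input <- function(cohort) {
  if (cohort$scale != "linear")
    tme_config_error("NMF input must be a linear-scale cohort")
  X <- cohort$values
  mx <- apply(X, 1, max)
  X <- X[mx > 0, , drop = FALSE] / mx[mx > 0]
  X
}

#' Non-negative matrix factorization by multiplicative updates
#'
#' Minimizes the squared Frobenius reconstruction error. The objective is
#' monotone non-increasing; iteration stops when the relative objective
#' change drops below `tol` or `max_iter` is reached. W columns are scaled
#' to unit L2 norm with the compensation absorbed into H.
#'
#' @param X Non-negative gene x sample matrix without all-zero rows.
#' @param k Factorization rank, `2 <= k < min(dim(X))` (k = 1 allowed for
#'   degenerate checks).
#' @param seed Integer seed for the random initialization.
#' @param max_iter Maximum number of update sweeps.
#' @param tol Relative objective-change stopping threshold.
#' @return A `factor_model` list: `W` (genes x k), `H` (k x samples), `k`,
#'   `rss` (squared Frobenius error), `iterations`, `seed`.
#' @export
nmf_factorize <- function(X, k, seed = 1L, max_iter = 200L, tol = 1e-5) {
  if (any(X < 0)) tme_error("X must be non-negative", "tme_domain_error")
  if (any(rowSums(X) == 0))
    tme_error("X has all-zero rows; filter them before factorizing",
              "tme_domain_error")
  if (k < 1 || k >= min(dim(X)) + 1)
    tme_config_error("k must satisfy 1 <= k <= min(dim(X))")
  set.seed(seed)
  n <- nrow(X); m <- ncol(X)
  scale0 <- sqrt(mean(X) / k)
  W <- matrix(stats::runif(n * k, 0.1, 1) * scale0, n, k)
  H <- matrix(stats::runif(k * m, 0.1, 1) * scale0, k, m)
  eps <- .Machine$double.eps
  obj_prev <- Inf
  obj_trace <- numeric(0)
  it <- 0L
  for (it in seq_len(max_iter)) {
    H <- H * (crossprod(W, X) / (crossprod(W) %*% H + eps))
    W <- W * (X %*% t(H)) / (W %*% tcrossprod(H) + eps)
    obj <- sum((X - W %*% H)^2)
    obj_trace <- c(obj_trace, obj)
    if (is.finite(obj_prev) && (obj_prev - obj) < tol * obj_prev) break
    obj_prev <- obj
  }
  # unit-L2 columns of W, compensation into H
  nrm <- sqrt(colSums(W^2))
  nrm[nrm == 0] <- 1
  W <- sweep(W, 2, nrm, "/")
  H <- sweep(H, 1, nrm, "*")
  rss <- sum((X - W %*% H)^2)
  rownames(W) <- rownames(X); colnames(H) <- colnames(X)
  colnames(W) <- rownames(H) <- paste0("F", seq_len(k))
  structure(list(W = W, H = H, k = k, rss = rss, iterations = it,
                 obj_trace = obj_trace, seed = seed), class = "factor_model")
}

#' Consensus NMF over random restarts
#'
#' Runs [nmf_factorize()] from `n_restarts` random initializations; each
#' restart assigns every sample to its arg-max factor, and the consensus
#' matrix entry C\[i, j\] is the fraction of restarts in which samples i and
#' j co-assign. The cophenetic correlation between 1 - C and the cophenetic
#' distances of its average-linkage dendrogram summarizes stability.
#'
#' @param X Non-negative matrix.
#' @param k Rank.
#' @param n_restarts Number of restarts (>= 2).
#' @param seed Integer seed (fans out per restart).
#' @param max_iter,tol Passed to [nmf_factorize()].
#' @return A `consensus_result` list: `consensus` (sample x sample),
#'   `cophenetic`, `best_model` (lowest-RSS restart), `assignments`
#'   (restart x sample factor indices), `rss` per restart, `k`.
#' @export
consensus_nmf <- function(X, k, n_restarts = 10L, seed = 1L,
                          max_iter = 200L, tol = 1e-5) {
  if (n_restarts < 2) tme_config_error("n_restarts must be >= 2")
  m <- ncol(X)
  assigns <- matrix(NA_integer_, n_restarts, m)
  models <- vector("list", n_restarts)
  for (r in seq_len(n_restarts)) {
    models[[r]] <- nmf_factorize(X, k, seed = derive_seed(seed,
                                                          paste0("restart", r)),
                                 max_iter = max_iter, tol = tol)
    assigns[r, ] <- assign_factor(models[[r]]$H)
  }
  C <- matrix(0, m, m)
  for (r in seq_len(n_restarts)) {
    a <- assigns[r, ]
    C <- C + outer(a, a, "==")
  }
  C <- C / n_restarts
  dimnames(C) <- list(colnames(X), colnames(X))
  d <- stats::as.dist(1 - C)
  coph <- if (stats::sd(d) == 0) 1 else {
    hc <- stats::hclust(d, method = "average")
    suppressWarnings(stats::cor(d, stats::cophenetic(hc)))
  }
  if (is.na(coph)) coph <- 1
  best <- which.min(vapply(models, `[[`, numeric(1), "rss"))
  structure(list(consensus = C, cophenetic = coph,
                 best_model = models[[best]], assignments = assigns,
                 rss = vapply(models, `[[`, numeric(1), "rss"), k = k),
            class = "consensus_result")
}

#' Select the factorization rank by BIC
#'
#' For each rank k, the best-restart squared reconstruction error RSS_k
#' feeds a Gaussian-residual BIC:
#' `BIC(k) = N*M*ln(RSS_k / (N*M)) + k*(N+M)*ln(N*M)` with N genes and M
#' samples. The arg-min rank is returned; ties (including reconstructions
#' below relative error 1e-9, treated as exact) break toward smaller k.
#'
#' @param X Non-negative matrix.
#' @param k_min,k_max Rank search range.
#' @param n_restarts Restarts per rank.
#' @param seed Integer seed.
#' @param max_iter,tol Passed to [nmf_factorize()].
#' @return List: `k` (chosen rank), `scores` (data.frame of k, rss, bic).
#' @export
select_rank <- function(X, k_min = 2L, k_max = 8L, n_restarts = 5L, seed = 1L,
                        max_iter = 200L, tol = 1e-5) {
  if (k_min < 1 || k_min > k_max) tme_config_error("need 1 <= k_min <= k_max")
  if (k_max >= min(dim(X)))
    tme_config_error("k_max must be smaller than both matrix dimensions")
  NM <- prod(dim(X))
  total <- sum(X^2)
  ks <- k_min:k_max
  rss <- vapply(ks, function(k) {
    best <- Inf
    for (r in seq_len(n_restarts)) {
      fm <- nmf_factorize(X, k, seed = derive_seed(seed,
                                                   paste0("k", k, "r", r)),
                          max_iter = max_iter, tol = tol)
      best <- min(best, fm$rss)
    }
    best
  }, numeric(1))
  rss_floored <- pmax(rss, 1e-9 * total)
  bic <- NM * log(rss_floored / NM) + ks * (sum(dim(X))) * log(NM)
  chosen <- ks[which.min(bic)]  # which.min takes the first (smallest k) tie
  list(k = chosen, scores = data.frame(k = ks, rss = rss, bic = bic))
}

#' Assign each sample to its arg-max factor
#'
#' @param H k x sample non-negative mixture matrix.
#' @return Integer vector of factor indices (named by sample when H has
#'   colnames). Ties break toward the lowest factor index (logged via
#'   message); an all-zero column is an error naming the sample.
#' @export
assign_factor <- function(H) {
  zero <- colSums(H) == 0
  if (any(zero))
    tme_error(sprintf("sample(s) with all-zero factor loadings: %s",
                      paste(colnames(H)[zero], collapse = ", ")),
              "tme_unassigned_error")
  idx <- apply(H, 2, function(col) {
    w <- which(col == max(col))
    if (length(w) > 1) message("factor-assignment tie broken to lowest index")
    w[1]
  })
  stats::setNames(as.integer(idx), colnames(H))
}

#' Classify factors into immune/non-immune classes and the three subtypes
#'
#' A factor is labelled immune iff a one-sided rank-sum test of its members'
#' IES against all other samples gives p < alpha AND the member median IES
#' exceeds the cohort median. Among immune factors, the same rule applied to
#' SES marks CAFs factors; remaining immune factors are activated, and
#' non-immune factors are inactivated. Factors with fewer than
#' `min_members` samples are unclassifiable; their members take the subtype
#' of the nearest classified factor centroid in (IES, SES) space.
#'
#' @param factor_assignment Named integer vector from [assign_factor()].
#' @param ies,ses Named per-sample immune / stromal enrichment scores.
#' @param alpha Rank-sum significance threshold (default 0.001).
#' @param min_members Minimum members for a classifiable factor.
#' @return A `subtype_labels` list: `labels` (data.frame sample, factor,
#'   class, subtype) and `factor_table` (per-factor summary).
#' @export
classify_factors <- function(factor_assignment, ies, ses, alpha = 0.001,
                             min_members = 3L) {
  samples <- names(factor_assignment)
  if (is.null(samples) || !all(samples %in% names(ies)) ||
      !all(samples %in% names(ses)))
    tme_config_error("IES/SES must be named and cover every assigned sample")
  ies <- ies[samples]; ses <- ses[samples]
  facs <- sort(unique(factor_assignment))

  factor_table <- do.call(rbind, lapply(facs, function(f) {
    member <- factor_assignment == f
    n_mem <- sum(member)
    if (n_mem < min_members)
      return(data.frame(factor = f, n = n_mem, immune = NA, caf = NA,
                        p_ies = NA_real_, p_ses = NA_real_,
                        median_ies = stats::median(ies[member]),
                        median_ses = stats::median(ses[member])))
    p_ies <- stats::wilcox.test(ies[member], ies[!member],
                                alternative = "greater", exact = FALSE)$p.value
    p_ses <- stats::wilcox.test(ses[member], ses[!member],
                                alternative = "greater", exact = FALSE)$p.value
    immune <- p_ies < alpha &&
      stats::median(ies[member]) > stats::median(ies)
    caf <- immune && p_ses < alpha &&
      stats::median(ses[member]) > stats::median(ses)
    data.frame(factor = f, n = n_mem, immune = immune, caf = caf,
               p_ies = p_ies, p_ses = p_ses,
               median_ies = stats::median(ies[member]),
               median_ses = stats::median(ses[member]))
  }))

  subtype_of_factor <- ifelse(!factor_table$immune, "inactivated",
                              ifelse(factor_table$caf, "CAFs", "activated"))
  names(subtype_of_factor) <- factor_table$factor

  unclassifiable <- factor_table$factor[is.na(factor_table$immune)]
  if (length(unclassifiable)) {
    message(sprintf("factor(s) %s have < %d members; members reassigned to nearest classified factor centroid",
                    paste(unclassifiable, collapse = ", "), min_members))
    ok <- factor_table[!is.na(factor_table$immune), , drop = FALSE]
    if (!nrow(ok))
      tme_config_error("no classifiable factors (all below min_members)")
    for (f in unclassifiable) {
      row <- factor_table[factor_table$factor == f, ]
      d <- (ok$median_ies - row$median_ies)^2 + (ok$median_ses - row$median_ses)^2
      subtype_of_factor[as.character(f)] <-
        subtype_of_factor[as.character(ok$factor[which.min(d)])]
    }
  }

  subtype <- subtype_of_factor[as.character(factor_assignment)]
  labels <- data.frame(
    sample = samples,
    factor = unname(factor_assignment),
    class = ifelse(subtype == "inactivated", "non-immune", "immune"),
    subtype = unname(subtype),
    stringsAsFactors = FALSE)
  structure(list(labels = labels, factor_table = factor_table),
            class = "subtype_labels")
}
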