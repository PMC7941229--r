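# Ridge-regression imputation of drug log-IC50 from expression against a
# reference cell-line panel, and subtype-wise response comparison.
#
# The panel's genes are z-scored across cell lines; ridge coefficients are
# (G'G + lambda I)^-1 G'y (computed in the dual so the cost scales with the
# number of cell lines), with lambda chosen by leave-one-out cross
# validation over a log-spaced grid when not fixed. Cohort expression is
# first rank-mapped onto the panel's per-gene empirical distribution (the
# cross-platform homogenization step), then standardized with the panel's
# gene means/sds and pushed through the linear model.

#' Fit a ridge model of log IC50 on panel expression
#'
#' @param panel_expr Gene x cell-line expression matrix (linear or log
#'   scale; used as given).
#' @param ic50 Named per-cell-line log IC50 vector.
#' @param lambda Fixed ridge penalty; if NULL, chosen by leave-one-out CV
#'   over `lambda_grid`.
#' @param lambda_grid Candidate penalties (default 13 log-spaced points in
#'   10^-2..10^4).
#' @param min_lines Minimum number of cell lines (default 20).
#' @return A `ridge_model`: `coef` (named per gene), `intercept`, `lambda`,
#'   `center`/`scale` (per-gene standardization), `panel_sorted` (per-gene
#'   sorted panel values for quantile mapping), `cv` (lambda, LOO MSE).
#' @export
fit_ridge_panel <- function(panel_expr, ic50, lambda = NULL,
                            lambda_grid = 10^seq(-2, 4, length.out = 13),
                            min_lines = 20L) {
  lines_shared <- intersect(colnames(panel_expr), names(ic50))
  if (length(lines_shared) < min_lines)
    tme_config_error(sprintf("need >= %d cell lines with IC50; have %d",
                             min_lines, length(lines_shared)))
  G0 <- panel_expr[, lines_shared, drop = FALSE]
  y <- ic50[lines_shared]
  ctr <- rowMeans(G0)
  scl <- apply(G0, 1, stats::sd)
  keep <- scl > 0
  G <- t((G0[keep, , drop = FALSE] - ctr[keep]) / scl[keep])  # lines x genes
  yc <- y - mean(y)
  K <- tcrossprod(G)
  eig <- eigen(K, symmetric = TRUE)
  lam_ev <- pmax(eig$values, 0)

  loo_mse <- function(lam) {
    shrink <- lam_ev / (lam_ev + lam)
    H <- eig$vectors %*% (shrink * t(eig$vectors))
    resid <- yc - H %*% yc
    h <- pmin(diag(H), 1 - 1e-12)
    mean((resid / (1 - h))^2)
  }
  cv <- NULL
  if (is.null(lambda)) {
    mses <- vapply(lambda_grid, loo_mse, numeric(1))
    cv <- data.frame(lambda = lambda_grid, loo_mse = mses)
    lambda <- lambda_grid[which.min(mses)]
  }
  alpha <- eig$vectors %*% ((t(eig$vectors) %*% yc) / (lam_ev + lambda))
  beta <- drop(crossprod(G, alpha))
  names(beta) <- rownames(G0)[keep]
  structure(list(coef = beta, intercept = mean(y), lambda = lambda,
                 center = ctr[keep], scale = scl[keep],
                 panel_sorted = apply(G0[keep, , drop = FALSE], 1, sort),
                 n_lines = length(lines_shared), cv = cv),
            class = "ridge_model")
}

#' Impute log IC50 for a cohort from a fitted panel model
#'
#' Each cohort gene is rank-mapped onto the panel's empirical distribution
#' for that gene, standardized with the panel's statistics, and projected
#' through the ridge coefficients.
#'
#' @param model A `ridge_model` from [fit_ridge_panel()].
#' @param cohort An [expression_cohort()] (same scale as the panel matrix
#'   the model was fitted on).
#' @return Named per-sample predicted log IC50. Model genes absent from the
#'   cohort are dropped with a warning when < 10% are missing, otherwise an
#'   error.
#' @export
impute_ic50 <- function(model, cohort) {
  genes_model <- names(model$coef)
  missing <- setdiff(genes_model, rownames(cohort$values))
  if (length(missing) / length(genes_model) >= 0.1)
    tme_config_error(sprintf(">= 10%% of model genes missing from cohort (%d/%d)",
                             length(missing), length(genes_model)))
  if (length(missing))
    warning(length(missing), " model gene(s) absent from cohort; dropped")
  genes_use <- setdiff(genes_model, missing)
  X <- cohort$values[genes_use, , drop = FALSE]
  n_pan <- nrow(model$panel_sorted)
  # rank-map each gene to the panel's empirical quantiles
  Xq <- t(vapply(genes_use, function(g) {
    r <- rank(X[g, ], ties.method = "average")
    model$panel_sorted[pmin(pmax(ceiling(r / ncol(X) * n_pan), 1), n_pan), g]
  }, numeric(ncol(X))))
  dimnames(Xq) <- list(genes_use, colnames(X))
  Z <- (Xq - model$center[genes_use]) / model$scale[genes_use]
  drop(crossprod(Z, model$coef[genes_use])) + model$intercept
}

#' Compare imputed drug response across subtypes
#'
#' Per drug, a Kruskal-Wallis test across subtypes plus pairwise
#' Mann-Whitney tests; Kruskal-Wallis p-values are BH-adjusted over drugs.
#'
#' @param imputed Sample x drug matrix of predicted log IC50.
#' @param labels Named subtype per sample (or `subtype_labels`).
#' @return List: `kw` (data.frame drug, H, p, q) and `pairwise` (data.frame
#'   drug, group_a, group_b, p).
#' @export
compare_response <- function(imputed, labels) {
  labels <- as_subtype_vector(labels)
  common <- intersect(rownames(imputed), names(labels))
  if (!length(common)) tme_config_error("labels do not cover imputed samples")
  imputed <- imputed[common, , drop = FALSE]
  lab <- labels[common]
  kw <- do.call(rbind, lapply(colnames(imputed), function(d) {
    res <- withCallingHandlers(
      kruskal_wallis(imputed[, d], lab),
      warning = function(w) invokeRestart("muffleWarning"))
    data.frame(drug = d, H = res$H, p = res$p, stringsAsFactors = FALSE)
  }))
  kw$q <- stats::p.adjust(kw$p, method = "BH")
  pairs <- utils::combn(sort(unique(lab)), 2)
  pw <- do.call(rbind, lapply(colnames(imputed), function(d) {
    do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
      a <- pairs[1, i]; b <- pairs[2, i]
      res <- withCallingHandlers(
        mann_whitney(imputed[lab == a, d], imputed[lab == b, d]),
        warning = function(w) invokeRestart("muffleWarning"))
      data.frame(drug = d, group_a = a, group_b = b, p = res$p,
                 stringsAsFactors = FALSE)
    }))
  }))
  list(kw = kw, pairwise = pw)
}

#' Generate a synthetic cell-line panel with planted drug sensitivity
#'
#' Cell lines share the cohort's latent programs with broadly varying
#' immune/stromal loadings; log IC50 increases with the line's stromal
#' loading and decreases with its immune loading, so on matched cohorts the
#' planted subtype response ordering is activated < inactivated < CAFs
#' (CAFs most resistant).
#'
#' @param truth Ground truth from [generate_expression()].
#' @param config The matching [cohort_config()].
#' @param n_lines Number of cell lines.
#' @param drugs Drug names (one model per drug).
#' @return List: `panel_expr` (gene x line), `ic50` (line x drug),
#'   `planted_order` (most sensitive to most resistant).
#' @export
generate_drug_panel <- function(truth, config, n_lines = 60L,
                                drugs = c("cisplatin", "paclitaxel",
                                          "etoposide", "vinorelbine",
                                          "gemcitabine")) {
  set.seed(derive_seed(config$seed, "drug_panel"))
  W <- truth$W_true
  k <- ncol(W)
  programs <- colnames(W)
  line_ids <- sprintf("CL%03d", seq_len(n_lines))
  H <- matrix(0.1, k, n_lines, dimnames = list(programs, line_ids))
  tumour_progs <- grep("^tumour", programs, value = TRUE)
  imm_share <- stats::runif(n_lines, 0.05, 0.42)
  str_share <- stats::runif(n_lines, 0.06, 0.45)
  shrink <- pmin(1, 0.85 / (imm_share + str_share))
  imm_share <- imm_share * shrink
  str_share <- str_share * shrink
  tum_share <- 1 - imm_share - str_share
  dom <- match(sample(tumour_progs, n_lines, replace = TRUE), programs)
  if (length(tumour_progs) > 1) {
    H[seq_along(tumour_progs), ] <- matrix(
      rep(tum_share * 0.15 / (length(tumour_progs) - 1),
          each = length(tumour_progs)), length(tumour_progs), n_lines)
    H[cbind(dom, seq_len(n_lines))] <- tum_share * 0.85
  } else H[1, ] <- tum_share
  H["immune", ] <- imm_share
  H["stroma", ] <- str_share
  expr <- (W %*% H) * exp(matrix(stats::rnorm(nrow(W) * n_lines, sd = 0.2),
                                 nrow(W), n_lines))
  ic50 <- vapply(seq_along(drugs), function(d) {
    w_str <- stats::runif(1, 5.5, 7.5)
    w_imm <- stats::runif(1, 3.0, 4.5)
    w_str * str_share - w_imm * imm_share + stats::rnorm(n_lines, sd = 0.15)
  }, numeric(n_lines))
  dimnames(ic50) <- list(line_ids, drugs)
  list(panel_expr = expr, ic50 = ic50,
       planted_order = c("activated", "inactivated", "CAFs"))
}
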