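# Outcome and association statistics used throughout the pipeline:
# Kaplan-Meier / log-rank, univariate Cox, exact r x c Fisher,
# Mann-Whitney, Kruskal-Wallis, Benjamini-Hochberg. These wrap the survival
# package and base stats (Breslow ties for Cox; two-sided Fisher p by
# probability ordering; normal approximation with tie correction for U)
# behind one validated interface.

#' Kaplan-Meier curves and log-rank test across groups
#'
#' Product-limit estimate per group and the k-1 degree-of-freedom log-rank
#' statistic; pairwise group tests are BH-adjusted. Groups with zero events
#' are excluded from pairwise testing with a warning.
#'
#' @param time Positive event/censoring times.
#' @param event Event indicator (1 = event, 0 = censored).
#' @param group Group label per sample (>= 2 groups with >= 1 event each).
#' @param pairwise Also compute pairwise log-rank tests.
#' @return List: `chisq`, `df`, `p`, `curves` (a `survfit` object),
#'   `pairwise` (data.frame with BH-adjusted q) when requested.
#' @export
km_logrank <- function(time, event, group, pairwise = TRUE) {
  if (any(!is.finite(time)) || any(time <= 0))
    tme_config_error("times must be positive and finite")
  if (sum(event) == 0)
    tme_error("no events observed; log-rank test undefined",
              "tme_config_error")
  group <- as.character(group)
  if (length(unique(group)) < 2)
    tme_config_error("need >= 2 groups")
  ev_by_group <- tapply(event, group, sum)
  if (any(ev_by_group == 0))
    warning("group(s) with zero events excluded from pairwise tests: ",
            paste(names(ev_by_group)[ev_by_group == 0], collapse = ", "))
  surv <- survival::Surv(time, event)
  sd0 <- survival::survdiff(surv ~ group)
  df <- length(unique(group)) - 1
  p <- stats::pchisq(sd0$chisq, df, lower.tail = FALSE)
  out <- list(chisq = unname(sd0$chisq), df = df, p = p,
              curves = survival::survfit(surv ~ group))
  if (pairwise) {
    grp_ok <- names(ev_by_group)[ev_by_group > 0]
    pairs <- utils::combn(sort(grp_ok), 2)
    pw <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
      sel <- group %in% pairs[, i]
      sdi <- survival::survdiff(survival::Surv(time[sel], event[sel]) ~
                                  group[sel])
      data.frame(group_a = pairs[1, i], group_b = pairs[2, i],
                 chisq = unname(sdi$chisq),
                 p = stats::pchisq(sdi$chisq, 1, lower.tail = FALSE),
                 stringsAsFactors = FALSE)
    }))
    pw$q <- stats::p.adjust(pw$p, method = "BH")
    out$pairwise <- pw
  }
  out
}

#' Univariate Cox proportional-hazards regression
#'
#' Partial-likelihood fit with Breslow tie handling; the hazard ratio is
#' `exp(coef)` with a Wald 95% confidence interval from the observed
#' information.
#'
#' @param covariate Numeric per-sample covariate (must vary).
#' @param time,event Survival outcome (>= 10 events).
#' @return List: `coef` (log hazard ratio), `hr`, `ci` (length-2), `se`,
#'   `p` (Wald), `n_events`.
#' @export
cox_univariate <- function(covariate, time, event) {
  if (stats::sd(covariate) == 0)
    tme_config_error("covariate is constant")
  if (sum(event) < 10)
    tme_config_error("need >= 10 events for a stable Cox fit")
  fit <- survival::coxph(survival::Surv(time, event) ~ covariate,
                         ties = "breslow")
  if (!is.null(fit$info) && !fit$info$converged)
    tme_error("Cox partial-likelihood maximization did not converge",
              "tme_convergence_error")
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(stats::vcov(fit)[1, 1]))
  list(coef = beta, hr = exp(beta),
       ci = exp(beta + c(-1, 1) * stats::qnorm(0.975) * se),
       se = se, p = 2 * stats::pnorm(-abs(beta / se)),
       n_events = sum(event))
}

#' Exact (or Monte Carlo) Fisher test for an r x c table
#'
#' Two-sided p by probability ordering: the sum of probabilities of all
#' margin-fixed tables no more probable than the observed one. All-zero rows
#' and columns are dropped first. `method = "auto"` uses full enumeration
#' for small tables and margin-preserving Monte Carlo (with add-one
#' correction) for large ones.
#'
#' @param table_counts r x c matrix of non-negative integer counts.
#' @param method `"auto"`, `"exact"` or `"mc"`.
#' @param n_mc Monte Carlo replicates for `method = "mc"`.
#' @param seed Seed for the Monte Carlo null.
#' @return The two-sided p-value.
#' @export
fisher_exact_rxc <- function(table_counts, method = c("auto", "exact", "mc"),
                             n_mc = 2e5, seed = 1L) {
  method <- match.arg(method)
  tc <- as.matrix(table_counts)
  if (any(tc < 0) || any(tc != round(tc)))
    tme_format_error("contingency table must hold non-negative integers")
  tc <- tc[rowSums(tc) > 0, colSums(tc) > 0, drop = FALSE]
  if (sum(tc) == 0 || any(dim(tc) < 2)) return(1)
  if (method == "auto") {
    # rough candidate-table count: product over free cells of margin sizes
    log_cand <- (nrow(tc) - 1) * (ncol(tc) - 1) * log(mean(colSums(tc)) + 1)
    method <- if (log_cand <= log(1e6)) "exact" else "mc"
  }
  if (method == "exact") {
    res <- tryCatch(
      stats::fisher.test(tc, workspace = 2e7),
      error = function(e)
        tme_error(paste0("exact enumeration infeasible (", conditionMessage(e),
                         "); use method='mc'"), "tme_config_error"))
    return(res$p.value)
  }
  set.seed(derive_seed(seed, "fisher_mc"))
  stats::fisher.test(tc, simulate.p.value = TRUE, B = n_mc)$p.value
}

#' Two-sample Mann-Whitney U test
#'
#' Normal approximation with tie correction. Fully tied data yields p = 1
#' with a warning.
#'
#' @param x,y Non-empty numeric samples.
#' @param alternative `"two.sided"`, `"less"` or `"greater"`.
#' @return List: `U`, `p`.
#' @export
mann_whitney <- function(x, y, alternative = c("two.sided", "less",
                                               "greater")) {
  alternative <- match.arg(alternative)
  if (!length(x) || !length(y)) tme_config_error("empty sample")
  if (stats::sd(c(x, y)) == 0) {
    warning("all values tied across groups; p = 1")
    return(list(U = length(x) * length(y) / 2, p = 1))
  }
  wt <- stats::wilcox.test(x, y, alternative = alternative, exact = FALSE)
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Kruskal-Wallis rank-sum test across groups
#'
#' Chi-square approximation with tie correction. Fully tied data yields
#' p = 1 with a warning.
#'
#' @param values Numeric vector.
#' @param group Group label per value.
#' @return List: `H`, `df`, `p`.
#' @export
kruskal_wallis <- function(values, group) {
  if (!length(values)) tme_config_error("empty input")
  if (stats::sd(values) == 0) {
    warning("all values tied across groups; p = 1")
    return(list(H = 0, df = length(unique(group)) - 1, p = 1))
  }
  kt <- stats::kruskal.test(values, factor(group))
  list(H = unname(kt$statistic), df = unname(kt$parameter), p = kt$p.value)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p_list Numeric vector of p-values.
#' @return q-values in the input order.
#' @export
bh_adjust <- function(p_list) stats::p.adjust(p_list, method = "BH")
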