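# Shared fixtures: small synthetic cohorts (cached per seed) and the
# independent brute-force oracles used to cross-check package
# implementations.

small_config <- function(seed = 1, ...) {
  cohort_config(n_samples = 90, n_genes = 250, seed = seed, ...)
}

.fixtures <- new.env(parent = emptyenv())

small_gen <- function(seed = 1) {
  key <- paste0("gen", seed)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- generate_expression(small_config(seed))
  .fixtures[[key]]
}

# cached small discovery run (consensus at the true rank + classification)
small_discovery <- function(seed = 1) {
  key <- paste0("disc", seed)
  if (is.null(.fixtures[[key]])) {
    gen <- small_gen(seed)
    X <- prepare_nmf_input(gen$cohort)
    cons <- consensus_nmf(X, 5, n_restarts = 6, seed = seed + 500)
    a <- assign_factor(cons$best_model$H)
    sc <- estimate_ies_ses(gen$cohort,
                           gen$truth$marker_sets$immune_signature,
                           gen$truth$marker_sets$stromal_signature)
    # alpha 0.05: the factor-vs-rest rank test has limited power for an
    # ~18-member CAFs factor at n = 90 (cohort-scale runs keep alpha = 0.001)
    lab <- classify_factors(a, sc$ies, sc$ses, alpha = 0.05)
    .fixtures[[key]] <- list(gen = gen, cons = cons, assignment = a,
                             scores = sc, labels = lab)
  }
  .fixtures[[key]]
}

# Brute-force ssGSEA oracle: explicit walk over the ranked list, one gene at
# a time. Deliberately loop-based and independent of the vectorized
# implementation.
ssgsea_oracle <- function(X, gene_set, alpha = 0.25) {
  vapply(seq_len(ncol(X)), function(j) {
    x <- X[, j]
    r <- rank(x, ties.method = "average")
    ord <- order(x, decreasing = TRUE)
    inset <- rownames(X)[ord] %in% gene_set
    w <- r[ord]^alpha
    total_in <- sum(w[inset])
    total_out <- sum(!inset)
    es <- 0; cum_in <- 0; cum_out <- 0
    for (i in seq_along(ord)) {
      if (inset[i]) cum_in <- cum_in + w[i] else cum_out <- cum_out + 1
      es <- es + (cum_in / total_in - cum_out / total_out)
    }
    es
  }, numeric(1))
}

# Exact two-sided Mann-Whitney p by full enumeration of group assignments
# (tie-free inputs only; feasible for n + m <= 12).
mw_exact_p <- function(x, y) {
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  u_stat <- function(idx) {
    xs <- pooled[idx]
    sum(rank(pooled)[idx]) - n * (n + 1) / 2
  }
  obs <- u_stat(seq_len(n))
  mu <- n * m / 2
  all_idx <- utils::combn(n + m, n)
  us <- apply(all_idx, 2, u_stat)
  mean(abs(us - mu) >= abs(obs - mu) - 1e-12)
}

expect_tme_error <- function(expr, class) {
  expect_error(expr, class = class)
}
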