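# ssGSEA scoring and the derived immune/stromal/cell-type scores.

random_cohort <- function(n_genes, n_samples, seed) {
  set.seed(seed)
  m <- matrix(rexp(n_genes * n_samples, rate = 0.2), n_genes, n_samples,
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  expression_cohort(m)
}

test_that("ssGSEA matches the brute-force cumulative-sum oracle", {
  for (i in 1:30) {
    co <- random_cohort(20, 5, seed = i)
    set.seed(i + 1000)
    gset <- sample(genes(co), sample(2:8, 1))
    got <- ssgsea(co, list(S = gset), normalize = FALSE)[, "S"]
    want <- ssgsea_oracle(co$values, gset)
    expect_equal(unname(got), want, tolerance = 1e-9)
  }
})

test_that("scores are invariant under strictly monotone transforms", {
  co <- random_cohort(30, 4, seed = 3)
  gset <- genes(co)[1:6]
  base <- ssgsea(co, list(S = gset), normalize = FALSE)
  sq <- expression_cohort(co$values^2)
  lg <- expression_cohort(log1p(co$values))
  expect_equal(ssgsea(sq, list(S = gset), normalize = FALSE), base)
  expect_equal(ssgsea(lg, list(S = gset), normalize = FALSE), base)
})

test_that("a top-expressed singleton-plus-one set scores positive and reversal negates", {
  co <- random_cohort(25, 3, seed = 4)
  top2 <- names(sort(co$values[, 1], decreasing = TRUE))[1:2]
  es <- ssgsea(co, list(S = top2), normalize = FALSE)[1, "S"]
  expect_gt(es, 0)

  # with unit weights (alpha = 0), reversing the ranking negates the score
  rev_co <- expression_cohort(max(co$values) - co$values + 1)
  es0 <- ssgsea(co, list(S = top2), alpha = 0, normalize = FALSE)
  es0_rev <- ssgsea(rev_co, list(S = top2), alpha = 0, normalize = FALSE)
  expect_equal(es0_rev, -es0, tolerance = 1e-9)
})

test_that("undersized sets are skipped with a warning", {
  co <- random_cohort(10, 2, seed = 5)
  expect_warning(sc <- ssgsea(co, list(ok = genes(co)[1:3],
                                       bad = c("absent1", "absent2"))),
                 "bad")
  expect_identical(colnames(sc), "ok")
  expect_error(suppressWarnings(ssgsea(co, list(bad = "absent"))),
               class = "tme_config_error")
})

test_that("planted IES/SES separations hold and die under permutation", {
  gen <- small_gen(1)
  truth <- gen$truth
  sc <- estimate_ies_ses(gen$cohort, truth$marker_sets$immune_signature,
                         truth$marker_sets$stromal_signature)
  imm <- truth$subtype %in% c("activated", "CAFs")
  p_imm <- stats::wilcox.test(sc$ies[imm], sc$ies[!imm],
                              alternative = "greater", exact = FALSE)$p.value
  expect_lt(p_imm, 0.001)
  med_ses <- tapply(sc$ses, truth$subtype, median)
  expect_equal(names(which.max(med_ses)), "CAFs")

  # permuting gene labels removes the planted separation. A randomly
  # relabelled set still picks up weak composition signal (the synthetic
  # transcriptome has exactly k latent axes, so every gene set correlates
  # with some of them), so the permuted p collapses toward the null rather
  # than vanishing identically.
  p_perm <- vapply(1:9, function(s) {
    set.seed(s + 40)
    perm <- gen$cohort$values
    rownames(perm) <- sample(rownames(perm))
    sc_p <- estimate_ies_ses(expression_cohort(perm),
                             truth$marker_sets$immune_signature,
                             truth$marker_sets$stromal_signature)
    stats::wilcox.test(sc_p$ies[imm], sc_p$ies[!imm],
                       alternative = "greater", exact = FALSE)$p.value
  }, numeric(1))
  expect_gt(median(p_perm), 0.05)
  expect_lt(p_imm, median(p_perm) / 100)
})

test_that("cell-type scores are marker means on log scale and monotone", {
  co <- random_cohort(20, 4, seed = 6)
  const <- expression_cohort(matrix(7, 5, 3,
                                    dimnames = list(sprintf("m%d", 1:5),
                                                    sprintf("s%d", 1:3))))
  sc <- score_cell_types(const, list(pop = sprintf("m%d", 1:5)))
  expect_equal(unname(sc[, "pop"]), rep(log2(8), 3))

  up <- co$values; up[1, ] <- up[1, ] * 4
  sc0 <- score_cell_types(co, list(pop = genes(co)[1:3]))
  sc1 <- score_cell_types(expression_cohort(up), list(pop = genes(co)[1:3]))
  expect_true(all(sc1[, "pop"] >= sc0[, "pop"]))

  expect_warning(score_cell_types(co, list(ok = genes(co)[1:3],
                                           none = "missing_gene")), "none")
})

test_that("T-cell-like scores are elevated in the planted immune class", {
  gen <- small_gen(1)
  sc <- score_cell_types(gen$cohort,
                         list(T_cells = gen$truth$marker_sets$immune_signature[1:10]))
  imm <- gen$truth$class == "immune"
  expect_lt(stats::wilcox.test(sc[imm, 1], sc[!imm, 1],
                               alternative = "greater",
                               exact = FALSE)$p.value, 0.001)
})

test_that("M1/M2 ratio behaves at equality and under planted dominance", {
  cs <- cbind(M1 = c(1, 2, 0.5), M2 = c(1, 1, 1))
  rownames(cs) <- sprintf("s%d", 1:3)
  r <- m1_m2_ratio(cs)
  expect_equal(unname(r[1]), 1)
  expect_gt(r[2], 1); expect_lt(r[3], 1)
  expect_error(m1_m2_ratio(cbind(M1 = 1)), class = "tme_config_error")
})

test_that("cytolytic activity is the offset geometric mean of GZMA and PRF1", {
  m <- rbind(GZMA = c(0, 99.99), PRF1 = c(0, 0.99), other = c(5, 5))
  colnames(m) <- c("s1", "s2")
  cyt <- cytolytic_activity(expression_cohort(m))
  expect_equal(unname(cyt), c(0.01, 10))
  expect_error(cytolytic_activity(expression_cohort(m[3, , drop = FALSE])),
               "GZMA", class = "tme_format_error")

  gen <- small_gen(1)
  cyt_s <- cytolytic_activity(gen$cohort)
  imm <- gen$truth$class == "immune"
  expect_lt(stats::wilcox.test(cyt_s[imm], cyt_s[!imm],
                               alternative = "greater",
                               exact = FALSE)$p.value, 0.001)
})
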