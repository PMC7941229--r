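# Differential expression, template derivation, NTP projection and
# subclass mapping.

test_that("identical groups yield zero fold-change and no significance", {
  gen <- small_gen(1)
  lg <- to_log2(gen$cohort)
  s <- samples(lg)[1:6]
  m <- lg$values[, c(s, s)]
  colnames(m) <- c(paste0("a", 1:6), paste0("b", 1:6))
  dup <- expression_cohort(m, scale = "log2")
  de <- differential_expression(dup, paste0("a", 1:6), paste0("b", 1:6))
  expect_true(all(de$log2fc == 0))
  expect_false(any(de$significant))
})

test_that("differential expression validates inputs", {
  gen <- small_gen(1)
  lg <- to_log2(gen$cohort)
  expect_error(differential_expression(gen$cohort, samples(lg)[1:5],
                                       samples(lg)[6:10]),
               class = "tme_config_error")   # linear scale rejected
  expect_error(differential_expression(lg, samples(lg)[1:5],
                                       samples(lg)[5:9]),
               class = "tme_label_error")    # overlap
  expect_error(differential_expression(lg, samples(lg)[1:2],
                                       samples(lg)[3:9]),
               class = "tme_config_error")   # too few
})

test_that("planted program genes are recovered with high sensitivity", {
  gen <- small_gen(2)
  truth <- gen$truth
  lg <- to_log2(gen$cohort)
  imm_samples <- names(truth$subtype)[truth$subtype == "activated"]
  inact_samples <- names(truth$subtype)[truth$subtype == "inactivated"]
  de <- differential_expression(lg, imm_samples, inact_samples,
                                fc_threshold = 0.4)
  imm_genes <- truth$marker_sets$immune_signature
  sig_up <- de$gene[de$significant & de$direction == "up"]
  sens <- mean(imm_genes %in% sig_up)
  expect_gte(sens, 0.9)
  # false discoveries among planted-null comparisons stay controlled:
  # genes called up in activated should be immune-program genes
  fdr <- mean(!(sig_up %in% imm_genes))
  expect_lte(fdr, 0.1)
})

test_that("BH step-up matches the hand-computed example", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
})

test_that("templates are unique per subtype, disjoint and planted-program aligned", {
  gen <- small_gen(1)
  tmpl <- derive_templates(gen$cohort, gen$truth$subtype)
  expect_s3_class(tmpl, "classifier_template")
  expect_length(Reduce(intersect, tmpl), 0)
  prog <- gen$truth$gene_program
  expect_true(all(prog[tmpl$CAFs] == "stroma"))
  expect_true(all(tmpl$activated %in% gen$truth$marker_sets$effector_signature))
  expect_true(all(startsWith(prog[tmpl$inactivated], "tumour")))

  # a gene high in two subtypes is excluded from both marker lists:
  # interface immune genes are high in activated AND CAFs
  interface <- setdiff(gen$truth$marker_sets$immune_signature,
                       gen$truth$marker_sets$effector_signature)
  expect_length(intersect(unlist(tmpl), interface), 0)

  expect_error(derive_templates(gen$cohort, gen$truth$subtype,
                                fc_threshold = 10),
               "relaxing", class = "tme_config_error")
})

test_that("NTP recovers a constructed exact-template sample", {
  tmpl <- structure(list(A = sprintf("g%d", 1:6), B = sprintf("g%d", 7:12)),
                    class = "classifier_template")
  set.seed(8)
  base <- matrix(rnorm(20 * 40, 5, 1), 20, 40,
                 dimnames = list(sprintf("g%d", 1:20), sprintf("s%d", 1:40)))
  # sample s1 engineered to be high exactly on A's markers
  base[1:6, 1] <- 12
  base[7:20, 1] <- 2
  co <- expression_cohort(pmax(base, 0), scale = "log2")
  res <- ntp_classify(co, tmpl, n_resample = 100, seed = 1)
  expect_equal(res$prediction[res$sample == "s1"], "A")
  expect_lte(res$p[res$sample == "s1"], 1 / 100)
  expect_true(all(res$p > 0 & res$p <= 1))
})

test_that("NTP projects into an independent cohort and fails on permuted templates", {
  gen <- small_gen(1)
  tmpl <- derive_templates(gen$cohort, gen$truth$subtype)
  gen2 <- generate_expression(small_config(seed = 404))
  res <- ntp_classify(gen2$cohort, tmpl, n_resample = 100, seed = 3)
  acc <- mean(res$prediction == gen2$truth$subtype[res$sample])
  expect_gte(acc, 0.85)

  # label-permuted templates: accuracy near chance
  accs <- vapply(1:6, function(s) {
    perm <- tmpl
    names(perm) <- names(tmpl)[c(2, 3, 1)]
    res_p <- ntp_classify(gen2$cohort, perm, n_resample = 10, seed = s)
    mean(res_p$prediction == gen2$truth$subtype[res_p$sample])
  }, numeric(1))
  expect_lte(mean(accs), 0.45)
})

test_that("NTP is invariant to affine rescaling of the expression matrix", {
  gen <- small_gen(1)
  tmpl <- derive_templates(gen$cohort, gen$truth$subtype)
  lg <- to_log2(gen$cohort)
  scaled <- 3.7 * lg$values + 11   # gene z-scores absorb the transform
  res0 <- ntp_classify(lg, tmpl, n_resample = 10, seed = 4)
  res1 <- ntp_classify(expression_cohort(scaled, scale = "log2"), tmpl,
                       n_resample = 10, seed = 4)
  expect_identical(res0$prediction, res1$prediction)
  expect_equal(res0$dist_activated, res1$dist_activated, tolerance = 1e-9)
})

test_that("self-projection reproduces discovery labels", {
  disc <- small_discovery(1)
  tmpl <- derive_templates(disc$gen$cohort, disc$labels)
  res <- ntp_classify(disc$gen$cohort, tmpl, n_resample = 50, seed = 5)
  acc <- mean(res$prediction ==
                disc$labels$labels$subtype[match(res$sample,
                                                 disc$labels$labels$sample)])
  expect_gte(acc, 0.9)
})

test_that("subclass mapping associates matched subtypes across cohorts", {
  gen <- small_gen(1)
  gen2 <- generate_expression(small_config(seed = 404))
  sm_self <- subclass_map(gen$cohort, gen$truth$subtype,
                          gen$cohort, gen$truth$subtype,
                          n_perm = 99, seed = 1)
  expect_true(all(diag(sm_self$p) == 1 / 100))
  expect_true(all(sm_self$p >= 1 / 100 & sm_self$p <= 1))

  # n_perm large enough that the smallest attainable Bonferroni p
  # (9 / (n_perm + 1)) clears 0.05
  sm <- subclass_map(gen$cohort, gen$truth$subtype,
                     gen2$cohort, gen2$truth$subtype,
                     n_perm = 499, seed = 2)
  # at this cohort size the permutation null has heavy tails (chance
  # subtype imbalance in permuted groups), so assert uncorrected diagonal
  # significance, null off-diagonals, and the matched subtype being the
  # strongest association in every row
  expect_true(all(diag(sm$p) < 0.05))
  off <- sm$p; diag(off) <- NA
  expect_true(all(off > 0.05, na.rm = TRUE))
  expect_equal(unname(apply(sm$statistic, 1, which.max)), 1:3)

  small <- subset_cohort(gen$cohort, genes = genes(gen$cohort)[1:50])
  expect_error(subclass_map(small, gen$truth$subtype, small,
                            gen$truth$subtype),
               class = "tme_config_error")
})
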