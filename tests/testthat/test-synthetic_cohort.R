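# Generator properties: config validation, planted expression structure,
# methylation silencing, mutation spectra, survival and clinical signals.

test_that("cohort_config rejects invalid settings", {
  expect_error(cohort_config(noise_sd = NA), class = "tme_config_error")
  expect_error(cohort_config(immune_effect = 0), class = "tme_config_error")
  expect_error(cohort_config(n_genes = 30, k_true = 5),
               class = "tme_config_error")
  expect_error(cohort_config(subtype_fractions = c(activated = 0.5, CAFs = 0.5,
                                                   inactivated = 0.5)),
               class = "tme_config_error")
})

test_that("noise-free expression equals the planted factor product exactly", {
  gen <- generate_expression(small_config(seed = 3, noise_sd = 0))
  expect_equal(gen$cohort$values, gen$truth$W_true %*% gen$truth$H_true,
               tolerance = 1e-12)
  expect_true(all(gen$cohort$values >= 0))
})

test_that("generators are bit-reproducible given seed and config", {
  g1 <- generate_expression(small_config(seed = 8))
  g2 <- generate_expression(small_config(seed = 8))
  expect_identical(g1$cohort$values, g2$cohort$values)
  expect_identical(g1$truth$subtype, g2$truth$subtype)
  cfg <- small_config(seed = 8)
  expect_identical(generate_survival(g1$truth, cfg),
                   generate_survival(g2$truth, cfg))
})

test_that("immune effect plants an expression separation that vanishes under the null", {
  imm_up <- 0; null_flat <- 0
  n_seeds <- 8
  for (s in seq_len(n_seeds)) {
    gen <- generate_expression(small_config(seed = s))
    imm <- gen$truth$marker_sets$immune_signature
    score <- colMeans(log2(gen$cohort$values[imm, ] + 1))
    grp <- gen$truth$class
    imm_up <- imm_up +
      (mean(score[grp == "immune"]) > mean(score[grp == "non-immune"]))

    gen0 <- generate_expression(small_config(seed = s, immune_effect = 1,
                                             stromal_effect = 1))
    imm0 <- gen0$truth$marker_sets$immune_signature
    score0 <- colMeans(log2(gen0$cohort$values[imm0, ] + 1))
    p0 <- stats::wilcox.test(score0[gen0$truth$class == "immune"],
                             score0[gen0$truth$class == "non-immune"],
                             exact = FALSE)$p.value
    null_flat <- null_flat + (p0 > 0.01)
  }
  expect_equal(imm_up, n_seeds)          # planted effect in every seed
  expect_gte(null_flat, n_seeds - 1)     # null separation absent
})

test_that("methylation plants in-range betas and expression anti-correlation", {
  neg_cor <- 0
  n_seeds <- 6
  for (s in seq_len(n_seeds)) {
    cfg <- small_config(seed = s, n_silenced = 10)
    gen <- generate_expression(cfg)
    meth <- generate_methylation(gen$truth, cfg, gen$cohort)
    expect_true(all(meth$tumour_beta >= 0 & meth$tumour_beta <= 1))
    expect_true(all(meth$normal_beta >= 0 & meth$normal_beta <= 1))
    g <- gen$truth$silenced_genes[1]
    probe <- meth$annotation$probe[meth$annotation$gene == g &
                                     meth$annotation$island][1]
    rho <- cor(meth$tumour_beta[probe, ],
               meth$cohort$values[g, colnames(meth$tumour_beta)],
               method = "spearman")
    neg_cor <- neg_cor + (rho < 0)
    # silenced genes hypermethylated relative to normals
    expect_gte(mean(meth$tumour_beta[probe, ]),
               mean(meth$normal_beta[probe, ]) + 0.3)
  }
  expect_gte(neg_cor, n_seeds - 1)
})

test_that("no planted silencing leaves tumour and normal betas exchangeable", {
  cfg <- small_config(seed = 2, n_silenced = 0)
  gen <- generate_expression(cfg)
  meth <- generate_methylation(gen$truth, cfg, gen$cohort)
  expect_identical(meth$cohort$values, gen$cohort$values)
  expect_lt(abs(mean(meth$tumour_beta) - mean(meth$normal_beta)), 0.01)
})

test_that("mutation generation follows the planted burden and spectrum", {
  cfg <- small_config(seed = 4)
  gen <- generate_expression(cfg)

  # zero burden -> empty table
  cfg0 <- small_config(seed = 4, tmb_means = c(activated = 0, CAFs = 0,
                                               inactivated = 0))
  mut0 <- generate_mutations(gen$truth, cfg0)
  expect_equal(nrow(mut0$mutations), 0)

  # law of large numbers: single-signature mixture converges to that column
  sig <- synthetic_signatures()
  expo1 <- cbind(activated = c(0, 0, 1), CAFs = c(0, 0, 1),
                 inactivated = c(0, 0, 1))
  rownames(expo1) <- colnames(sig)
  cfg_big <- small_config(seed = 4, tmb_means = c(activated = 60, CAFs = 60,
                                                  inactivated = 60))
  mut1 <- generate_mutations(gen$truth, cfg_big, sig, expo1)
  expect_gte(nrow(mut1$mutations), 5000)
  spec <- trinucleotide_spectrum(mut1$mutations, per = "cohort")
  expect_lt(sum(abs(spec[, 1] - sig[, "S3"])), 0.1)

  # malformed signature matrix rejected
  bad <- sig; bad[1, 1] <- bad[1, 1] + 0.5
  expect_error(generate_mutations(gen$truth, cfg, bad),
               class = "tme_config_error")
})

test_that("planted burden difference is detectable by rank test", {
  cfg <- cohort_config(n_samples = 200, n_genes = 250, seed = 5,
                       subtype_fractions = c(activated = 0.5, CAFs = 0,
                                             inactivated = 0.5),
                       tmb_means = c(activated = 10, CAFs = 10,
                                     inactivated = 2))
  gen <- generate_expression(cfg)
  mut <- generate_mutations(gen$truth, cfg)
  counts <- table(factor(mut$mutations$Tumor_Sample_Barcode,
                         levels = names(gen$truth$subtype)))
  p <- stats::wilcox.test(counts[gen$truth$subtype == "activated"],
                          counts[gen$truth$subtype == "inactivated"],
                          exact = FALSE)$p.value
  expect_lt(p, 0.01)
})

test_that("survival hazards are recovered and the null is calibrated", {
  # parameter recovery: ln(HR) close to planted value on average
  est <- replicate(25, {
    cfg <- cohort_config(n_samples = 300, n_genes = 250,
                         seed = sample.int(1e6, 1),
                         subtype_fractions = c(activated = 0.5, CAFs = 0,
                                               inactivated = 0.5),
                         hazard_ratios = c(activated = 1, CAFs = 1,
                                           inactivated = 2))
    gen <- generate_expression(cfg)
    surv <- generate_survival(gen$truth, cfg)
    x <- as.numeric(surv$subtype == "inactivated")
    cox_univariate(x, surv$time, surv$event)$coef
  })
  expect_lt(abs(mean(est) - log(2)), 0.2)

  # equal hazards -> log-rank p roughly uniform
  set.seed(99)
  pvals <- replicate(150, {
    cfg <- cohort_config(n_samples = 120, n_genes = 250,
                         seed = sample.int(1e6, 1),
                         hazard_ratios = c(activated = 1, CAFs = 1,
                                           inactivated = 1))
    gen <- .fixtures$null_surv_gen
    if (is.null(gen)) {
      gen <- generate_expression(cfg)
      .fixtures$null_surv_gen <- gen
    }
    surv <- generate_survival(gen$truth, cfg)
    km_logrank(surv$time, surv$event, surv$subtype, pairwise = FALSE)$p
  })
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("fully censored survival leaves the log-rank test undefined", {
  cfg <- small_config(seed = 6)
  gen <- small_gen(6)
  surv <- generate_survival(gen$truth, cfg)
  surv$event <- 0L
  expect_error(km_logrank(surv$time, surv$event, surv$subtype),
               "no events", class = "tme_config_error")
})

test_that("clinical covariates follow subtype-conditional probabilities", {
  cfg <- small_config(seed = 7)
  gen <- small_gen(7)

  # deterministic covariate -> strong association
  det <- list(det_cov = list(
    categories = c("x", "y", "z"),
    probs = rbind(activated = c(1, 0, 0), CAFs = c(0, 1, 0),
                  inactivated = c(0, 0, 1))))
  cl <- generate_clinical(gen$truth, cfg, det)
  expect_lt(fisher_exact_rxc(table(cl$det_cov, cl$subtype)), 0.001)
  expect_false(anyNA(cl$det_cov))  # missing rate 0 by default

  # uniform probabilities -> null calibration
  unif <- list(u = list(categories = c("a", "b"),
                        probs = rbind(activated = c(0.5, 0.5),
                                      CAFs = c(0.5, 0.5),
                                      inactivated = c(0.5, 0.5))))
  hits <- sum(vapply(1:40, function(s) {
    cfg_s <- small_config(seed = s + 300)
    gen_s <- generate_expression(cfg_s)
    cl_s <- generate_clinical(gen_s$truth, cfg_s, unif)
    fisher_exact_rxc(table(cl_s$u, cl_s$subtype)) > 0.05
  }, logical(1)))
  expect_gte(hits, 34)  # >= 85% of null runs non-significant

  # invalid probabilities rejected; missingness honoured
  bad <- unif; bad$u$probs[1, ] <- c(0.7, 0.6)
  expect_error(generate_clinical(gen$truth, cfg, bad),
               class = "tme_config_error")
  cfg_miss <- small_config(seed = 7, missing_rate = 0.3)
  cl_miss <- generate_clinical(gen$truth, cfg_miss, unif)
  expect_gt(mean(is.na(cl_miss$u)), 0.1)
})

test_that("ground-truth manifest is valid JSON separate from the data", {
  gen <- small_gen()
  path <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(gen$truth, path)
  manifest <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_identical(sort(unique(unlist(manifest$subtype))),
                   sort(unique(unname(gen$truth$subtype))))
  expect_setequal(manifest$silenced_genes, gen$truth$silenced_genes)
})
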