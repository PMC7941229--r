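# NMF factorization, consensus, BIC rank selection and factor
# classification.

test_that("multiplicative updates recover an exact low-rank factorization", {
  set.seed(1)
  W0 <- matrix(runif(60 * 3), 60, 3)
  H0 <- matrix(runif(3 * 20), 3, 20)
  X <- W0 %*% H0
  dimnames(X) <- list(sprintf("g%d", 1:60), sprintf("s%d", 1:20))
  fm <- nmf_factorize(X, 3, seed = 2, max_iter = 2000, tol = 1e-12)
  expect_lte(fm$rss, 1e-6 * sum(X^2))
  expect_true(all(fm$W >= 0) && all(fm$H >= 0))
  # unit-L2 W columns with compensation absorbed into H
  expect_equal(unname(colSums(fm$W^2)), rep(1, 3), tolerance = 1e-8)
})

test_that("rank-1 matrices factor perfectly at k = 1", {
  set.seed(2)
  X <- outer(runif(30), runif(10))
  dimnames(X) <- list(sprintf("g%d", 1:30), sprintf("s%d", 1:10))
  fm <- nmf_factorize(X, 1, seed = 1, max_iter = 500, tol = 1e-12)
  expect_lt(fm$rss / sum(X^2), 1e-8)
})

test_that("the objective is monotone non-increasing and inputs are validated", {
  set.seed(3)
  X <- matrix(rexp(300), 30, 10,
              dimnames = list(sprintf("g%d", 1:30), sprintf("s%d", 1:10)))
  fm <- nmf_factorize(X, 4, seed = 5, max_iter = 100, tol = 0)
  expect_true(all(diff(fm$obj_trace) <= 1e-8 * fm$obj_trace[-length(fm$obj_trace)]))

  Xneg <- X; Xneg[1, 1] <- -1
  expect_error(nmf_factorize(Xneg, 2), class = "tme_domain_error")
  Xzero <- X; Xzero[1, ] <- 0
  expect_error(nmf_factorize(Xzero, 2), class = "tme_domain_error")
})

test_that("consensus on separable blocks is crisp, on noise it is not", {
  set.seed(4)
  X <- matrix(0.01, 40, 24)
  X[1:20, 1:12] <- 5 + matrix(runif(240), 20)
  X[21:40, 13:24] <- 5 + matrix(runif(240), 20)
  dimnames(X) <- list(sprintf("g%d", 1:40), sprintf("s%d", 1:24))
  cons <- consensus_nmf(X, 2, n_restarts = 6, seed = 9)
  expect_true(all(cons$consensus %in% c(0, 1)))
  expect_equal(cons$cophenetic, 1, tolerance = 1e-9)

  noise <- matrix(rexp(40 * 24), 40, 24,
                  dimnames = dimnames(X))
  cons_noise <- consensus_nmf(noise, 2, n_restarts = 6, seed = 9)
  expect_lt(cons_noise$cophenetic, cons$cophenetic)

  # definition check at 2 restarts: consensus is the average of two 0/1
  # co-assignment matrices
  c2 <- consensus_nmf(X, 2, n_restarts = 2, seed = 3)
  manual <- (outer(c2$assignments[1, ], c2$assignments[1, ], "==") +
               outer(c2$assignments[2, ], c2$assignments[2, ], "==")) / 2
  expect_equal(unname(c2$consensus), unname(manual))
  expect_error(consensus_nmf(X, 2, n_restarts = 1), class = "tme_config_error")
})

test_that("BIC selects the planted rank and degenerates sensibly", {
  gen <- generate_expression(cohort_config(n_samples = 150, n_genes = 600,
                                           seed = 31))
  X <- prepare_nmf_input(gen$cohort)
  rs <- select_rank(X, 2, 7, n_restarts = 3, seed = 11)
  expect_equal(rs$k, 5)
  expect_true(all(is.finite(rs$scores$bic)))

  # rank-1 noiseless matrix: extra factors only add penalty -> k_min chosen
  set.seed(5)
  X1 <- outer(runif(40, 1, 2), runif(15, 1, 2))
  dimnames(X1) <- list(sprintf("g%d", 1:40), sprintf("s%d", 1:15))
  rs1 <- select_rank(X1, 1, 4, n_restarts = 3, seed = 2, max_iter = 500)
  expect_equal(rs1$k, 1)

  expect_error(select_rank(X1, 2, 20), class = "tme_config_error")
})

test_that("factor assignment takes the arg-max with deterministic ties", {
  H <- cbind(s1 = c(0.1, 0.9, 0), s2 = c(0.5, 0.5, 0), s3 = c(0, 0, 1))
  rownames(H) <- paste0("F", 1:3)
  expect_message(a <- assign_factor(H), "tie")
  expect_equal(unname(a), c(2L, 1L, 3L))

  H0 <- H; H0[, "s3"] <- 0
  expect_error(assign_factor(H0), "s3", class = "tme_unassigned_error")
})

test_that("factor classification labels immune and CAFs factors by IES/SES", {
  set.seed(6)
  assignment <- stats::setNames(rep(1:3, each = 30), sprintf("s%d", 1:90))
  ies <- stats::setNames(c(rnorm(30, 3), rnorm(30, 3), rnorm(30, 0)),
                         names(assignment))
  ses <- stats::setNames(c(rnorm(30, 0), rnorm(30, 3), rnorm(30, 0)),
                         names(assignment))
  lab <- classify_factors(assignment, ies, ses, alpha = 0.01)
  sub_of <- with(lab$labels, tapply(subtype, factor, unique))
  expect_equal(as.character(sub_of), c("activated", "CAFs", "inactivated"))
  expect_true(all(lab$labels$class[lab$labels$subtype == "inactivated"] ==
                    "non-immune"))

  # conservative limit: with absurdly small alpha nothing is immune
  lab0 <- classify_factors(assignment, ies, ses, alpha = 1e-12)
  expect_true(all(lab0$labels$subtype == "inactivated"))

  # tiny factors are reassigned to the nearest classified centroid
  a2 <- assignment; a2[1:2] <- 9L
  expect_message(lab2 <- classify_factors(a2, ies, ses, alpha = 0.01),
                 "reassigned")
  expect_equal(unique(lab2$labels$subtype[lab2$labels$factor == 9]),
               "activated")
})

test_that("planted subtypes are recovered on the small cohort", {
  disc <- small_discovery(1)
  ari <- adjusted_rand_index(disc$labels$labels$subtype,
                             disc$gen$truth$subtype[disc$labels$labels$sample])
  expect_gte(ari, 0.8)
  # independent oracle for the ARI computation itself
  skip_if_not_installed("mclust")
  expect_equal(ari,
               mclust::adjustedRandIndex(
                 disc$labels$labels$subtype,
                 disc$gen$truth$subtype[disc$labels$labels$sample]),
               tolerance = 1e-12)
})

test_that("immune class IES exceeds the non-immune class on planted data", {
  disc <- small_discovery(1)
  lab <- disc$labels$labels
  p <- stats::wilcox.test(disc$scores$ies[lab$sample[lab$class == "immune"]],
                          disc$scores$ies[lab$sample[lab$class == "non-immune"]],
                          alternative = "greater", exact = FALSE)$p.value
  expect_lt(p, 0.001)
})
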