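# Orchestration of the discovery -> scoring -> classification pipeline and
# the collated result bundle. Every stage is deterministic given the run
# seed (fanned out per stage by derive_seed) and writes plain TSV/JSON so
# reruns are byte-identical.

#' Run the full discovery pipeline on a training cohort
#'
#' Standardizes the cohort for NMF, optionally selects the factorization
#' rank by BIC, runs consensus NMF, scores IES/SES, classifies factors into
#' the three subtypes, and derives the subtype marker templates.
#'
#' @param cohort A linear-scale [expression_cohort()].
#' @param immune_set,stromal_set Gene sets for IES/SES.
#' @param k Factorization rank; if NULL, selected by BIC over `k_range`.
#' @param k_range Rank search range for BIC selection.
#' @param n_restarts Consensus restarts.
#' @param seed Run seed.
#' @param alpha Factor-classification significance threshold.
#' @param fc_threshold,q_threshold Template derivation thresholds.
#' @param max_iter,tol NMF iteration controls.
#' @param out_dir If non-NULL, write labels/consensus/BIC/template/manifest
#'   files there.
#' @return List: `labels` (a `subtype_labels`), `consensus`, `rank`
#'   (NULL when `k` fixed), `scores` (ies/ses), `templates`, `manifest`.
#' @export
run_discovery <- function(cohort, immune_set, stromal_set, k = NULL,
                          k_range = 2:8, n_restarts = 10L, seed = 1L,
                          alpha = 0.001, fc_threshold = 0.4, q_threshold = 0.05,
                          max_iter = 200L, tol = 1e-5, out_dir = NULL) {
  t0 <- Sys.time()
  manifest <- list(seed = seed, stages = list(), outputs = list())
  X <- prepare_nmf_input(cohort)

  rank_res <- NULL
  if (is.null(k)) {
    rank_res <- select_rank(X, min(k_range), max(k_range),
                            n_restarts = max(3L, n_restarts %/% 2L),
                            seed = derive_seed(seed, "rank"),
                            max_iter = max_iter, tol = tol)
    k <- rank_res$k
    manifest$stages$rank_selection <- list(status = "done", chosen_k = k)
  }
  cons <- consensus_nmf(X, k, n_restarts = n_restarts,
                        seed = derive_seed(seed, "consensus"),
                        max_iter = max_iter, tol = tol)
  manifest$stages$consensus_nmf <- list(status = "done", k = k,
                                        cophenetic = cons$cophenetic)

  assignment <- assign_factor(cons$best_model$H)
  scores <- estimate_ies_ses(cohort, immune_set, stromal_set)
  labels <- classify_factors(assignment, scores$ies, scores$ses,
                             alpha = alpha)
  manifest$stages$classification <- list(
    status = "done",
    sizes = as.list(table(labels$labels$subtype)))

  templates <- derive_templates(cohort, labels, fc_threshold = fc_threshold,
                                q_threshold = q_threshold)
  manifest$stages$templates <- list(status = "done",
                                    sizes = as.list(lengths(templates)))
  manifest$elapsed_sec <- as.numeric(difftime(Sys.time(), t0, units = "secs"))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      labels = file.path(out_dir, "labels.tsv"),
      consensus = file.path(out_dir, "consensus.tsv"),
      templates = file.path(out_dir, "templates.gmt"),
      manifest = file.path(out_dir, "manifest.json"))
    write_tsv(labels$labels, paths$labels)
    write_matrix_tsv(cons$consensus, paths$consensus)
    if (!is.null(rank_res)) {
      paths$bic <- file.path(out_dir, "bic.tsv")
      write_tsv(rank_res$scores, paths$bic)
    }
    write_gmt(templates, paths$templates)
    manifest$outputs <- paths
    jsonlite::write_json(manifest[setdiff(names(manifest), "elapsed_sec")],
                         paths$manifest, auto_unbox = TRUE, pretty = TRUE)
  }
  list(labels = labels, consensus = cons, rank = rank_res, scores = scores,
       templates = templates, manifest = manifest)
}

#' Project the subtype classifier into a validation cohort
#'
#' NTP classification with the training templates, IES/SES contrasts across
#' predicted subtypes, and (when the training cohort is supplied) the
#' subclass map between training and validation subtypes.
#'
#' @param cohort Validation [expression_cohort()].
#' @param templates A `classifier_template`.
#' @param immune_set,stromal_set Gene sets for IES/SES.
#' @param train_cohort,train_labels Optional training cohort and labels for
#'   subclass mapping.
#' @param n_resample NTP resamples.
#' @param n_perm Subclass-map permutations.
#' @param seed Run seed.
#' @return List: `ntp` (per-sample predictions), `scores`, `score_tests`
#'   (IES/SES Kruskal-Wallis p across predicted subtypes), `subclass`
#'   (NULL without a training cohort).
#' @export
run_validation <- function(cohort, templates, immune_set, stromal_set,
                           train_cohort = NULL, train_labels = NULL,
                           n_resample = 1000L, n_perm = 500L, seed = 1L) {
  if (!length(unlist(templates)))
    tme_config_error("empty classifier template")
  ntp <- ntp_classify(cohort, templates, n_resample = n_resample,
                      seed = derive_seed(seed, "validation_ntp"))
  scores <- estimate_ies_ses(cohort, immune_set, stromal_set)
  pred <- stats::setNames(ntp$prediction, ntp$sample)
  score_tests <- list(
    ies_kw = kruskal_wallis(scores$ies[names(pred)], pred),
    ses_kw = kruskal_wallis(scores$ses[names(pred)], pred))
  subclass <- NULL
  if (!is.null(train_cohort) && !is.null(train_labels))
    subclass <- subclass_map(train_cohort, train_labels, cohort, pred,
                             n_perm = n_perm,
                             seed = derive_seed(seed, "subclass"))
  list(ntp = ntp, scores = scores, score_tests = score_tests,
       subclass = subclass)
}

#' Collate pipeline results into one machine-readable report
#'
#' Builds the summary tables mirroring the analysis surfaces: subtype
#' sizes, IES/SES contrasts, survival and clinical association tests,
#' genomic burden contrasts, epigenetic call counts and the drug response
#' table. Sections without results are marked `"absent"`, never fabricated.
#'
#' @param discovery Result of [run_discovery()].
#' @param validation Result of [run_validation()] (optional).
#' @param survival_tests,clinical_tests,genomics,epigenetics,drugs Optional
#'   precomputed section contents (lists/data.frames from the respective
#'   modules).
#' @param path If non-NULL, the report is written there as JSON.
#' @return The report list.
#' @export
run_report <- function(discovery = NULL, validation = NULL,
                       survival_tests = NULL, clinical_tests = NULL,
                       genomics = NULL, epigenetics = NULL, drugs = NULL,
                       path = NULL) {
  if (is.null(discovery) && is.null(validation) && is.null(survival_tests) &&
      is.null(clinical_tests) && is.null(genomics) && is.null(epigenetics) &&
      is.null(drugs))
    tme_config_error("at least one completed stage is required")
  section <- function(x, build) if (is.null(x)) "absent" else build(x)
  report <- list(
    discovery = section(discovery, function(d) list(
      subtype_sizes = as.list(table(d$labels$labels$subtype)),
      class_sizes = as.list(table(d$labels$labels$class)),
      cophenetic = d$consensus$cophenetic,
      chosen_k = if (is.null(d$rank)) d$consensus$k else d$rank$k,
      template_sizes = as.list(lengths(d$templates)))),
    validation = section(validation, function(v) list(
      predicted_sizes = as.list(table(v$ntp$prediction)),
      ies_kw_p = v$score_tests$ies_kw$p,
      ses_kw_p = v$score_tests$ses_kw$p)),
    survival = section(survival_tests, identity),
    clinical = section(clinical_tests, identity),
    genomics = section(genomics, identity),
    epigenetics = section(epigenetics, identity),
    drugs = section(drugs, identity))
  if (!is.null(path))
    jsonlite::write_json(report, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA, force = TRUE)
  report
}
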