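# Synthetic multi-omic cohort generator with planted ground truth.
#
# The generator emulates the structure of a bulk HGSOC cohort: every sample
# is a non-negative mixture of k_true latent expression programs (k_true - 2
# tumour programs plus one immune and one stromal program), with three
# planted subtypes:
#   activated   - immune program elevated (immune_effect), dominant
#   CAFs        - immune program elevated AND stromal program elevated
#                 (stromal_effect), stromal program dominant
#   inactivated - baseline immune/stromal loadings, tumour program dominant
# Expression is the factor product under multiplicative log-normal noise
# (FPKM is non-negative and heteroscedastic). Methylation, mutations,
# survival, clinical covariates and broad copy number are generated
# conditionally on the planted subtype so each downstream analysis has a
# recoverable signal.

#' Configuration for the synthetic cohort generator
#'
#' Defaults are the study conditions used throughout the test-suite:
#' a 300-sample, 2,000-gene cohort with five latent programs and subtype
#' fractions mirroring an activated/CAFs/inactivated split of roughly
#' 40/20/40.
#'
#' @param n_samples,n_genes Cohort dimensions.
#' @param k_true Number of planted latent programs (>= 3: tumour programs
#'   plus one immune and one stromal program).
#' @param subtype_fractions Named proportions over
#'   `c(activated, CAFs, inactivated)`, summing to 1.
#' @param immune_effect Multiplicative loading of the immune program in
#'   immune subtypes (activated and CAFs); 1 means no immune signal.
#' @param stromal_effect Multiplicative loading of the stromal program in the
#'   CAFs subtype; 1 means no stromal signal.
#' @param noise_sd Standard deviation of the multiplicative log-normal noise
#'   (natural-log scale).
#' @param hazard_ratios Named per-subtype hazard multipliers (exponential
#'   event times; activated is the reference).
#' @param tmb_means Named per-subtype mean mutation counts per sample.
#' @param n_silenced Number of planted epigenetically silenced genes.
#' @param n_normals Number of adjacent-normal methylation samples.
#' @param cna_alter_prob Named per-subtype probability that a chromosome arm
#'   carries a broad gain or loss.
#' @param missing_rate Missing-value rate for clinical covariates.
#' @param seed Integer seed; every generator is bit-reproducible given the
#'   seed and configuration.
#' @return A validated `cohort_config` list.
#' @export
cohort_config <- function(n_samples = 300L,
                          n_genes = 2000L,
                          k_true = 5L,
                          subtype_fractions = c(activated = 0.4, CAFs = 0.2,
                                                inactivated = 0.4),
                          immune_effect = 5,
                          stromal_effect = 4.5,
                          noise_sd = 0.3,
                          hazard_ratios = c(activated = 1, CAFs = 2,
                                            inactivated = 1.4),
                          tmb_means = c(activated = 120, CAFs = 100,
                                        inactivated = 60),
                          n_silenced = 50L,
                          n_normals = 20L,
                          cna_alter_prob = c(activated = 0.15, CAFs = 0.15,
                                             inactivated = 0.35),
                          missing_rate = 0,
                          seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
              k_true = as.integer(k_true),
              subtype_fractions = subtype_fractions,
              immune_effect = immune_effect, stromal_effect = stromal_effect,
              noise_sd = noise_sd, hazard_ratios = hazard_ratios,
              tmb_means = tmb_means, n_silenced = as.integer(n_silenced),
              n_normals = as.integer(n_normals),
              cna_alter_prob = cna_alter_prob, missing_rate = missing_rate,
              seed = as.integer(seed))
  nums <- unlist(cfg[c("n_samples", "n_genes", "k_true", "subtype_fractions",
                       "immune_effect", "stromal_effect", "noise_sd",
                       "hazard_ratios", "tmb_means", "n_silenced",
                       "n_normals", "cna_alter_prob", "missing_rate", "seed")])
  if (anyNA(nums) || any(!is.finite(nums)))
    tme_config_error("cohort_config values must be finite and non-missing")
  if (cfg$n_samples < 1 || cfg$n_genes < 1)
    tme_config_error("n_samples and n_genes must be positive")
  if (cfg$k_true < 3)
    tme_config_error("k_true must be >= 3 (tumour + immune + stromal programs)")
  if (cfg$n_genes < 10 * cfg$k_true)
    tme_config_error("n_genes must be at least 10 * k_true")
  sf <- cfg$subtype_fractions
  if (!setequal(names(sf), subtype_levels) ||
      abs(sum(sf) - 1) > 1e-12 || any(sf < 0))
    tme_config_error(
      "subtype_fractions must be named activated/CAFs/inactivated and sum to 1")
  if (cfg$immune_effect <= 0 || cfg$stromal_effect <= 0)
    tme_config_error("effect sizes must be > 0")
  if (cfg$noise_sd < 0) tme_config_error("noise_sd must be >= 0")
  for (fld in c("hazard_ratios", "tmb_means", "cna_alter_prob")) {
    if (!setequal(names(cfg[[fld]]), subtype_levels))
      tme_config_error(sprintf("%s must be named by subtype", fld))
    if (any(cfg[[fld]] < 0)) tme_config_error(sprintf("%s must be >= 0", fld))
  }
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    tme_config_error("missing_rate must be in [0, 1)")
  class(cfg) <- "cohort_config"
  cfg
}

subtype_levels <- c("activated", "CAFs", "inactivated")

# Per-sample program loadings form a compartment composition (sum 1):
# immune and stromal fractions are set first (baseline fractions times the
# subtype's effect multiplier, under a small log-normal infiltration
# jitter), and the tumour programs absorb the remainder, so immune/stromal
# infiltration dilutes tumour purity exactly as in bulk tumours. In the
# CAFs subtype the expanding stroma slightly crowds the immune fraction
# (factor 1 - 0.085*(stromal_effect - 1)), keeping CAFs immune content just
# below the activated subtype as stromal content grows; at effect 1 every
# subtype shares one composition (the null).
share_base <- list(immune = 0.10, stroma = 0.12, tumour_dominant = 0.45,
                   jitter_sd = 0.12)

#' Generate a synthetic expression cohort with planted ground truth
#'
#' @param config A [cohort_config()].
#' @return A list with `cohort` (an [expression_cohort()], linear scale) and
#'   `truth` (ground-truth manifest: subtype/class per sample, gene-program
#'   map, planted factor matrices, marker gene sets, silenced genes).
#' @export
generate_expression <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_samples; m <- config$n_genes; k <- config$k_true
  n_tumour_prog <- k - 2L
  programs <- c(paste0("tumour", seq_len(n_tumour_prog)), "immune", "stroma")

  # Gene-level structure is a fixed "genome annotation", seeded only by the
  # cohort dimensions: independently generated cohorts of the same shape
  # share gene identities, program membership and magnitudes (CD8A is an
  # immune gene in every cohort), which is what makes cross-cohort
  # classifier projection meaningful. Sample-level randomness below follows
  # config$seed.
  set.seed(derive_seed(31L * m + 7L * k, "gene_annotation"))
  gene_ids <- sprintf("G%04d", seq_len(m))
  sample_ids <- sprintf("S%03d", seq_len(n))

  # gene -> program allocation: equal-size disjoint blocks, so every factor
  # carries comparable weight in the factorization
  prog_of_gene <- sample(rep(programs, length.out = m))
  names(prog_of_gene) <- gene_ids
  # immune genes split into effector genes (pure immune program: IFN /
  # cytolytic machinery, which separates activated from CAFs tumours) and
  # interface genes (chemokines, antigen presentation) that cross-load on
  # the stromal program because stroma expresses them too
  imm_genes <- gene_ids[prog_of_gene == "immune"]
  effector <- sample(imm_genes, round(0.4 * length(imm_genes)))
  # name one effector pair after the cytolytic genes so the
  # cytolytic-activity score works on synthetic data out of the box
  names(prog_of_gene)[match(effector[1:2], gene_ids)] <- c("GZMA", "PRF1")
  gene_ids[match(effector[1:2], gene_ids)] <- c("GZMA", "PRF1")
  effector[1:2] <- c("GZMA", "PRF1")
  interface <- setdiff(gene_ids[prog_of_gene == "immune"], effector)

  # FPKM-like per-gene magnitudes
  magnitude <- stats::rlnorm(m, meanlog = 1.5, sdlog = 1)
  W <- matrix(0, m, k, dimnames = list(gene_ids, programs))
  W[cbind(seq_len(m), match(prog_of_gene, programs))] <- magnitude
  W[interface, "stroma"] <- 0.5 * magnitude[match(interface, gene_ids)]

  set.seed(derive_seed(config$seed, "expression"))

  subtype <- sample(rep(subtype_levels,
                        times = round(config$subtype_fractions[subtype_levels] * n))[seq_len(n)])
  if (length(subtype) < n)  # rounding shortfall
    subtype <- c(subtype, sample(subtype_levels, n - length(subtype),
                                 replace = TRUE,
                                 prob = config$subtype_fractions[subtype_levels]))
  names(subtype) <- sample_ids
  tumour_prog <- sample(paste0("tumour", seq_len(n_tumour_prog)), n,
                        replace = TRUE)
  names(tumour_prog) <- sample_ids

  crowd <- max(0.5, 1 - 0.085 * (config$stromal_effect - 1))
  f_imm <- share_base$immune *
    ifelse(subtype == "activated", config$immune_effect,
           ifelse(subtype == "CAFs", config$immune_effect * crowd, 1)) *
    exp(stats::rnorm(n, sd = share_base$jitter_sd))
  f_str <- share_base$stroma *
    ifelse(subtype == "CAFs", config$stromal_effect, 1) *
    exp(stats::rnorm(n, sd = share_base$jitter_sd))
  over <- (f_imm + f_str) > 0.95
  rescale <- ifelse(over, 0.95 / (f_imm + f_str), 1)
  f_imm <- f_imm * rescale; f_str <- f_str * rescale
  f_tum <- 1 - f_imm - f_str

  H <- matrix(0, k, n, dimnames = list(programs, sample_ids))
  if (n_tumour_prog > 1) {
    H[seq_len(n_tumour_prog), ] <- matrix(
      rep(f_tum * (1 - share_base$tumour_dominant) / (n_tumour_prog - 1),
          each = n_tumour_prog), n_tumour_prog, n)
    H[cbind(match(tumour_prog, programs), seq_len(n))] <-
      f_tum * share_base$tumour_dominant
  } else {
    H[1, ] <- f_tum
  }
  H["immune", ] <- f_imm
  H["stroma", ] <- f_str

  X <- W %*% H
  if (config$noise_sd > 0)
    X <- X * exp(matrix(stats::rnorm(m * n, sd = config$noise_sd), m, n))

  silenced <- sample(gene_ids[startsWith(prog_of_gene, "tumour")],
                     min(config$n_silenced, sum(startsWith(prog_of_gene, "tumour"))))

  marker_sets <- list(
    immune_signature = gene_ids[prog_of_gene == "immune"],
    stromal_signature = gene_ids[prog_of_gene == "stroma"],
    effector_signature = effector)

  truth <- list(subtype = subtype,
                class = ifelse(subtype == "inactivated", "non-immune", "immune"),
                tumour_program = tumour_prog,
                gene_program = prog_of_gene,
                W_true = W, H_true = H,
                marker_sets = marker_sets,
                silenced_genes = silenced,
                config = config)
  list(cohort = expression_cohort(X, scale = "linear"), truth = truth)
}

#' Generate methylation beta matrices with planted silencing
#'
#' Planted silenced genes receive high promoter-island beta in tumours
#' (mean >= normal mean + 0.3) with per-sample variation, and the matched
#' expression rows are multiplied by a suppression factor that decreases in
#' beta, planting the expression-methylation anti-correlation. All other
#' probes are drawn from the normal-like low-beta distribution.
#'
#' @param truth Ground truth from [generate_expression()].
#' @param config The [cohort_config()] used to generate it.
#' @param cohort The matching [expression_cohort()]; its silenced-gene rows
#'   are suppressed in the returned copy.
#' @return List: `tumour_beta` and `normal_beta` (probe x sample matrices),
#'   `annotation` (probe, gene, promoter, island), and `cohort` (expression
#'   with silencing applied).
#' @export
generate_methylation <- function(truth, config, cohort) {
  set.seed(derive_seed(config$seed, "methylation"))
  gene_ids <- names(truth$gene_program)
  sample_ids <- names(truth$subtype)
  m <- length(gene_ids)

  annotation <- data.frame(
    probe = sprintf("cg%05d", seq_len(m)),
    gene = gene_ids, promoter = TRUE, island = TRUE,
    stringsAsFactors = FALSE)
  # extra probes exercising the selection rules: a promoter non-island probe
  # and a duplicate island probe for a sparse subset of genes
  extra_ni <- gene_ids[seq(1, m, by = 20)]
  extra_dup <- gene_ids[seq(2, m, by = 25)]
  annotation <- rbind(
    annotation,
    data.frame(probe = sprintf("cg9%05d", seq_along(extra_ni)),
               gene = extra_ni, promoter = TRUE, island = FALSE,
               stringsAsFactors = FALSE),
    data.frame(probe = sprintf("cg8%05d", seq_along(extra_dup)),
               gene = extra_dup, promoter = TRUE, island = TRUE,
               stringsAsFactors = FALSE))

  np <- nrow(annotation)
  n <- length(sample_ids)
  clamp01 <- function(x) pmin(pmax(x, 0), 1)

  tumour_beta <- matrix(clamp01(stats::rnorm(np * n, mean = 0.15, sd = 0.05)),
                        np, n,
                        dimnames = list(annotation$probe, sample_ids))
  normal_ids <- sprintf("N%03d", seq_len(config$n_normals))
  normal_beta <- matrix(
    clamp01(stats::rnorm(np * config$n_normals, mean = 0.15, sd = 0.05)),
    np, config$n_normals, dimnames = list(annotation$probe, normal_ids))

  vals <- cohort$values
  sil <- intersect(truth$silenced_genes, rownames(vals))
  for (g in sil) {
    b <- clamp01(stats::rnorm(n, mean = 0.62, sd = 0.2))
    on_gene <- annotation$gene == g & annotation$island
    tumour_beta[on_gene, ] <- matrix(rep(b, each = sum(on_gene)),
                                     sum(on_gene), n)
    # suppression decays exponentially in beta, planting a methylation-
    # expression anti-correlation strong enough to survive the
    # composition-driven expression variance across subtypes
    vals[g, ] <- vals[g, ] * pmax(exp(-3 * b), 0.02)
  }
  list(tumour_beta = tumour_beta, normal_beta = normal_beta,
       annotation = annotation,
       cohort = expression_cohort(vals, scale = "linear",
                                  metadata = cohort$metadata))
}

#' Synthetic 96-channel reference mutational signatures
#'
#' Three well-separated synthetic signatures over the 96 trinucleotide
#' substitution channels (columns sum to 1): S1 concentrated on C>A
#' channels, S2 on C>T, S3 spread over T>* channels. Synthetic stand-ins for
#' testing the deconvolution machinery, not COSMIC signatures.
#'
#' @return A 96 x 3 matrix with channel rownames like `ACA[C>A]`.
#' @export
synthetic_signatures <- function() {
  ch <- context_channels()
  sig <- matrix(0.25 / 96, 96, 3, dimnames = list(ch, c("S1", "S2", "S3")))
  blocks <- list(S1 = 1:16, S2 = 33:48, S3 = 49:96)
  for (s in names(blocks)) {
    w <- stats::dnorm(seq_along(blocks[[s]]),
                      mean = length(blocks[[s]]) / 2, sd = 4)
    sig[blocks[[s]], s] <- sig[blocks[[s]], s] + 0.75 * w / sum(w)
  }
  sweep(sig, 2, colSums(sig), "/")
}

#' The 96 trinucleotide substitution channel labels
#' @return Character vector like `ACA[C>A]`, ordered by substitution type
#'   then 5'/3' flanks.
#' @export
context_channels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  unlist(lapply(subs, function(s) {
    ref <- substr(s, 1, 1)
    as.vector(t(outer(bases, bases, function(f5, f3)
      paste0(f5, ref, f3, "[", s, "]"))))
  }))
}

variant_classes <- c(Missense_Mutation = 0.60, Silent = 0.20,
                     Nonsense_Mutation = 0.08, Frame_Shift_Del = 0.05,
                     Splice_Site = 0.04, In_Frame_Ins = 0.03)

#' Generate a mutation table with subtype-dependent burden and spectra
#'
#' Per-sample mutation counts are Poisson with the subtype's mean; each
#' mutation is assigned a 96-channel trinucleotide context by sampling from
#' the sample's mixed signature spectrum.
#'
#' @param truth Ground truth from [generate_expression()].
#' @param config The [cohort_config()].
#' @param signatures 96 x S reference signature matrix, columns summing to 1.
#' @param exposures S x 3 matrix of per-subtype signature mixtures (columns
#'   named by subtype, each summing to 1).
#' @return List: `mutations` (minimal MAF data.frame) and `exposures`
#'   (S x sample matrix of true per-sample exposure fractions).
#' @export
generate_mutations <- function(truth, config,
                               signatures = synthetic_signatures(),
                               exposures = NULL) {
  set.seed(derive_seed(config$seed, "mutations"))
  if (any(abs(colSums(signatures) - 1) > 1e-6))
    tme_config_error("signature matrix columns must sum to 1")
  if (is.null(exposures)) {
    exposures <- cbind(activated = c(0.1, 0.2, 0.7),
                       CAFs = c(0.2, 0.3, 0.5),
                       inactivated = c(0.6, 0.3, 0.1))
    rownames(exposures) <- colnames(signatures)
  }
  if (any(abs(colSums(exposures) - 1) > 1e-9))
    tme_config_error("exposure mixtures must sum to 1 per subtype")

  sample_ids <- names(truth$subtype)
  true_expo <- exposures[, truth$subtype, drop = FALSE]
  colnames(true_expo) <- sample_ids

  channels <- context_channels()
  rows <- lapply(sample_ids, function(s) {
    lam <- config$tmb_means[[truth$subtype[[s]]]]
    cnt <- stats::rpois(1, lam)
    if (cnt == 0) return(NULL)
    spectrum <- as.vector(signatures %*% true_expo[, s])
    ctx <- sample.int(96, cnt, replace = TRUE, prob = spectrum) - 1L
    sub <- channels[ctx + 1L]
    ref <- substr(sub, 2, 2)
    alt <- substr(sub, 7, 7)
    data.frame(Tumor_Sample_Barcode = s,
               Hugo_Symbol = sample(names(truth$gene_program), cnt,
                                    replace = TRUE),
               Variant_Classification = sample(names(variant_classes), cnt,
                                               replace = TRUE,
                                               prob = variant_classes),
               Reference_Allele = ref, Tumor_Seq_Allele2 = alt,
               context_96 = ctx, stringsAsFactors = FALSE)
  })
  mutations <- do.call(rbind, rows)
  if (is.null(mutations))
    mutations <- data.frame(Tumor_Sample_Barcode = character(0),
                            Hugo_Symbol = character(0),
                            Variant_Classification = character(0),
                            Reference_Allele = character(0),
                            Tumor_Seq_Allele2 = character(0),
                            context_96 = integer(0))
  rownames(mutations) <- NULL
  list(mutations = mutations, exposures = true_expo)
}

#' Generate survival data with subtype-specific hazards
#'
#' Exponential event times with the subtype's hazard multiplier on a
#' baseline of median 36 months for the reference subtype; independent
#' uniform censoring on (0, `cens_max`).
#'
#' @param truth Ground truth from [generate_expression()].
#' @param config The [cohort_config()].
#' @param cens_max Upper bound of the uniform censoring distribution
#'   (months).
#' @return Data.frame: sample, time (months), event (0/1), subtype,
#'   true_hazard.
#' @export
generate_survival <- function(truth, config, cens_max = 84) {
  set.seed(derive_seed(config$seed, "survival"))
  sample_ids <- names(truth$subtype)
  base_rate <- log(2) / 36
  hr <- config$hazard_ratios[truth$subtype]
  t_event <- stats::rexp(length(sample_ids), rate = base_rate * hr)
  t_cens <- stats::runif(length(sample_ids), 0, cens_max)
  data.frame(sample = sample_ids,
             time = pmax(pmin(t_event, t_cens), 1e-3),
             event = as.integer(t_event <= t_cens),
             subtype = unname(truth$subtype),
             true_hazard = unname(base_rate * hr),
             stringsAsFactors = FALSE)
}

default_clinical_covariates <- function() {
  list(
    vascular_invasion = list(
      categories = c("No", "Yes"),
      probs = rbind(activated = c(0.45, 0.55), CAFs = c(0.2, 0.8),
                    inactivated = c(0.55, 0.45))),
    residual_disease = list(
      categories = c("None", "1-20mm", ">20mm"),
      probs = rbind(activated = c(0.25, 0.55, 0.20), CAFs = c(0.10, 0.62, 0.28),
                    inactivated = c(0.28, 0.54, 0.18))),
    grade = list(
      categories = c("G1-G2", "G3-G4"),
      probs = rbind(activated = c(0.12, 0.88), CAFs = c(0.15, 0.85),
                    inactivated = c(0.12, 0.88))))
}

#' Generate a clinical covariate table
#'
#' Each covariate is drawn from subtype-conditional category probabilities;
#' entries are independently set missing at `config$missing_rate`.
#'
#' @param truth Ground truth from [generate_expression()].
#' @param config The [cohort_config()].
#' @param covariates Named list of `list(categories, probs)` where `probs`
#'   is a subtype x category matrix with rows summing to 1.
#' @return Data.frame with one row per sample.
#' @export
generate_clinical <- function(truth, config,
                              covariates = default_clinical_covariates()) {
  set.seed(derive_seed(config$seed, "clinical"))
  for (nm in names(covariates)) {
    pr <- covariates[[nm]]$probs
    if (any(abs(rowSums(pr) - 1) > 1e-9))
      tme_config_error(sprintf(
        "covariate '%s': category probabilities must sum to 1 per subtype", nm))
  }
  sample_ids <- names(truth$subtype)
  out <- data.frame(sample = sample_ids, subtype = unname(truth$subtype),
                    stringsAsFactors = FALSE)
  for (nm in names(covariates)) {
    cov <- covariates[[nm]]
    vals <- vapply(truth$subtype, function(s)
      sample(cov$categories, 1, prob = cov$probs[s, ]), character(1))
    if (config$missing_rate > 0)
      vals[stats::runif(length(vals)) < config$missing_rate] <- NA
    out[[nm]] <- unname(vals)
  }
  out
}

chromosome_arms <- function() {
  acro <- c(13, 14, 15, 21, 22)  # no broad p-arm calls
  arms <- c(paste0(setdiff(1:22, acro), "p"), paste0(1:22, "q"))
  arms[order(as.integer(sub("[pq]", "", arms)), sub("^[0-9]+", "", arms))]
}

#' Generate a broad arm-level copy-number table
#'
#' Immune subtypes carry fewer broad gains/losses (lower
#' `cna_alter_prob`), emulating the low chromosomal-aberration burden of
#' immune-infiltrated tumours.
#'
#' @param truth Ground truth from [generate_expression()].
#' @param config The [cohort_config()].
#' @return Arms x samples numeric matrix of broad values.
#' @export
generate_cna <- function(truth, config) {
  set.seed(derive_seed(config$seed, "cna"))
  arms <- chromosome_arms()
  sample_ids <- names(truth$subtype)
  vals <- matrix(stats::rnorm(length(arms) * length(sample_ids), sd = 0.05),
                 length(arms), length(sample_ids),
                 dimnames = list(arms, sample_ids))
  for (j in seq_along(sample_ids)) {
    p <- config$cna_alter_prob[[truth$subtype[[j]]]]
    altered <- stats::runif(length(arms)) < p
    sign <- sample(c(-1, 1), sum(altered), replace = TRUE)
    vals[altered, j] <- sign * (0.35 + stats::rexp(sum(altered), rate = 1 / 0.15))
  }
  vals
}

#' Write the ground-truth manifest as JSON
#'
#' The manifest is kept separate from the generated data files so planted
#' labels cannot leak into pipeline inputs.
#'
#' @param truth Ground truth from [generate_expression()].
#' @param path Output JSON path.
#' @return The path, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  manifest <- list(
    subtype = as.list(truth$subtype),
    class = as.list(truth$class),
    gene_program = as.list(truth$gene_program),
    silenced_genes = truth$silenced_genes,
    marker_sets = truth$marker_sets,
    seed = truth$config$seed)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
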