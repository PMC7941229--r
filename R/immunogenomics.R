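# Genomic correlates of the immune classes: tumour mutation burden,
# 96-channel mutation spectra with NNLS signature deconvolution, broad
# copy-number burden, and group-wise mutation enrichment.

nonsynonymous_classes <- c("Missense_Mutation", "Nonsense_Mutation",
                           "Nonstop_Mutation", "Frame_Shift_Del",
                           "Frame_Shift_Ins", "Splice_Site",
                           "In_Frame_Del", "In_Frame_Ins",
                           "Translation_Start_Site")

known_classes <- c(nonsynonymous_classes, "Silent", "Intron", "3'UTR",
                   "5'UTR", "3'Flank", "5'Flank", "RNA", "IGR")

#' Tumour mutation burden (nonsynonymous mutations per megabase)
#'
#' @param mutations Minimal MAF data.frame (see [read_maf()]).
#' @param exome_mb Callable exome size in megabases (default 38).
#' @param count_classes Variant classifications counted as nonsynonymous.
#' @param samples Optional sample universe, so mutation-free samples get
#'   TMB 0.
#' @return Named per-sample TMB vector. Unknown classifications are not
#'   counted and trigger one warning.
#' @export
compute_tmb <- function(mutations, exome_mb = 38,
                        count_classes = nonsynonymous_classes,
                        samples = NULL) {
  if (exome_mb <= 0) tme_config_error("exome_mb must be > 0")
  unknown <- setdiff(unique(mutations$Variant_Classification), known_classes)
  if (length(unknown))
    warning("unknown variant classification(s) not counted: ",
            paste(unknown, collapse = ", "))
  keep <- mutations$Variant_Classification %in% count_classes
  counts <- table(factor(mutations$Tumor_Sample_Barcode[keep],
                         levels = samples %||%
                           sort(unique(mutations$Tumor_Sample_Barcode))))
  stats::setNames(as.numeric(counts) / exome_mb, names(counts))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalized 96-channel trinucleotide mutation spectra
#'
#' @param mutations Minimal MAF data.frame with a `context_96` column
#'   (channel index 0..95).
#' @param per `"sample"` (one spectrum per sample), `"group"` (requires
#'   `groups`), or `"cohort"` (one pooled spectrum).
#' @param groups Named group label per sample (for `per = "group"`).
#' @return 96 x spectra matrix, each non-empty column summing to 1; empty
#'   spectra are zero vectors flagged by a warning.
#' @export
trinucleotide_spectrum <- function(mutations, per = c("cohort", "sample",
                                                      "group"),
                                   groups = NULL) {
  per <- match.arg(per)
  if (nrow(mutations) &&
      any(mutations$context_96 < 0 | mutations$context_96 > 95))
    tme_format_error("context_96 values must be in [0, 95]")
  key <- switch(per,
                cohort = rep("cohort", nrow(mutations)),
                sample = mutations$Tumor_Sample_Barcode,
                group = {
                  if (is.null(groups))
                    tme_config_error("per='group' requires groups")
                  as.character(groups[mutations$Tumor_Sample_Barcode])
                })
  lv <- if (per == "group" && !is.null(groups)) sort(unique(groups))
        else sort(unique(key))
  if (!length(lv)) lv <- "cohort"
  counts <- table(factor(mutations$context_96, levels = 0:95),
                  factor(key, levels = lv))
  spec <- matrix(as.numeric(counts), 96, length(lv),
                 dimnames = list(context_channels(), lv))
  tot <- colSums(spec)
  if (any(tot == 0))
    warning("empty spectrum for: ", paste(lv[tot == 0], collapse = ", "))
  spec[, tot > 0] <- sweep(spec[, tot > 0, drop = FALSE], 2, tot[tot > 0], "/")
  spec
}

#' Non-negative least squares signature deconvolution
#'
#' Solves `min || spectrum - R e ||_2` subject to `e >= 0` (Lawson-Hanson
#' NNLS) for each spectrum against the 96 x S reference matrix R; exposure
#' fractions are `e / sum(e)`.
#'
#' @param spectrum 96-vector or 96 x n matrix of normalized spectra.
#' @param reference 96 x S reference signature matrix, columns summing to 1.
#' @return List: `exposures` (S x n), `fractions` (S x n, columns summing to
#'   1 where total > 0), `residual` (per-spectrum residual norm).
#' @export
fit_signatures <- function(spectrum, reference) {
  if (is.null(dim(spectrum))) spectrum <- matrix(spectrum, ncol = 1)
  if (nrow(reference) != 96 || nrow(spectrum) != 96)
    tme_config_error("spectra and reference must have 96 channel rows")
  if (any(abs(colSums(reference) - 1) > 1e-6))
    tme_config_error("reference signature columns must sum to 1")
  S <- ncol(reference); n <- ncol(spectrum)
  expo <- matrix(0, S, n, dimnames = list(colnames(reference),
                                          colnames(spectrum)))
  resid <- numeric(n)
  for (j in seq_len(n)) {
    fit <- pracma::lsqnonneg(reference, spectrum[, j])
    expo[, j] <- fit$x
    resid[j] <- sqrt(sum((spectrum[, j] - reference %*% fit$x)^2))
  }
  tot <- colSums(expo)
  frac <- expo
  frac[, tot > 0] <- sweep(expo[, tot > 0, drop = FALSE], 2, tot[tot > 0], "/")
  list(exposures = expo, fractions = frac, residual = resid)
}

#' Microsatellite-instability proxy score
#'
#' ssGSEA enrichment of a user-supplied MSI-associated gene set. This is an
#' expression-based proxy, not a sequence-derived MSI caller; interpret
#' accordingly.
#'
#' @param cohort An [expression_cohort()].
#' @param msi_set Character vector of MSI-associated genes.
#' @param alpha ssGSEA exponent.
#' @return Named per-sample score vector.
#' @export
msi_score <- function(cohort, msi_set, alpha = 0.25) {
  ssgsea(cohort, list(MSI = msi_set), alpha = alpha, normalize = TRUE)[, "MSI"]
}

#' Broad copy-number gain and loss burden
#'
#' Fraction of chromosome arms whose broad value exceeds the amplification
#' threshold (gain) or falls below the deletion threshold (loss).
#'
#' @param broad_table Arms x samples matrix of broad GISTIC-style values.
#' @param amp_threshold Gain threshold (default 0.3).
#' @param del_threshold Loss threshold (default -0.3).
#' @return Data.frame: `sample`, `gain_burden`, `loss_burden`.
#' @export
cna_burden <- function(broad_table, amp_threshold = 0.3,
                       del_threshold = -0.3) {
  data.frame(sample = colnames(broad_table),
             gain_burden = colMeans(broad_table >= amp_threshold),
             loss_burden = colMeans(broad_table <= del_threshold),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Group-wise mutation enrichment (frequency-based)
#'
#' For every gene mutated in at least `min_count` samples, a Fisher exact
#' test on the mutated/not x group contingency table, BH-corrected over
#' tested genes. A frequency-based screen for group-associated mutated
#' genes (no background mutation modelling).
#'
#' @param mutations Minimal MAF data.frame.
#' @param labels Named group label per sample (exactly two groups).
#' @param min_count Minimum mutated samples for a gene to be tested.
#' @return Data.frame: `gene`, per-group mutated counts, `p`, `q`, ordered
#'   by p.
#' @export
group_mutation_enrichment <- function(mutations, labels, min_count = 5L) {
  groups <- sort(unique(labels))
  if (length(groups) != 2)
    tme_config_error("labels must define exactly two groups")
  samples <- names(labels)
  mut <- unique(mutations[mutations$Tumor_Sample_Barcode %in% samples,
                          c("Tumor_Sample_Barcode", "Hugo_Symbol")])
  tab <- table(mut$Hugo_Symbol)
  test_genes <- names(tab)[tab >= min_count]
  if (!length(test_genes))
    return(data.frame(gene = character(0), n_a = integer(0), n_b = integer(0),
                      p = numeric(0), q = numeric(0)))
  n_group <- table(factor(labels, levels = groups))
  res <- do.call(rbind, lapply(test_genes, function(g) {
    mutated <- unique(mut$Tumor_Sample_Barcode[mut$Hugo_Symbol == g])
    n_mut <- table(factor(labels[mutated], levels = groups))
    ct <- rbind(mutated = as.numeric(n_mut),
                wild = as.numeric(n_group - n_mut))
    data.frame(gene = g, n_a = as.numeric(n_mut)[1], n_b = as.numeric(n_mut)[2],
               p = stats::fisher.test(ct)$p.value, stringsAsFactors = FALSE)
  }))
  names(res)[2:3] <- paste0("n_", groups)
  res$q <- stats::p.adjust(res$p, method = "BH")
  res[order(res$p), ]
}
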