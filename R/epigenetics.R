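# Promoter CpG-island probe selection and calling of epigenetically
# silenced/activated genes, plus the joint expression-methylation
# intersection.
#
# A gene is called silenced when its promoter-island probe is hypermethylated
# in tumours relative to normals (delta-beta and rank-test q) AND its
# methylation anti-correlates with its expression across tumours; activated
# genes satisfy the same compound rule with all signs reversed.

#' Select one promoter CpG-island probe per gene
#'
#' Keeps probes flagged as both promoter and island; genes with multiple
#' such probes keep the probe with the highest tumour beta variance.
#'
#' @param annotation Data.frame with columns `probe`, `gene`, `promoter`,
#'   `island`.
#' @param tumour_beta Probe x sample beta matrix (used for the variance
#'   tie-break).
#' @return Data.frame `probe`, `gene` with one row per gene.
#' @export
select_promoter_island_probes <- function(annotation, tumour_beta) {
  ann <- annotation[annotation$promoter & annotation$island, , drop = FALSE]
  ann <- ann[ann$probe %in% rownames(tumour_beta), , drop = FALSE]
  if (!nrow(ann)) return(data.frame(probe = character(0), gene = character(0)))
  v <- apply(tumour_beta[ann$probe, , drop = FALSE], 1, stats::var)
  ann <- ann[order(ann$gene, -v), ]
  ann <- ann[!duplicated(ann$gene), c("probe", "gene")]
  rownames(ann) <- NULL
  ann
}

#' Call epigenetically silenced and activated genes
#'
#' Per gene (one promoter-island probe each):
#' `dbeta = mean tumour beta - mean normal beta` with a two-sided rank-test
#' p (BH q over genes), and `rho` = Spearman correlation between beta and
#' expression across matched tumours (BH q over genes). Silenced iff
#' `dbeta >= dbeta_threshold`, methylation `q < q_threshold`,
#' `rho <= -rho_threshold` and correlation `q < q_threshold`; activated with
#' all signs reversed.
#'
#' @param tumour_beta,normal_beta Probe x sample beta matrices.
#' @param annotation Probe annotation (see
#'   [select_promoter_island_probes()]).
#' @param cohort Matched [expression_cohort()] (>= 10 shared samples with
#'   `tumour_beta`).
#' @param dbeta_threshold Minimum |delta-beta| (default 0.2).
#' @param q_threshold BH q cut-off (default 0.05).
#' @param rho_threshold Minimum |Spearman rho| (default 0.3).
#' @return Data.frame per gene: `gene`, `probe`, `dbeta`, `meth_p`,
#'   `meth_q`, `rho`, `cor_p`, `cor_q`, `status` in
#'   `{silenced, activated, none}`.
#' @export
call_epigenetic_regulation <- function(tumour_beta, normal_beta, annotation,
                                       cohort, dbeta_threshold = 0.2,
                                       q_threshold = 0.05,
                                       rho_threshold = 0.3) {
  if (is.null(normal_beta) || ncol(normal_beta) == 0)
    tme_config_error("epigenetic calls require a normal-sample beta panel")
  probes <- select_promoter_island_probes(annotation, tumour_beta)
  probes <- probes[probes$gene %in% rownames(cohort$values), , drop = FALSE]
  shared <- intersect(colnames(tumour_beta), colnames(cohort$values))
  if (length(shared) < 10)
    tme_config_error("need >= 10 samples shared between methylation and expression")
  expr <- to_log2(cohort)$values[, shared, drop = FALSE]
  tb <- tumour_beta[probes$probe, shared, drop = FALSE]
  nb <- normal_beta[probes$probe, , drop = FALSE]

  meth_p <- vapply(seq_len(nrow(tb)), function(i) {
    if (stats::sd(c(tb[i, ], nb[i, ])) == 0) return(1)
    stats::wilcox.test(tb[i, ], nb[i, ], exact = FALSE)$p.value
  }, numeric(1))
  dbeta <- rowMeans(tb) - rowMeans(nb)
  rho <- vapply(seq_len(nrow(tb)), function(i) {
    e <- expr[probes$gene[i], ]
    if (stats::sd(tb[i, ]) == 0 || stats::sd(e) == 0) return(0)
    suppressWarnings(stats::cor(tb[i, ], e, method = "spearman"))
  }, numeric(1))
  cor_p <- vapply(seq_len(nrow(tb)), function(i) {
    e <- expr[probes$gene[i], ]
    if (stats::sd(tb[i, ]) == 0 || stats::sd(e) == 0) return(1)
    suppressWarnings(stats::cor.test(tb[i, ], e,
                                     method = "spearman")$p.value)
  }, numeric(1))
  meth_q <- stats::p.adjust(meth_p, method = "BH")
  cor_q <- stats::p.adjust(cor_p, method = "BH")

  silenced <- dbeta >= dbeta_threshold & meth_q < q_threshold &
    rho <= -rho_threshold & cor_q < q_threshold
  activated <- dbeta <= -dbeta_threshold & meth_q < q_threshold &
    rho >= rho_threshold & cor_q < q_threshold
  data.frame(gene = probes$gene, probe = probes$probe, dbeta = dbeta,
             meth_p = meth_p, meth_q = meth_q, rho = rho, cor_p = cor_p,
             cor_q = cor_q,
             status = ifelse(silenced, "silenced",
                             ifelse(activated, "activated", "none")),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Joint differentially-expressed / differentially-methylated gene list
#'
#' Intersection of significant genes from a differential-expression table
#' and genes with a non-none epigenetic status, with a per-gene
#' direction-consistency flag (silenced genes should be down-regulated,
#' activated genes up-regulated, in the tested contrast).
#'
#' @param de_table Output of [differential_expression()].
#' @param calls Output of [call_epigenetic_regulation()].
#' @return Data.frame: `gene`, `status`, `log2fc`, `consistent`.
#' @export
joint_deg_dmg <- function(de_table, calls) {
  sig_de <- de_table[de_table$significant, , drop = FALSE]
  sig_epi <- calls[calls$status != "none", , drop = FALSE]
  shared <- intersect(sig_de$gene, sig_epi$gene)
  if (!length(shared))
    return(data.frame(gene = character(0), status = character(0),
                      log2fc = numeric(0), consistent = logical(0)))
  lfc <- sig_de$log2fc[match(shared, sig_de$gene)]
  status <- sig_epi$status[match(shared, sig_epi$gene)]
  data.frame(gene = shared, status = status, log2fc = lfc,
             consistent = (status == "silenced" & lfc < 0) |
               (status == "activated" & lfc > 0),
             stringsAsFactors = FALSE)
}
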