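#!/usr/bin/env Rscript
# Outcome analyses: Kaplan-Meier / log-rank across the three subtypes with
# BH-adjusted pairwise contrasts, univariate Cox on the subtype hazard, and
# Fisher exact tests of the clinical covariates.

suppressPackageStartupMessages(library(tmeclass))

surv <- read.delim("results/cohort/train_survival.tsv")
clin <- read_clinical("results/cohort/train_clinical.tsv")
labels_df <- read.delim("results/discovery/labels.tsv")
sub <- setNames(labels_df$subtype, labels_df$sample)

dir.create("results/outcome", showWarnings = FALSE, recursive = TRUE)

grp <- sub[surv$sample]
lr <- km_logrank(surv$time, surv$event, grp)
cat("Three-subtype log-rank: chi-square", round(lr$chisq, 2),
    "df", lr$df, "p", signif(lr$p, 3), "\n")
write_tsv(lr$pairwise, "results/outcome/pairwise_logrank.tsv")
print(lr$pairwise)

cox <- cox_univariate(as.numeric(grp == "CAFs"), surv$time, surv$event)
cat(sprintf("CAFs vs rest: HR = %.2f (95%% CI %.2f-%.2f), p = %.3g\n",
            cox$hr, cox$ci[1], cox$ci[2], cox$p))

assoc <- do.call(rbind, lapply(
  setdiff(names(clin), c("sample", "subtype")), function(v) {
    tab <- table(clin[[v]], sub[clin$sample])
    data.frame(covariate = v, p = fisher_exact_rxc(tab))
  }))
assoc$q <- bh_adjust(assoc$p)
write_tsv(assoc, "results/outcome/clinical_associations.tsv")
print(assoc)
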