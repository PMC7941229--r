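#!/usr/bin/env Rscript
# Genomic correlates of the immune classes: TMB, cytolytic activity,
# mutation-signature exposures, broad copy-number burden and group-wise
# mutated-gene enrichment.

suppressPackageStartupMessages(library(tmeclass))

cohort <- read_expression("results/cohort/train_expression.tsv")
mutations <- read_maf("results/cohort/train_mutations.maf")
cna <- read_broad_cna("results/cohort/train_cna.tsv")
labels_df <- read.delim("results/discovery/labels.tsv")
cls <- setNames(labels_df$class, labels_df$sample)

dir.create("results/genomics", showWarnings = FALSE, recursive = TRUE)

tmb <- compute_tmb(mutations, samples = names(cls))
cyt <- cytolytic_activity(cohort)
burden <- cna_burden(cna)
tot_burden <- setNames(burden$gain_burden + burden$loss_burden, burden$sample)

report <- data.frame(
  measure = c("TMB", "CYT", "CNA burden"),
  immune_median = c(median(tmb[cls == "immune"]),
                    median(cyt[cls == "immune"]),
                    median(tot_burden[cls == "immune"])),
  nonimmune_median = c(median(tmb[cls == "non-immune"]),
                       median(cyt[cls == "non-immune"]),
                       median(tot_burden[cls == "non-immune"])),
  p = c(mann_whitney(tmb[cls == "immune"], tmb[cls == "non-immune"],
                     alternative = "greater")$p,
        mann_whitney(cyt[cls == "immune"], cyt[cls == "non-immune"],
                     alternative = "greater")$p,
        mann_whitney(tot_burden[cls == "immune"],
                     tot_burden[cls == "non-immune"],
                     alternative = "less")$p))
write_tsv(report, "results/genomics/class_contrasts.tsv")
print(report)

spec <- trinucleotide_spectrum(mutations, per = "group", groups = cls)
fit <- fit_signatures(spec, synthetic_signatures())
cat("Signature exposure fractions by class:\n")
print(round(fit$fractions, 3))
write_tsv(data.frame(signature = rownames(fit$fractions), fit$fractions),
          "results/genomics/signature_exposures.tsv")

enr <- group_mutation_enrichment(mutations, cls)
write_tsv(head(enr, 20), "results/genomics/mutation_enrichment_top20.tsv")
cat("Genes with q < 0.05 in group enrichment:", sum(enr$q < 0.05), "\n")
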