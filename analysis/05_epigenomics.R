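#!/usr/bin/env Rscript
# Promoter CpG-island probe selection, epigenetic silencing/activation
# calling, and the joint differential-expression / differential-methylation
# gene list for the immune vs non-immune contrast.

suppressPackageStartupMessages(library(tmeclass))

cohort <- read_expression("results/cohort/train_expression.tsv")
tumour_beta <- read_methylation("results/cohort/train_meth_tumour.tsv")
normal_beta <- read_methylation("results/cohort/train_meth_normal.tsv")
annotation <- read.delim("results/cohort/probe_annotation.tsv")
labels_df <- read.delim("results/discovery/labels.tsv")

dir.create("results/epigenomics", showWarnings = FALSE, recursive = TRUE)

calls <- call_epigenetic_regulation(tumour_beta, normal_beta, annotation,
                                    cohort)
write_tsv(calls, "results/epigenomics/epigenetic_calls.tsv")
cat("Silenced:", sum(calls$status == "silenced"),
    "| activated:", sum(calls$status == "activated"),
    "| promoter-island genes tested:", nrow(calls), "\n")

imm <- labels_df$sample[labels_df$class == "immune"]
non <- labels_df$sample[labels_df$class == "non-immune"]
de <- differential_expression(to_log2(cohort), imm, non, fc_threshold = 0.4)
joint <- joint_deg_dmg(de, calls)
write_tsv(joint, "results/epigenomics/joint_deg_dmg.tsv")
cat("Jointly differentially expressed and methylated genes:", nrow(joint),
    "(", sum(joint$consistent), "direction-consistent )\n")
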