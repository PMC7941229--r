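#!/usr/bin/env Rscript
# Simulate the study cohorts: a 300-sample training cohort and an
# independent validation cohort of the same design, with matched
# methylation, mutation, copy-number, survival and clinical layers.
# Outputs land under results/cohort/.

suppressPackageStartupMessages(library(tmeclass))

out <- "results/cohort"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg_train <- cohort_config(seed = 101)
cfg_valid <- cohort_config(seed = 202)

train <- generate_expression(cfg_train)
valid <- generate_expression(cfg_valid)

meth <- generate_methylation(train$truth, cfg_train, train$cohort)
train$cohort <- meth$cohort   # silencing applied to the expression layer
mut <- generate_mutations(train$truth, cfg_train)
surv <- generate_survival(train$truth, cfg_train)
clin <- generate_clinical(train$truth, cfg_train)
cna <- generate_cna(train$truth, cfg_train)

write_expression(train$cohort, file.path(out, "train_expression.tsv"))
write_expression(valid$cohort, file.path(out, "valid_expression.tsv"))
write_matrix_tsv(meth$tumour_beta, file.path(out, "train_meth_tumour.tsv"))
write_matrix_tsv(meth$normal_beta, file.path(out, "train_meth_normal.tsv"))
write_tsv(meth$annotation, file.path(out, "probe_annotation.tsv"))
write_maf(mut$mutations, file.path(out, "train_mutations.maf"))
write_tsv(surv, file.path(out, "train_survival.tsv"))
write_tsv(clin, file.path(out, "train_clinical.tsv"))
write_matrix_tsv(cna, file.path(out, "train_cna.tsv"))
write_gmt(train$truth$marker_sets, file.path(out, "marker_sets.gmt"))
write_ground_truth(train$truth, file.path(out, "train_truth.json"))
write_ground_truth(valid$truth, file.path(out, "valid_truth.json"))

cat("Simulated training cohort:", nrow(train$cohort$values), "genes x",
    ncol(train$cohort$values), "samples;",
    "planted subtype sizes:",
    paste(names(table(train$truth$subtype)),
          table(train$truth$subtype), collapse = ", "), "\n")
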