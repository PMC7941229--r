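#!/usr/bin/env Rscript
# Supervised projection of the subtype classifier into the independent
# validation cohort: NTP labels, IES/SES contrasts and the subclass map
# back to the training cohort.

suppressPackageStartupMessages(library(tmeclass))

valid <- read_expression("results/cohort/valid_expression.tsv")
train <- read_expression("results/cohort/train_expression.tsv")
markers <- read_gmt("results/cohort/marker_sets.gmt")
templates <- read_gmt("results/discovery/templates.gmt")
labels_df <- read.delim("results/discovery/labels.tsv")
train_labels <- setNames(labels_df$subtype, labels_df$sample)

val <- run_validation(valid, templates,
                      immune_set = markers$immune_signature,
                      stromal_set = markers$stromal_signature,
                      train_cohort = train, train_labels = train_labels,
                      n_resample = 500, n_perm = 499, seed = 21)

dir.create("results/validation", showWarnings = FALSE, recursive = TRUE)
write_tsv(val$ntp, "results/validation/ntp.tsv")
write_matrix_tsv(val$subclass$p_bonferroni,
                 "results/validation/subclass_p_bonferroni.tsv")

cat("Predicted subtype sizes:\n"); print(table(val$ntp$prediction))
cat("IES Kruskal-Wallis p:", signif(val$score_tests$ies_kw$p, 3),
    "| SES:", signif(val$score_tests$ses_kw$p, 3), "\n")
truth <- jsonlite::read_json("results/cohort/valid_truth.json",
                             simplifyVector = TRUE)
acc <- mean(val$ntp$prediction == unlist(truth$subtype)[val$ntp$sample])
cat("NTP accuracy against planted subtypes:", round(acc, 3), "\n")
cat("Subclass map (Bonferroni p):\n")
print(signif(val$subclass$p_bonferroni, 3))
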