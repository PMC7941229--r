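#!/usr/bin/env Rscript
# Consensus-NMF discovery on the training cohort: BIC rank selection,
# consensus factorization, IES/SES scoring, factor -> subtype
# classification, and derivation of the marker-gene templates.

suppressPackageStartupMessages(library(tmeclass))

cohort <- read_expression("results/cohort/train_expression.tsv")
markers <- read_gmt("results/cohort/marker_sets.gmt")

disc <- run_discovery(cohort,
                      immune_set = markers$immune_signature,
                      stromal_set = markers$stromal_signature,
                      k_range = 2:8, n_restarts = 8, seed = 11,
                      out_dir = "results/discovery")

cat("Chosen rank:", disc$rank$k, "\n")
cat("Cophenetic correlation:", round(disc$consensus$cophenetic, 3), "\n")
print(table(disc$labels$labels$class))
print(table(disc$labels$labels$subtype))
cat("Template sizes:",
    paste(names(disc$templates), lengths(disc$templates), collapse = ", "),
    "\n")

truth <- jsonlite::read_json("results/cohort/train_truth.json",
                             simplifyVector = TRUE)
ari <- adjusted_rand_index(disc$labels$labels$subtype,
                           unlist(truth$subtype)[disc$labels$labels$sample])
cat("ARI against planted subtypes:", round(ari, 3), "\n")
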