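#!/usr/bin/env Rscript
# Collate the per-stage outputs into one machine-readable report.

suppressPackageStartupMessages(library(tmeclass))

labels_df <- read.delim("results/discovery/labels.tsv")
ntp <- read.delim("results/validation/ntp.tsv")

report <- run_report(
  discovery = NULL,
  validation = NULL,
  survival_tests = as.list(read.delim("results/outcome/pairwise_logrank.tsv")),
  clinical_tests = as.list(read.delim("results/outcome/clinical_associations.tsv")),
  genomics = as.list(read.delim("results/genomics/class_contrasts.tsv")),
  epigenetics = list(
    n_silenced = sum(read.delim("results/epigenomics/epigenetic_calls.tsv")$status == "silenced"),
    n_joint = nrow(read.delim("results/epigenomics/joint_deg_dmg.tsv"))),
  drugs = as.list(read.delim("results/drugs/kruskal_wallis.tsv")),
  path = "results/report.json")

cat("Report sections:",
    paste(names(report), ifelse(vapply(report, identical, logical(1), "absent"),
                                "(absent)", "(present)")), "\n")
cat("Subtype sizes in discovery labels:\n")
print(table(labels_df$subtype))
cat("Validation NTP sizes:\n")
print(table(ntp$prediction))
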