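#!/usr/bin/env Rscript
# Stage 1: simulate the urine sWGS cohort.
#
# Builds the study-shaped synthetic cohort — 26 healthy controls, 27 other-CNS
# controls and 35 glioma patients (5 with a follow-up sample; 40 cancer
# samples, 93 in total) — from the calibrated group presets (medians 137, 108
# and 101 bp), and writes the fragment-length table and label table that the
# later stages consume.

suppressPackageStartupMessages(library(gliofrag))

seed <- 20260920L
dir.create("results", showWarnings = FALSE)

cohort <- simulate_cohort(cohort_spec(list(
  list(preset = "healthy_urine", n = 26),
  list(preset = "cns_urine", n = 27),
  list(preset = "glioma_urine", n = 35, followups = 5)),
  fragments_per_sample = 2e4, master_seed = seed))

write_fragment_table(cohort$samples, "results/cohort_fragments.tsv")
write.table(cohort$labels, "results/cohort_labels.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("Simulated %d samples (%d cancer, %d control) from %d patients.\n",
            nrow(cohort$labels), sum(cohort$labels$label == "cancer"),
            sum(cohort$labels$label == "control"),
            length(unique(cohort$labels$patient_id))))
cat("Wrote results/cohort_fragments.tsv and results/cohort_labels.tsv\n")
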