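#!/usr/bin/env Rscript
# Stage 3: fragmentation-feature classification.
#
# Builds the 10-feature matrix (nine 30-bp bin proportions + OSC_10bp),
# reports single-feature AUCs, runs k-means (k = 2) and PCA, and evaluates
# the four model families (LR, RF, SVM, GLMEN) under grouped 5-fold x
# 10-repeat cross-validation (50 iterations), writing per-iteration AUC and
# threshold metrics.

suppressPackageStartupMessages(library(gliofrag))

seed <- 20260920L
samples <- read_fragment_table("results/cohort_fragments.tsv")
labels <- read.delim("results/cohort_labels.tsv")

fm <- feature_matrix(samples, labels)
fm$timepoint <- labels$timepoint[match(fm$sample_id, labels$sample_id)]
write.table(fm, "results/feature_matrix.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

# single-feature screening --------------------------------------------------
feats <- setdiff(names(fm), c("sample_id", "patient_id", "label", "timepoint"))
sf <- do.call(rbind, lapply(feats, function(f) {
  r <- single_feature_auc(fm, f)
  data.frame(feature = f, auc = r$auc, direction = r$direction)
}))
sf <- sf[order(-sf$auc), ]
write.table(sf, "results/single_feature_auc.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("Single-feature AUCs (best first):\n"); print(sf, row.names = FALSE)

# unsupervised structure ----------------------------------------------------
km <- cluster_kmeans(fm, k = 2, seed = derive_seed(seed, "kmeans"))
cat("\nk-means (k = 2) cluster composition:\n")
print(km$composition, row.names = FALSE)
pca <- pca_summary(fm)
cat("\nPCA variance explained (first 3 PCs):",
    paste(round(pca$variance_explained[1:3], 3), collapse = ", "), "\n")

# grouped repeated CV, four families ----------------------------------------
cv <- run_experiment(fm,
                     specs = lapply(c("LR", "RF", "SVM", "GLMEN"), model_spec),
                     scheme = cv_scheme(seed = derive_seed(seed, "cv")))
summ <- do.call(rbind, lapply(names(cv), function(fam) {
  r <- cv[[fam]]
  write.table(cbind(iteration = seq_along(r$auc), auc = r$auc, r$metrics),
              sprintf("results/cv_metrics_%s.tsv", fam),
              sep = "\t", quote = FALSE, row.names = FALSE)
  data.frame(family = fam,
             median_auc = median(r$auc, na.rm = TRUE),
             auc_lo = min(r$auc, na.rm = TRUE),
             auc_hi = max(r$auc, na.rm = TRUE),
             median_accuracy = median(r$metrics$accuracy))
}))
write.table(summ, "results/cv_summary.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("\nGrouped repeated-CV summary (50 iterations per family):\n")
print(summ, row.names = FALSE)
cat("\nWrote results/feature_matrix.tsv, single_feature_auc.tsv, cv_metrics_*.tsv, cv_summary.tsv\n")
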