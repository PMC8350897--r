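#!/usr/bin/env Rscript
# Stage 2: fragment-size profiles of the simulated cohort.
#
# Per-group sample medians, pooled medians, the median ECDF, two-sample KS
# distances between glioma and each control group, Wilcoxon rank-sum
# comparisons of per-sample medians, P(30-60) summaries, and the 10-bp
# oscillation amplitude. Reads the tables written by stage 1.

suppressPackageStartupMessages(library(gliofrag))

samples <- read_fragment_table("results/cohort_fragments.tsv")
labels <- read.delim("results/cohort_labels.tsv")

by_group <- split(labels$sample_id, labels$group)
pool <- function(ids) unlist(lapply(samples[ids], `[[`, "lengths"),
                             use.names = FALSE)

# per-sample summaries ------------------------------------------------------
per_sample <- do.call(rbind, lapply(labels$sample_id, function(id) {
  s <- samples[[id]]
  data.frame(sample_id = id,
             median_bp = median_size(s),
             P30_60 = proportion_in_range(s, 30, 60),
             OSC_10bp = osc_amplitude(frag_histogram(s, 1, 500)))
}))
per_sample <- merge(labels, per_sample, by = "sample_id")
write.table(per_sample, "results/size_profile_per_sample.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("Group medians of per-sample median fragment size (bp):\n")
med_tab <- tapply(per_sample$median_bp, per_sample$group, median)
print(round(med_tab, 1))

# group comparisons ---------------------------------------------------------
# Two notions of distribution distance: the two-sample KS on pooled reads
# (dominated by within-sample resolution) and the sup-norm between the group
# median ECDFs (the group-level summary curves, which is what separates the
# cohorts visually).
gl <- pool(by_group$glioma_urine)
ks_h <- ks_distance(gl, pool(by_group$healthy_urine))
ks_c <- ks_distance(gl, pool(by_group$cns_urine))
grid <- 1:500
med_ecdf <- lapply(by_group, function(ids)
  median_ecdf(lapply(samples[ids], ecdf_table, grid = grid)))
d_med <- function(a, b) max(abs(med_ecdf[[a]]$F - med_ecdf[[b]]$F))
w_h <- rank_sum_p(per_sample$median_bp[per_sample$group == "glioma_urine"],
                  per_sample$median_bp[per_sample$group == "healthy_urine"])
w_c <- rank_sum_p(per_sample$median_bp[per_sample$group == "glioma_urine"],
                  per_sample$median_bp[per_sample$group == "cns_urine"])

comp <- data.frame(
  comparison = c("glioma_vs_healthy", "glioma_vs_cns"),
  ks_distance_pooled = c(ks_h$D, ks_c$D),
  ks_distance_median_ecdf = c(d_med("glioma_urine", "healthy_urine"),
                              d_med("glioma_urine", "cns_urine")),
  ranksum_p_sample_medians = c(w_h, w_c))
write.table(comp, "results/size_profile_comparisons.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("\nPooled-distribution KS distances and rank-sum tests:\n")
print(comp)

# median ECDF per group ------------------------------------------------------
ecdf_rows <- lapply(names(by_group), function(g)
  data.frame(group = g, length = grid, F = med_ecdf[[g]]$F))
write.table(do.call(rbind, ecdf_rows), "results/median_ecdf.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("\nMedian P(30-60) per group:\n")
print(round(tapply(per_sample$P30_60, per_sample$group, median), 4))
cat("\nMedian OSC_10bp per group:\n")
print(round(tapply(per_sample$OSC_10bp, per_sample$group, median), 4))
cat("\nWrote results/size_profile_per_sample.tsv, size_profile_comparisons.tsv, median_ecdf.tsv\n")
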