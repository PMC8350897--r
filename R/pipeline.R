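#' Default run configuration
#'
#' The configuration mirrors the analysis defaults throughout the package:
#' 30-bp bins over 30-300 bp, canonical oscillation positions, the 0.25
#' per-locus AF cap, 10%/1% blacklist thresholds, alpha = 0.05 and the
#' 5-fold x 10-repeat grouped CV. The default cohort shape follows the urine
#' study: 26 healthy, 27 other-CNS and 35 glioma patients with 5 follow-up
#' glioma samples (40 cancer samples, 93 total).
#'
#' @param master_seed master seed for every stage.
#' @param out_dir output directory (created if needed); NULL disables writing.
#' @return a nested config list, serialisable to YAML.
#' @export
default_config <- function(master_seed = 1L, out_dir = NULL) {
  list(
    master_seed = as.integer(master_seed),
    out_dir = out_dir,
    cohort = list(
      groups = list(
        list(preset = "healthy_urine", n = 26L),
        list(preset = "cns_urine", n = 27L),
        list(preset = "glioma_urine", n = 35L, followups = 5L)),
      fragments_per_sample = 2e4,
      w_jitter_sd = 0.03),
    imaf = list(enabled = TRUE, n_loci = 2000L, depth = 200L, tf = 1e-3,
                error_rate = 1e-5, n_controls = 20L, alpha = 0.05),
    classify = list(models = c("LR", "RF", "SVM", "GLMEN"),
                    outer_folds = 5L, inner_folds = 5L, repeats = 10L,
                    scenario = "all", features = "all"))
}

#' Read / write a run configuration as YAML
#' @param path YAML file path.
#' @param config a config list.
#' @return `read_config` returns the config list.
#' @export
read_config <- function(path) yaml::read_yaml(path)

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path); invisible(path)
}

#' Run the full synthetic-cohort pipeline
#'
#' simulate -> fragment features -> size-profile statistics -> (optional)
#' locus simulation + IMAF -> grouped CV classification -> report. The report
#' collects the group medians, the glioma-vs-healthy and glioma-vs-CNS KS
#' distances and rank-sum p-values, the P(30-60) group summaries, the IMAF
#' ledger and detection call, and the per-family AUC distributions. Fully
#' deterministic given the config's master seed.
#'
#' @param config a config list (see [default_config()]) or a YAML file path.
#' @return the report list (also written as `report.json` plus feature and
#'   metric TSVs when `out_dir` is set).
#' @export
run_pipeline <- function(config = default_config()) {
  if (is.character(config)) config <- read_config(config)
  seed <- config$master_seed

  # --- simulate -------------------------------------------------------------
  cs <- cohort_spec(config$cohort$groups,
                    fragments_per_sample = config$cohort$fragments_per_sample,
                    master_seed = seed,
                    w_jitter_sd = config$cohort$w_jitter_sd)
  cohort <- simulate_cohort(cs)

  # --- features -------------------------------------------------------------
  fm <- feature_matrix(cohort$samples, cohort$labels)
  fm$timepoint <- cohort$labels$timepoint[match(fm$sample_id,
                                                cohort$labels$sample_id)]

  # --- size-profile statistics ---------------------------------------------
  by_group <- split(cohort$labels$sample_id, cohort$labels$group)
  pool <- function(ids) unlist(lapply(cohort$samples[ids],
                                      function(s) s$lengths), use.names = FALSE)
  medians <- lapply(by_group, function(ids)
    stats::median(vapply(cohort$samples[ids],
                         function(s) median_size(s), numeric(1))))
  sizestats <- list(group_median_bp = medians)
  if (all(c("glioma_urine", "healthy_urine", "cns_urine") %in% names(by_group))) {
    gl <- pool(by_group$glioma_urine)
    he <- pool(by_group$healthy_urine)
    cn <- pool(by_group$cns_urine)
    sizestats$ks_glioma_vs_healthy <- ks_distance(gl, he)$D
    sizestats$ks_glioma_vs_cns <- ks_distance(gl, cn)$D
    med_p3060 <- function(ids) stats::median(
      vapply(cohort$samples[ids], proportion_in_range, numeric(1), 30, 60))
    sizestats$median_P30_60 <- lapply(by_group, function(ids) med_p3060(ids))
  }

  # --- IMAF -----------------------------------------------------------------
  imaf_report <- NULL
  if (isTRUE(config$imaf$enabled)) {
    ls <- locus_sim_spec(n_loci = config$imaf$n_loci, depth = config$imaf$depth,
                         tf = config$imaf$tf,
                         error_rates = c(other = config$imaf$error_rate),
                         seed = derive_seed(seed, "imaf"))
    tab <- simulate_locus_table(ls)
    ctrl <- simulate_control_matrix(ls, config$imaf$n_controls)
    bl <- blacklist_loci(ctrl)
    res <- compute_imaf(tab$loci, bl, alpha = config$imaf$alpha)
    det <- call_detection(res, tab$loci, alpha = config$imaf$alpha)
    sz <- split_sizes_by_mutation(tab$reads, retained = res$retained)
    imaf_report <- list(
      true_tf = config$imaf$tf, imaf = res$imaf,
      retained_loci = length(res$retained),
      excluded = as.list(table(res$excluded$reason)),
      detection = det,
      mutant_median_bp = if (length(sz$mutant)) median_size(sz$mutant) else NA,
      nonmutant_median_bp = if (length(sz$nonmutant)) median_size(sz$nonmutant) else NA)
  }

  # --- classification -------------------------------------------------------
  cl <- config$classify
  specs <- lapply(cl$models, function(f)
    model_spec(f, seed = derive_seed(seed, paste0("model/", f))))
  cv <- run_experiment(fm, specs,
                       cv_scheme(outer_folds = cl$outer_folds,
                                 inner_folds = cl$inner_folds,
                                 repeats = cl$repeats,
                                 seed = derive_seed(seed, "cv")),
                       scenario = cl$scenario,
                       features = cl$features)
  auc_summary <- lapply(cv, function(r)
    list(median_auc = stats::median(r$auc, na.rm = TRUE),
         range = range(r$auc, na.rm = TRUE),
         median_accuracy = stats::median(r$metrics$accuracy)))

  km <- cluster_kmeans(fm, k = 2L, seed = derive_seed(seed, "kmeans"))

  report <- list(
    n_samples = nrow(fm),
    n_cancer = sum(fm$label == "cancer"),
    n_control = sum(fm$label == "control"),
    sizestats = sizestats,
    imaf = imaf_report,
    classification = auc_summary,
    kmeans_composition = km$composition)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.table(fm, file.path(config$out_dir, "feature_matrix.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (fam in names(cv))
      utils::write.table(
        cbind(iteration = seq_along(cv[[fam]]$auc), auc = cv[[fam]]$auc,
              cv[[fam]]$metrics),
        file.path(config$out_dir, paste0("cv_metrics_", fam, ".tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(report)
}
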