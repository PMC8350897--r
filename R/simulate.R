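#' Specify a synthetic cohort
#'
#' @param groups list of group blocks, each a list with `preset` (a name from
#'   [preset_names()]), `n` (number of patients), optional `fragments`
#'   (fragments per sample, default taken from `fragments_per_sample`) and
#'   optional `followups` (number of patients in the block that contribute an
#'   additional follow-up sample, sharing their patient id) and optional
#'   `target_median` (bp) overriding the preset's published median.
#' @param fragments_per_sample default fragments per sample (2e4).
#' @param master_seed integer master seed for the whole cohort.
#' @param w_jitter_sd sd of the per-sample jitter applied to the calibrated
#'   short-fragment weight (truncated to \[0,1\]). This is the generator's
#'   between-subject variability; 0 makes every sample in a group i.i.d. from
#'   the same pmf.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(groups, fragments_per_sample = 2e4, master_seed = 1L,
                        w_jitter_sd = 0.03) {
  for (g in groups) {
    if (is.null(g$preset) || !g$preset %in% preset_names())
      stop("config error: unknown preset '", g$preset, "'")
    if (is.null(g$n) || g$n < 0) stop("config error: group needs n >= 0")
  }
  structure(list(groups = groups, fragments_per_sample = fragments_per_sample,
                 master_seed = as.integer(master_seed),
                 w_jitter_sd = w_jitter_sd),
            class = "cohort_spec")
}

#' Simulate a cohort of fragment samples
#'
#' Each patient gets a per-sample size model: the group preset calibrated to
#' its published median, with the short-fragment weight jittered per patient
#' to emulate between-subject variability. Sample-level seeds derive
#' deterministically from the master seed and the sample's identity, so the
#' cohort is byte-reproducible and insensitive to group reordering.
#' Class labels follow the preset: `glioma_*`/`*_mutant` presets are
#' "cancer", the rest "control".
#'
#' @param spec a [cohort_spec()].
#' @return list with `samples` (named list of `fragment_sample`) and `labels`
#'   (data.frame: sample_id, patient_id, group, label, timepoint).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  samples <- list(); rows <- list()
  for (g in spec$groups) {
    if (g$n == 0) next
    preset <- calibrate_preset(g$preset, target_median = g$target_median)
    nfrag <- if (!is.null(g$fragments)) g$fragments else spec$fragments_per_sample
    nfu <- if (!is.null(g$followups)) g$followups else 0L
    if (nfu > g$n) stop("config error: more followups than patients")
    for (i in seq_len(g$n)) {
      pid <- sprintf("%s_p%02d", g$preset, i)
      tps <- c("baseline", if (i <= nfu) "followup")
      for (tp in tps) {
        sid <- if (tp == "baseline") pid else paste0(pid, "_fu")
        key <- paste0("sample/", sid)
        w <- preset$model$params$w_short
        if (spec$w_jitter_sd > 0) {
          w <- with_seed(derive_seed(spec$master_seed, paste0(key, "/jitter")),
                         stats::rnorm(1, w, spec$w_jitter_sd))
          w <- min(max(w, 0), 1)
        }
        pars <- preset$model$params
        model <- build_size_model(w_short = w, short_mu = pars$short_mu,
                                  short_sigma = pars$short_sigma,
                                  mono_mu = pars$mono_mu,
                                  mono_sigma = pars$mono_sigma,
                                  osc_amp = pars$osc_amp,
                                  osc_period = pars$osc_period,
                                  osc_phase = pars$osc_phase)
        smp <- sample_fragments(model, nfrag,
                                seed = derive_seed(spec$master_seed, paste0(key, "/draw")),
                                sample_id = sid, patient_id = pid,
                                group = g$preset, fluid = "unknown",
                                timepoint = tp)
        samples[[sid]] <- smp
        rows[[sid]] <- data.frame(sample_id = sid, patient_id = pid,
                                  group = g$preset, label = preset$label,
                                  timepoint = tp, stringsAsFactors = FALSE)
      }
    }
  }
  labels <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sample_id = character(), patient_id = character(),
               group = character(), label = character(),
               timepoint = character(), stringsAsFactors = FALSE)
  rownames(labels) <- NULL
  list(samples = samples, labels = labels)
}

#' Specify a synthetic locus table
#'
#' @param n_loci number of patient-specific panel loci.
#' @param depth mean informative reads per locus (Poisson depth model).
#' @param tf true tumor fraction in \[0,1\].
#' @param rep_factors per-locus representation factors (recycled); model
#'   shared vs private clone accessibility. Default 1 for all loci.
#' @param error_rates named vector of per-trinucleotide-class background
#'   mutant-read probabilities; classes are assigned to loci round-robin.
#' @param mutant_preset,nonmutant_preset preset names for per-read fragment
#'   sizes of mutant and non-mutant reads.
#' @param seed integer seed.
#' @return a `locus_sim_spec` list.
#' @export
locus_sim_spec <- function(n_loci, depth, tf,
                           rep_factors = 1,
                           error_rates = c(other = 1e-5),
                           mutant_preset = "urine_mutant",
                           nonmutant_preset = "urine_nonmutant",
                           seed = 1L) {
  stopifnot(n_loci >= 1, depth > 0, tf >= 0, tf <= 1,
            all(rep_factors >= 0), all(error_rates >= 0))
  rep_i <- rep_len(rep_factors, n_loci)
  e_i <- rep_len(unname(error_rates), n_loci)
  if (any(tf * rep_i + e_i > 1))
    stop("parameter error: tf * rep + error rate exceeds 1 at some locus")
  structure(list(n_loci = as.integer(n_loci), depth = depth, tf = tf,
                 rep_factors = rep_i, error_rates = error_rates,
                 class_names = rep_len(names(error_rates), n_loci),
                 e_i = e_i,
                 mutant_preset = mutant_preset,
                 nonmutant_preset = nonmutant_preset,
                 seed = as.integer(seed)),
            class = "locus_sim_spec")
}

#' Simulate a locus observation table with per-read fragment sizes
#'
#' Per locus, informative reads `n_i ~ Poisson(depth)` and mutant reads
#' `m_i ~ Binomial(n_i, tf * rep_i + e_i)`. Mutant reads carry fragment
#' lengths drawn from the mutant size model, non-mutant reads from the
#' non-mutant model. The truth record keeps the generating parameters.
#'
#' @param spec a [locus_sim_spec()].
#' @return list with `loci` (data.frame: locus_id, chrom, pos, ref, alt,
#'   informative_reads, mutant_reads, trinucleotide_class, error_rate,
#'   rep_factor), `reads` (data.frame: locus_id, length, is_mutant) and
#'   `truth` (generating parameters).
#' @export
simulate_locus_table <- function(spec) {
  stopifnot(inherits(spec, "locus_sim_spec"))
  mut_model <- calibrate_preset(spec$mutant_preset)$model
  non_model <- calibrate_preset(spec$nonmutant_preset)$model
  L <- spec$n_loci
  p_i <- spec$tf * spec$rep_factors + spec$e_i

  counts <- with_seed(derive_seed(spec$seed, "locus/counts"), {
    n_i <- stats::rpois(L, spec$depth)
    m_i <- stats::rbinom(L, n_i, p_i)
    list(n_i = n_i, m_i = m_i)
  })
  n_i <- counts$n_i; m_i <- counts$m_i

  mut_len <- if (sum(m_i) > 0)
    sample_fragments(mut_model, sum(m_i),
                     seed = derive_seed(spec$seed, "locus/mutlen"))$lengths
  else integer(0)
  non_len <- if (sum(n_i - m_i) > 0)
    sample_fragments(non_model, sum(n_i - m_i),
                     seed = derive_seed(spec$seed, "locus/nonlen"))$lengths
  else integer(0)

  loci <- data.frame(
    locus_id = sprintf("L%05d", seq_len(L)),
    chrom = "chr1", pos = 1000L * seq_len(L),
    ref = "A", alt = "T",
    informative_reads = n_i, mutant_reads = m_i,
    trinucleotide_class = spec$class_names,
    error_rate = spec$e_i, rep_factor = spec$rep_factors,
    stringsAsFactors = FALSE)

  reads <- data.frame(
    locus_id = c(rep(loci$locus_id, m_i), rep(loci$locus_id, n_i - m_i)),
    length = c(mut_len, non_len),
    is_mutant = rep(c(TRUE, FALSE), c(sum(m_i), sum(n_i - m_i))),
    stringsAsFactors = FALSE)

  list(loci = loci, reads = reads,
       truth = list(tf = spec$tf, depth = spec$depth,
                    rep_factors = spec$rep_factors, e_i = spec$e_i,
                    seed = spec$seed,
                    mutant_preset = spec$mutant_preset,
                    nonmutant_preset = spec$nonmutant_preset))
}

#' Simulate a control-cohort locus matrix
#'
#' Draws `n_controls` independent tumor-fraction-zero samples over the same
#' loci, giving the (mutant, informative) count matrix used by
#' [blacklist_loci()]. Individual loci can be made systematically noisy via
#' `noisy_error_rates` (a per-locus error-rate vector overriding the spec's).
#'
#' @param spec a [locus_sim_spec()]; its `tf` is ignored (controls are tf=0).
#' @param n_controls number of control samples.
#' @param noisy_error_rates optional per-locus error-rate vector (length
#'   `n_loci`) replacing the spec's class rates.
#' @return list of matrices `mutant` and `informative` (loci x controls), with
#'   locus ids as rownames.
#' @export
simulate_control_matrix <- function(spec, n_controls,
                                    noisy_error_rates = NULL) {
  stopifnot(inherits(spec, "locus_sim_spec"), n_controls >= 1)
  e_i <- if (is.null(noisy_error_rates)) spec$e_i
         else rep_len(noisy_error_rates, spec$n_loci)
  L <- spec$n_loci
  res <- with_seed(derive_seed(spec$seed, "controls"), {
    n <- matrix(stats::rpois(L * n_controls, spec$depth), nrow = L)
    m <- matrix(stats::rbinom(L * n_controls, as.vector(n), rep(e_i, n_controls)),
                nrow = L)
    list(n = n, m = m)
  })
  ids <- sprintf("L%05d", seq_len(L))
  rownames(res$n) <- rownames(res$m) <- ids
  list(mutant = res$m, informative = res$n)
}
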