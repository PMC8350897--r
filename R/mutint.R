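#' Filter tumor tissue variant calls
#'
#' Post-calling filters for patient-specific somatic variants from
#' multi-region tumor exome sequencing. A call PASSes iff:
#' base quality (PHRED) >= 30, at least 4 tumor mutant reads with at least
#' one on each strand, zero germline mutant reads, and germline depth >= 10.
#'
#' @param calls data.frame with columns chrom, pos, ref, alt,
#'   tumor_mutant_reads, tumor_mutant_fwd, tumor_mutant_rev,
#'   germline_mutant_reads, germline_depth, base_quality_phred.
#' @return the input with logical `pass` and character `fail_reason`
#'   ("" when passing; semicolon-joined reasons otherwise).
#' @export
filter_tissue_variants <- function(calls) {
  need <- c("tumor_mutant_reads", "tumor_mutant_fwd", "tumor_mutant_rev",
            "germline_mutant_reads", "germline_depth", "base_quality_phred")
  miss <- setdiff(need, names(calls))
  if (length(miss))
    stop("input error: missing column(s) ", paste(miss, collapse = ", "))
  if (any(calls$tumor_mutant_fwd + calls$tumor_mutant_rev !=
            calls$tumor_mutant_reads))
    stop("input error: strand counts do not sum to tumor_mutant_reads")
  reasons <- list(
    base_quality = calls$base_quality_phred < 30,
    mutant_reads = calls$tumor_mutant_reads < 4,
    strand       = calls$tumor_mutant_fwd < 1 | calls$tumor_mutant_rev < 1,
    germline     = calls$germline_mutant_reads > 0,
    germline_depth = calls$germline_depth < 10)
  fail <- Reduce(`|`, reasons)
  rs <- apply(do.call(cbind, reasons), 1L, function(r)
    paste(names(reasons)[r], collapse = ";"))
  calls$pass <- !fail
  calls$fail_reason <- rs
  calls
}

#' Classify panel loci as shared, private or merged-only
#'
#' A locus called in >= 2 tumor subparts is `shared`, in exactly one subpart
#' `private`, and a locus only recovered when reads from all subparts are
#' pooled before calling is `merged_only`.
#'
#' @param per_subpart_calls named list (one element per subpart) of character
#'   vectors of locus keys ("chrom:pos:ref:alt").
#' @param merged_calls character vector of locus keys from merged calling.
#' @return data.frame(locus, sharing, n_subparts), deduplicated by locus.
#' @export
classify_sharing <- function(per_subpart_calls, merged_calls) {
  if (length(per_subpart_calls) < 2L)
    stop("input error: need calls from >= 2 tumor subparts")
  counts <- table(unlist(lapply(per_subpart_calls, unique)))
  sub_loci <- names(counts)
  all_loci <- union(sub_loci, merged_calls)
  if (length(all_loci) == 0L)
    return(data.frame(locus = character(), sharing = character(),
                      n_subparts = integer(), stringsAsFactors = FALSE))
  n_sub <- as.integer(counts[match(all_loci, sub_loci)])
  n_sub[is.na(n_sub)] <- 0L
  sharing <- ifelse(n_sub >= 2L, "shared",
                    ifelse(n_sub == 1L, "private", "merged_only"))
  data.frame(locus = all_loci, sharing = sharing, n_subparts = n_sub,
             stringsAsFactors = FALSE)
}

#' Blacklist noisy panel loci from a control matrix
#'
#' A locus is blacklisted iff more than 10% of control samples show signal
#' (>= 1 mutant read) at it, or its mean control allele fraction (mean of
#' per-sample m/n over samples with n > 0) exceeds 1%.
#'
#' @param control_matrix list with matrices `mutant` and `informative`
#'   (loci x control samples, shared rownames).
#' @param max_signal_fraction signal-fraction threshold (default 0.10).
#' @param max_mean_af mean-AF threshold (default 0.01).
#' @return data.frame(locus, signal_fraction, mean_af, blacklisted, reason);
#'   loci with zero depth in every control are dropped with a warning.
#' @export
blacklist_loci <- function(control_matrix, max_signal_fraction = 0.10,
                           max_mean_af = 0.01) {
  m <- control_matrix$mutant; n <- control_matrix$informative
  stopifnot(is.matrix(m), is.matrix(n), all(dim(m) == dim(n)))
  if (ncol(m) < 1L) stop("input error: need >= 1 control sample")
  if (any(m > n)) stop("input error: mutant reads exceed informative reads")
  all_zero <- rowSums(n) == 0
  if (any(all_zero)) {
    warning(sum(all_zero), " locus/loci with zero depth in all controls excluded")
    m <- m[!all_zero, , drop = FALSE]; n <- n[!all_zero, , drop = FALSE]
  }
  sig_frac <- rowMeans(m >= 1)
  af <- m / n; af[n == 0] <- NA
  mean_af <- rowMeans(af, na.rm = TRUE)
  bl_sig <- sig_frac > max_signal_fraction
  bl_af <- mean_af > max_mean_af
  reason <- ifelse(bl_sig & bl_af, "signal_fraction;mean_af",
                   ifelse(bl_sig, "signal_fraction",
                          ifelse(bl_af, "mean_af", "")))
  data.frame(locus = rownames(m), signal_fraction = sig_frac,
             mean_af = mean_af, blacklisted = bl_sig | bl_af,
             reason = reason, row.names = NULL, stringsAsFactors = FALSE)
}

#' Upper binomial tail probability P(X >= m)
#'
#' Exact and numerically stable for very small success probabilities
#' (computed on the upper tail directly, not via 1 - CDF).
#'
#' @param m,n counts with 0 <= m <= n.
#' @param p success probability in \[0,1\].
#' @return P(X >= m) for X ~ Binomial(n, p).
#' @export
binomial_tail <- function(m, n, p) {
  if (any(m < 0 | m > n) || any(p < 0 | p > 1))
    stop("input error: need 0 <= m <= n and 0 <= p <= 1")
  ifelse(m == 0, 1, stats::pbinom(m - 1, n, p, lower.tail = FALSE))
}

#' Integrated mutant allele fraction with outlier suppression
#'
#' IMAF is the pooled mutant fraction `sum(m_i) / sum(n_i)` over the
#' patient-specific panel loci, after three exclusion steps:
#' \enumerate{
#'   \item blacklisted loci are dropped;
#'   \item loci with per-locus allele fraction `m/n >= 0.25` are dropped
#'     (such fractions are implausible for body-fluid ctDNA and usually
#'     indicate mis-genotyped SNPs);
#'   \item iteratively, each remaining locus is tested with the exact upper
#'     binomial tail `P(X >= m | n, IMAF)`; loci whose Bonferroni-corrected
#'     p-value (multiplier = number of loci entering this stage) falls below
#'     `alpha` are excluded as outliers and IMAF recomputed, to a fixpoint
#'     (at most `max_iter` passes; `max_iter = 1` gives the single-pass
#'     variant).
#' }
#'
#' @param observations data.frame with columns locus_id, informative_reads,
#'   mutant_reads and optionally error_rate (needed by [call_detection()]).
#' @param blacklist character vector of blacklisted locus ids (or the output
#'   of [blacklist_loci()], whose blacklisted rows are used).
#' @param alpha Bonferroni-corrected significance level (default 0.05).
#' @param max_iter maximum outlier-suppression passes (default 10).
#' @return object of class `imaf_result`: list(imaf, retained, excluded
#'   (data.frame locus_id + reason), total_mutant, total_informative,
#'   iterations, undefined flag).
#' @export
compute_imaf <- function(observations, blacklist = character(),
                         alpha = 0.05, max_iter = 10L) {
  obs <- observations
  need <- c("locus_id", "informative_reads", "mutant_reads")
  miss <- setdiff(need, names(obs))
  if (length(miss))
    stop("input error: missing column(s) ", paste(miss, collapse = ", "))
  if (nrow(obs) < 1L) stop("input error: need >= 1 locus observation")
  if (any(obs$mutant_reads > obs$informative_reads))
    stop("input error: mutant reads exceed informative reads")
  if (is.data.frame(blacklist))
    blacklist <- blacklist$locus[blacklist$blacklisted]

  excluded <- data.frame(locus_id = character(), reason = character(),
                         stringsAsFactors = FALSE)
  drop <- function(ids, reason) {
    if (length(ids))
      excluded <<- rbind(excluded,
                         data.frame(locus_id = ids, reason = reason,
                                    stringsAsFactors = FALSE))
  }

  bl <- obs$locus_id %in% blacklist
  drop(obs$locus_id[bl], "blacklist")
  obs <- obs[!bl, , drop = FALSE]

  af_hi <- obs$informative_reads > 0 &
    obs$mutant_reads / obs$informative_reads >= 0.25
  drop(obs$locus_id[af_hi], "af_ge_0.25")
  obs <- obs[!af_hi, , drop = FALSE]

  L <- nrow(obs)   # Bonferroni multiplier: loci interrogated for this sample
  iters <- 0L
  repeat {
    tot_n <- sum(obs$informative_reads)
    if (tot_n == 0) break
    imaf <- sum(obs$mutant_reads) / tot_n
    if (iters >= max_iter || nrow(obs) == 0L) break
    pv <- binomial_tail(obs$mutant_reads, obs$informative_reads, imaf)
    out <- pv * L < alpha & obs$mutant_reads > 0
    iters <- iters + 1L
    if (!any(out)) break
    drop(obs$locus_id[out], "outlier")
    obs <- obs[!out, , drop = FALSE]
  }

  tot_n <- sum(obs$informative_reads)
  undefined <- nrow(obs) == 0L || tot_n == 0
  structure(list(
    imaf = if (undefined) NA_real_ else sum(obs$mutant_reads) / tot_n,
    retained = obs$locus_id,
    excluded = excluded,
    total_mutant = sum(obs$mutant_reads),
    total_informative = tot_n,
    iterations = iters,
    undefined = undefined,
    retained_obs = obs),
    class = "imaf_result")
}

#' @export
print.imaf_result <- function(x, ...) {
  cat(sprintf("imaf_result: IMAF = %s (%d/%d reads over %d retained loci; %d excluded; %d outlier pass(es))\n",
              format(x$imaf), x$total_mutant, x$total_informative,
              length(x$retained), nrow(x$excluded), x$iterations))
  invisible(x)
}

#' Pooled-binomial ctDNA detection call
#'
#' A deliberately simple detection rule (method tag "pooled-binomial", not a
#' re-implementation of the INVAR likelihood machinery): one-sided exact
#' binomial test of the pooled mutant count against the depth-weighted mean
#' background error rate of the retained loci. Detected iff at least one
#' mutant read was seen and p < `alpha`.
#'
#' @param imaf_result an [compute_imaf()] result.
#' @param observations the observation data.frame, which must carry an
#'   `error_rate` column (per-locus background rates are inputs here, not
#'   estimated).
#' @param alpha significance level (default 0.05).
#' @return list(detected, p, p0, method = "pooled-binomial").
#' @export
call_detection <- function(imaf_result, observations, alpha = 0.05) {
  stopifnot(inherits(imaf_result, "imaf_result"))
  if (is.null(observations$error_rate))
    stop("config error: observations lack an error_rate column")
  keep <- observations$locus_id %in% imaf_result$retained
  obs <- observations[keep, , drop = FALSE]
  tot_n <- sum(obs$informative_reads)
  tot_m <- sum(obs$mutant_reads)
  if (tot_n == 0 || tot_m == 0)
    return(list(detected = FALSE, p = 1, p0 = NA_real_,
                method = "pooled-binomial"))
  p0 <- sum(obs$informative_reads * obs$error_rate) / tot_n
  p <- binomial_tail(tot_m, tot_n, p0)
  list(detected = tot_m >= 1 && p < alpha, p = p, p0 = p0,
       method = "pooled-binomial")
}

#' Split per-read fragment sizes by mutation status
#'
#' Partitions the per-read records of a locus table into mutant and
#' non-mutant fragment samples (optionally restricted to retained loci), for
#' the mutant vs non-mutant size comparison.
#'
#' @param reads data.frame with columns locus_id, length, is_mutant.
#' @param retained optional locus ids to restrict to.
#' @param sample_id base id for the two output samples.
#' @return list(mutant, nonmutant): two `fragment_sample`s (possibly empty,
#'   flagged via their zero length).
#' @export
split_sizes_by_mutation <- function(reads, retained = NULL,
                                    sample_id = "sample") {
  need <- c("locus_id", "length", "is_mutant")
  if (!all(need %in% names(reads)))
    stop("input error: per-read records need columns ",
         paste(need, collapse = ", "))
  if (!is.null(retained)) reads <- reads[reads$locus_id %in% retained, ]
  list(
    mutant = fragment_sample(reads$length[reads$is_mutant],
                             sample_id = paste0(sample_id, "_mutant")),
    nonmutant = fragment_sample(reads$length[!reads$is_mutant],
                                sample_id = paste0(sample_id, "_nonmutant")))
}
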