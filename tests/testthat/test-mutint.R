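make_calls <- function(...) {
  base <- data.frame(chrom = "chr1", pos = 100L, ref = "A", alt = "T",
                     tumor_depth = 50L, tumor_mutant_reads = 4L,
                     tumor_mutant_fwd = 3L, tumor_mutant_rev = 1L,
                     germline_depth = 15L, germline_mutant_reads = 0L,
                     base_quality_phred = 35)
  mods <- list(...)
  out <- base[rep(1L, max(1L, length(mods))), ]
  for (i in seq_along(mods)) out[i, names(mods[[i]])] <- mods[[i]]
  rownames(out) <- NULL
  out
}

test_that("tissue variant filters apply the published rule set", {
  res <- filter_tissue_variants(make_calls(
    list(),                                                    # clean PASS
    list(tumor_mutant_fwd = 4L, tumor_mutant_rev = 0L),        # strand fail
    list(tumor_mutant_reads = 6L, tumor_mutant_fwd = 5L,
         germline_mutant_reads = 1L, germline_depth = 20L),    # germline fail
    list(base_quality_phred = 25),                             # quality fail
    list(tumor_mutant_reads = 3L, tumor_mutant_fwd = 2L),      # support fail
    list(germline_depth = 8L)))                                # coverage fail
  expect_equal(res$pass, c(TRUE, rep(FALSE, 5)))
  expect_match(res$fail_reason[2], "strand")
  expect_match(res$fail_reason[3], "germline")
  expect_match(res$fail_reason[4], "base_quality")
  expect_match(res$fail_reason[5], "mutant_reads")
  expect_match(res$fail_reason[6], "germline_depth")

  nostrand <- make_calls(list())
  nostrand$tumor_mutant_fwd <- NULL
  expect_error(filter_tissue_variants(nostrand), "missing column")
  bad <- make_calls(list(tumor_mutant_fwd = 1L, tumor_mutant_rev = 1L))
  expect_error(filter_tissue_variants(bad), "strand counts")
})

test_that("sharing classification distinguishes shared/private/merged-only", {
  subparts <- list(S1 = c("1:100:A:T", "1:200:C:G"),
                   S2 = c("1:300:G:A"),
                   S3 = c("1:100:A:T"))
  merged <- c("1:100:A:T", "1:300:G:A", "1:400:T:C")
  res <- classify_sharing(subparts, merged)
  lab <- stats::setNames(res$sharing, res$locus)
  expect_equal(lab[["1:100:A:T"]], "shared")     # in S1 and S3
  expect_equal(lab[["1:200:C:G"]], "private")    # S1 only
  expect_equal(lab[["1:300:G:A"]], "private")    # S2 only
  expect_equal(lab[["1:400:T:C"]], "merged_only")
  expect_equal(anyDuplicated(res$locus), 0)
  expect_error(classify_sharing(list(S1 = "x"), character()), ">= 2")
})

test_that("blacklisting applies the 10% signal and 1% mean-AF rules", {
  mk <- function(m, n) list(
    mutant = matrix(m, nrow = 1, dimnames = list("L1", NULL)),
    informative = matrix(n, nrow = 1, dimnames = list("L1", NULL)))

  # signal in 2/10 controls -> blacklisted (0.2 > 0.1)
  b1 <- blacklist_loci(mk(c(1, 1, rep(0, 8)), rep(1000, 10)))
  expect_true(b1$blacklisted)
  expect_match(b1$reason, "signal_fraction")

  # signal in 1/10, mean AF 0.002 -> kept
  b2 <- blacklist_loci(mk(c(20, rep(0, 9)), rep(1000, 10)))
  expect_false(b2$blacklisted)

  # low signal fraction but mean AF 2% -> blacklisted by AF rule
  b3 <- blacklist_loci(mk(c(400, rep(0, 19)), rep(1000, 20)))
  expect_true(b3$blacklisted)
  expect_equal(b3$reason, "mean_af")

  # pure function of the matrix: reapplication is identical
  cm <- list(mutant = matrix(rpois(40, 0.3), 10,
                             dimnames = list(sprintf("L%d", 1:10), NULL)),
             informative = matrix(1000L, 10, 4,
                                  dimnames = list(sprintf("L%d", 1:10), NULL)))
  expect_identical(blacklist_loci(cm), blacklist_loci(cm))

  # all-zero-depth locus excluded with a warning
  cm0 <- list(mutant = matrix(0L, 2, 3, dimnames = list(c("L1", "L2"), NULL)),
              informative = matrix(c(0L, 0L, 0L, 10L, 10L, 10L), 2,
                                   byrow = TRUE,
                                   dimnames = list(c("L1", "L2"), NULL)))
  expect_warning(b0 <- blacklist_loci(cm0), "zero depth")
  expect_equal(b0$locus, "L2")
})

test_that("binomial upper tail is exact against direct pmf summation", {
  expect_equal(binomial_tail(0, 100, 0.01), 1)
  expect_equal(binomial_tail(1, 2, 0.5), 0.75)
  cases <- expand.grid(n = c(10, 500, 10000), p = c(1e-8, 1e-5, 0.01, 0.5))
  for (i in seq_len(nrow(cases))) {
    n <- cases$n[i]; p <- cases$p[i]
    for (m in unique(pmin(n, c(0, 1, 2, 5, round(n / 2))))) {
      oracle <- sum(stats::dbinom(m:n, n, p))
      got <- binomial_tail(m, n, p)
      expect_equal(got, oracle, tolerance = 1e-12)
    }
  }
  expect_error(binomial_tail(5, 2, 0.5), "input error")
  expect_error(binomial_tail(1, 2, 1.5), "input error")
})

test_that("IMAF: pooled ratio, AF cap, blacklist and the exclusion ledger", {
  toy <- data.frame(locus_id = c("a", "b", "c"),
                    informative_reads = c(1000L, 1000L, 500L),
                    mutant_reads = c(2L, 0L, 1L))
  res <- compute_imaf(toy)
  expect_equal(res$imaf, 1.2e-3)
  expect_equal(length(res$retained) + nrow(res$excluded), nrow(toy))

  # a high-AF locus among low-AF loci is dropped by the 0.25 cap
  hi <- rbind(toy, data.frame(locus_id = "d", informative_reads = 10L,
                              mutant_reads = 3L))
  res2 <- compute_imaf(hi)
  expect_equal(res2$excluded$reason[res2$excluded$locus_id == "d"],
               "af_ge_0.25")
  expect_equal(res2$imaf, 1.2e-3)

  # blacklisted loci leave the calculation before anything else
  res3 <- compute_imaf(toy, blacklist = "a")
  expect_equal(res3$imaf, 1 / 1500)
  expect_equal(res3$excluded$reason, "blacklist")

  # undefined IMAF flagged when nothing remains
  res4 <- compute_imaf(toy[1, , drop = FALSE], blacklist = "a")
  expect_true(res4$undefined)
  expect_true(is.na(res4$imaf))
})

test_that("outlier suppression removes a spiked locus and spares zero-mutant loci", {
  sp <- locus_sim_spec(999, 250, 1e-4, error_rates = c(x = 0), seed = 21)
  tab <- simulate_locus_table(sp)
  obs <- rbind(tab$loci[, c("locus_id", "informative_reads", "mutant_reads")],
               data.frame(locus_id = "SPIKE", informative_reads = 250L,
                          mutant_reads = 50L))
  res <- compute_imaf(obs)
  expect_true("SPIKE" %in% res$excluded$locus_id)
  expect_equal(res$excluded$reason[res$excluded$locus_id == "SPIKE"],
               "outlier")
  # zero-mutant loci are never excluded as outliers
  zero_ids <- obs$locus_id[obs$mutant_reads == 0]
  expect_false(any(zero_ids %in% res$excluded$locus_id))
  # recovered IMAF close to the true tf
  N <- res$total_informative
  expect_lt(abs(res$imaf - 1e-4), 3 * sqrt(1e-4 * (1 - 1e-4) / N))
  expect_equal(length(res$retained) + nrow(res$excluded), nrow(obs))
})

test_that("adding a zero-mutant locus can only decrease or preserve IMAF", {
  toy <- data.frame(locus_id = c("a", "b"),
                    informative_reads = c(500L, 800L),
                    mutant_reads = c(3L, 1L))
  base <- compute_imaf(toy)$imaf
  more <- rbind(toy, data.frame(locus_id = "z", informative_reads = 600L,
                                mutant_reads = 0L))
  expect_lte(compute_imaf(more)$imaf, base)
})

test_that("single-pass mode stops after one exclusion round", {
  obs <- data.frame(locus_id = sprintf("L%03d", 1:200),
                    informative_reads = 1000L,
                    mutant_reads = c(rep(0L, 196), 1L, 1L, 30L, 60L))
  multi <- compute_imaf(obs)
  single <- compute_imaf(obs, max_iter = 1L)
  expect_lte(single$iterations, 1L)
  expect_gte(multi$iterations, single$iterations)
  expect_true(all(single$excluded$locus_id %in%
                    c(multi$excluded$locus_id)))
})

test_that("pooled-binomial detection calls behave at the boundaries", {
  obs <- data.frame(locus_id = c("a", "b"),
                    informative_reads = c(1000L, 1000L),
                    mutant_reads = c(0L, 0L),
                    error_rate = c(1e-5, 1e-5))
  res <- compute_imaf(obs)
  det <- call_detection(res, obs)
  expect_false(det$detected)
  expect_equal(det$p, 1)
  expect_equal(det$method, "pooled-binomial")

  # e = 1e-5 everywhere, sum n = 1e6, sum m = 100 -> detected
  obs2 <- data.frame(locus_id = sprintf("L%d", 1:100),
                     informative_reads = 10000L,
                     mutant_reads = 1L,
                     error_rate = 1e-5)
  res2 <- compute_imaf(obs2)
  det2 <- call_detection(res2, obs2)
  expect_true(det2$detected)
  expect_equal(det2$p, binomial_tail(100, 1e6, 1e-5))

  expect_error(call_detection(res2, obs2[, 1:3]), "error_rate")
})

test_that("per-read sizes split by mutation status with the expected medians", {
  reads <- data.frame(locus_id = rep("L1", 4),
                      length = c(90L, 110L, 160L, 170L),
                      is_mutant = c(TRUE, TRUE, FALSE, FALSE))
  sz <- split_sizes_by_mutation(reads)
  expect_equal(median_size(sz$mutant), 100)
  expect_equal(median_size(sz$nonmutant), 165)

  none <- split_sizes_by_mutation(reads[!reads$is_mutant, ])
  expect_length(none$mutant$lengths, 0)
  expect_error(split_sizes_by_mutation(data.frame(length = 1)), "per-read")

  # synthetic urine table reproduces the mutant/non-mutant medians; the
  # mutant read count (~12k here) keeps the sample-median sd near 1 bp
  sp <- locus_sim_spec(2000, 600, 0.01, error_rates = c(x = 1e-5),
                       mutant_preset = "urine_mutant",
                       nonmutant_preset = "urine_nonmutant", seed = 8)
  tab <- simulate_locus_table(sp)
  sz2 <- split_sizes_by_mutation(tab$reads)
  expect_lte(abs(median_size(sz2$mutant) - 101), 3)
  expect_lte(abs(median_size(sz2$nonmutant) - 133), 2)
})
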