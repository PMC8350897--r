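test_that("histogram heights equal a direct tally over all fragments", {
  s <- fragment_sample(c(100, 100, 200, 300))
  h <- frag_histogram(s, 1, 500)
  expect_equal(h$height[h$grid == 100], 0.5)
  expect_equal(h$height[h$grid == 200], 0.25)
  expect_equal(sum(h$height), 1)

  # truncated grid: total < 1, denominator still all fragments
  ht <- frag_histogram(s, 1, 250)
  expect_equal(sum(ht$height), 0.75)

  # brute-force tally oracle on random samples
  for (seed in 1:5) {
    lens <- gliofrag:::with_seed(seed, sample(20:400, 300, replace = TRUE))
    h <- frag_histogram(lens, 20, 400)
    oracle <- vapply(h$grid, function(x) sum(lens == x) / length(lens),
                     numeric(1))
    expect_equal(h$height, oracle)
  }
  expect_error(frag_histogram(integer(0)), "empty sample")
})

test_that("median and range proportions follow their definitions", {
  expect_equal(median_size(c(1, 2, 3)), 2)
  expect_equal(median_size(c(100, 200)), 150)
  expect_error(median_size(integer(0)), "empty")

  expect_equal(proportion_in_range(c(30, 60, 61), 30, 60), 2 / 3)
  expect_equal(proportion_in_range(c(30, 60, 61), 1, 500), 1)
  expect_error(proportion_in_range(c(1, 2), 10, 5), "lo > hi")

  # calibrated glioma urine is enriched in 30-60 bp vs healthy urine
  gl <- sample_fragments(calibrate_preset("glioma_urine"), 1e5, seed = 2)
  he <- sample_fragments(calibrate_preset("healthy_urine"), 1e5, seed = 2)
  expect_gt(proportion_in_range(gl, 30, 60), proportion_in_range(he, 30, 60))
})

test_that("nine bins partition 30-300 bp with inclusive printed bounds", {
  expect_equal(unname(bin_proportions(rep(45, 10))),
               c(1, rep(0, 8)))
  p <- bin_proportions(c(60, 61))
  expect_equal(unname(p[c("P30_60", "P61_90")]), c(0.5, 0.5))

  for (seed in 1:10) {
    lens <- gliofrag:::with_seed(seed, sample(1:500, 200, replace = TRUE))
    expect_equal(sum(bin_proportions(lens)),
                 proportion_in_range(lens, 30, 300))
  }
})

test_that("ECDFs and their pointwise median behave as order statistics", {
  e <- ecdf_table(c(1, 2, 3), grid = 1:5)
  expect_equal(e$F[2], 2 / 3)
  expect_true(all(diff(e$F) >= 0))
  expect_equal(e$F[5], 1)

  one <- ecdf_table(c(5, 10), grid = 1:20)
  expect_equal(median_ecdf(list(one))$F, one$F)

  # three tiny step functions: median at a probe point is the middle value
  es <- lapply(list(c(2, 4), c(3, 9), c(8, 10)), ecdf_table, grid = 1:10)
  m <- median_ecdf(es)
  # at x = 4: F values are 1, 0.5, 0 -> middle 0.5 (hand-computed)
  expect_equal(m$F[4], 0.5)
  # bounded by pointwise min and max
  Fs <- sapply(es, `[[`, "F")
  expect_true(all(m$F >= apply(Fs, 1, min) & m$F <= apply(Fs, 1, max)))
  expect_error(median_ecdf(list()), "empty")
})

test_that("KS distance equals the brute-force sup over pooled points", {
  expect_equal(ks_distance(c(1, 2, 3), c(1, 2, 3))$D, 0)
  expect_equal(ks_distance(c(1, 2, 3), c(10, 11, 12))$D, 1)

  for (seed in 1:50) {
    ab <- gliofrag:::with_seed(seed, list(
      a = sample(1:60, sample(5:30, 1), replace = TRUE),
      b = sample(1:60, sample(5:30, 1), replace = TRUE)))
    pooled <- sort(unique(c(ab$a, ab$b)))
    oracle <- max(abs(vapply(pooled, function(x)
      mean(ab$a <= x) - mean(ab$b <= x), numeric(1))))
    expect_equal(ks_distance(ab$a, ab$b)$D, oracle)
    # cross-check against the stock KS statistic
    suppressWarnings(
      expect_equal(ks_distance(ab$a, ab$b)$D,
                   unname(stats::ks.test(ab$a, ab$b)$statistic)))
  }
  expect_error(ks_distance(numeric(0), 1:3), "empty")
})

test_that("rank-sum p-values match exact enumeration and singleton identity", {
  expect_equal(rank_sum_p(5, 5), 1)
  # {1,2} vs {3,4}: 6 equally likely rank splits, the observed one is the
  # most extreme on its side -> two-sided p = 2 * 1/6 = 1/3
  expect_equal(rank_sum_p(c(1, 2), c(3, 4)), 1 / 3)
  # large same-distribution draws: p well away from 0
  a <- gliofrag:::with_seed(1, stats::rpois(200, 100))
  b <- gliofrag:::with_seed(2, stats::rpois(200, 100))
  expect_gt(rank_sum_p(a, b), 0.01)
})

test_that("extrema detection applies the strict 5-bp-window rule", {
  mk <- function(h, lo = 48) structure(
    list(grid = seq(lo, lo + length(h) - 1L), height = h / sum(h)),
    class = "frag_histogram")

  # single interior peak
  h <- mk(c(rep(1, 10), 2, 3, 2, rep(1, 80)))
  e <- detect_extrema(h, window = c(50, 140))
  expect_equal(e$maxima, 59)   # position of the 3

  # constant heights: strictness gives no extrema at all
  e2 <- detect_extrema(mk(rep(1, 100)), window = c(50, 140))
  expect_length(e2$maxima, 0)
  expect_length(e2$minima, 0)

  # plateau: leftmost of the two tied top positions reported
  h3 <- mk(c(rep(1, 10), 3, 3, rep(1, 81)))
  e3 <- detect_extrema(h3, window = c(50, 140))
  expect_equal(e3$maxima, 58)

  expect_error(detect_extrema(mk(rep(1, 20)), window = c(10, 140)),
               "window outside")
})

test_that("detected maxima sit on the analytic cosine crests", {
  m <- build_size_model(osc_amp = 0.5, osc_phase = 59.7, osc_period = 10.4)
  h <- structure(list(grid = m$support, height = m$pmf),
                 class = "frag_histogram")
  found <- detect_extrema(h, window = c(55, 138))$maxima
  crests <- 59.7 + 10.4 * (0:6)   # interior crests of the window
  for (cr in crests)
    expect_true(any(abs(found - cr) <= 1),
                label = sprintf("crest at %.1f detected", cr))
})

test_that("brute-force window scan agrees with detect_extrema on random histograms", {
  brute <- function(h, window) {
    g <- h$grid; v <- h$height
    out <- list(maxima = integer(0), minima = integer(0))
    for (y in g[g >= window[1] & g <= window[2]]) {
      nb <- which(g >= y - 2 & g <= y + 2 & g != y)
      i <- match(y, g)
      for (sgn in c(1, -1)) {
        d <- sgn * (v[i] - v[nb])
        ok <- all(d[g[nb] < y] > 0) && all(d[g[nb] > y] >= 0) && any(d > 0)
        if (ok) {
          fld <- if (sgn == 1) "maxima" else "minima"
          out[[fld]] <- c(out[[fld]], y)
        }
      }
    }
    out
  }
  for (seed in 1:20) {
    v <- gliofrag:::with_seed(seed, sample(1:6, 101, replace = TRUE))
    h <- structure(list(grid = 40:140, height = v / sum(v)),
                   class = "frag_histogram")
    expect_identical(detect_extrema(h, c(50, 130)), brute(h, c(50, 130)))
  }
})

test_that("unimodal histogram yields exactly one window maximum, no interior minima", {
  v <- stats::dnorm(30:160, 95, 12)
  h <- structure(list(grid = 30:160, height = v / sum(v)),
                 class = "frag_histogram")
  e <- detect_extrema(h, c(50, 140))
  expect_length(e$maxima, 1)
  interior <- e$minima[e$minima > 52 & e$minima < 138]
  expect_length(interior, 0)
})

test_that("average_positions matches ranks and rounds to integer bp", {
  one <- list(list(maxima = c(58L, 69L), minima = c(62L, 73L)))
  expect_equal(average_positions(one)$maxima, c(58L, 69L))
  two <- list(list(maxima = 58, minima = 62), list(maxima = 60, minima = 64))
  expect_equal(average_positions(two)$maxima, 59L)
  expect_equal(average_positions(two)$minima, 63L)
  expect_error(average_positions(list()), "input error")
})

test_that("oscillation amplitude: closed forms and depth invariance", {
  uni <- structure(list(grid = 1:500, height = rep(1 / 500, 500)),
                   class = "frag_histogram")
  expect_equal(osc_amplitude(uni), 0)

  # heights h1 at all 8 maxima, h2 at all 8 minima -> 8 * (h1 - h2)
  spec <- peak_valley_spec()
  h <- rep(0.001, 500)
  h[spec$maxima] <- 0.004; h[spec$minima] <- 0.0015
  h <- h / sum(h)
  hist <- structure(list(grid = 1:500, height = h), class = "frag_histogram")
  expect_equal(osc_amplitude(hist, spec),
               8 * (h[spec$maxima[1]] - h[spec$minima[1]]))

  # duplicating every fragment changes nothing (normalised heights)
  lens <- gliofrag:::with_seed(3, sample(40:200, 500, replace = TRUE))
  a1 <- osc_amplitude(frag_histogram(lens, 1, 500))
  a2 <- osc_amplitude(frag_histogram(c(lens, lens), 1, 500))
  expect_equal(a1, a2)

  expect_error(osc_amplitude(structure(list(grid = 100:120, height = rep(1/21, 21)),
                                       class = "frag_histogram")),
               "off the histogram grid")
})

test_that("feature vectors and the cohort matrix have the documented layout", {
  v <- feature_vector(fragment_sample(rep(45, 50)))
  expect_named(v, c("P30_60", "P61_90", "P91_120", "P121_150", "P151_180",
                    "P181_210", "P211_240", "P241_270", "P271_300",
                    "OSC_10bp"))
  expect_equal(unname(v[1:9]), c(1, rep(0, 8)))

  cohort <- simulate_cohort(cohort_spec(list(
    list(preset = "healthy_urine", n = 2),
    list(preset = "glioma_urine", n = 2)),
    fragments_per_sample = 2000, master_seed = 4))
  fm <- feature_matrix(cohort$samples, cohort$labels)
  expect_equal(dim(fm), c(4, 13))
  expect_false(anyNA(fm))

  # permuting label-row order permutes matrix rows only
  perm <- cohort$labels[c(3, 1, 4, 2), ]
  fm2 <- feature_matrix(cohort$samples, perm)
  expect_equal(fm2[order(fm2$sample_id), ], fm[order(fm$sample_id), ],
               ignore_attr = TRUE)

  bad <- cohort$labels[-1, ]
  expect_error(feature_matrix(cohort$samples, bad), "label missing")
  bad2 <- cohort$labels; bad2$label[1] <- "case"
  expect_error(feature_matrix(cohort$samples, bad2), "cancer")
})
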