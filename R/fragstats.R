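#' Normalised fragment-length histogram
#'
#' `height(x)` is the number of fragments of length exactly `x` divided by
#' the *total* number of fragments in the sample (not just those inside
#' `[lo, hi]`), so heights are comparable across grids and sum to <= 1 on a
#' truncated grid.
#'
#' @param sample a `fragment_sample` (non-empty) or an integer length vector.
#' @param lo,hi integer grid bounds in bp.
#' @return object of class `frag_histogram`: list(grid, height).
#' @export
frag_histogram <- function(sample, lo = 1L, hi = 500L) {
  lens <- if (inherits(sample, "fragment_sample")) sample$lengths else as.integer(sample)
  if (length(lens) == 0L) stop("input error: empty sample")
  stopifnot(lo >= 1, hi >= lo)
  grid <- lo:hi
  # tabulate drops values outside [1, nbins], i.e. lengths outside the grid
  height <- tabulate(lens - lo + 1L, nbins = hi - lo + 1L) / length(lens)
  structure(list(grid = grid, height = height), class = "frag_histogram")
}

#' Median fragment size
#'
#' Standard sample median: for an even count, the midpoint of the two central
#' order statistics (possibly half-integer).
#'
#' @param sample a `fragment_sample` or integer vector.
#' @return median length in bp.
#' @export
median_size <- function(sample) {
  lens <- if (inherits(sample, "fragment_sample")) sample$lengths else sample
  if (length(lens) == 0L) stop("input error: empty sample")
  stats::median(lens)
}

#' Proportion of fragments in an inclusive length range
#'
#' @param sample a `fragment_sample` or integer vector.
#' @param lo,hi inclusive bounds in bp, `lo <= hi`.
#' @return fraction of all fragments with `lo <= length <= hi`.
#' @export
proportion_in_range <- function(sample, lo, hi) {
  lens <- if (inherits(sample, "fragment_sample")) sample$lengths else sample
  if (length(lens) == 0L) stop("input error: empty sample")
  if (lo > hi) stop("input error: lo > hi")
  mean(lens >= lo & lens <= hi)
}

.bin_bounds <- cbind(lo = c(30, 61, 91, 121, 151, 181, 211, 241, 271),
                     hi = c(60, 90, 120, 150, 180, 210, 240, 270, 300))

#' The nine 30-bp bin proportions
#'
#' P(30-60), P(61-90), ..., P(271-300): disjoint inclusive bins partitioning
#' 30-300 bp, each as a fraction of all fragments in the sample.
#'
#' @param sample a `fragment_sample` or integer vector.
#' @return named numeric vector `P30_60 ... P271_300`.
#' @export
bin_proportions <- function(sample) {
  p <- apply(.bin_bounds, 1L, function(b)
    proportion_in_range(sample, b["lo"], b["hi"]))
  names(p) <- sprintf("P%d_%d", .bin_bounds[, "lo"], .bin_bounds[, "hi"])
  p
}

#' Empirical CDF on an integer grid
#'
#' @param sample a `fragment_sample` or integer vector.
#' @param grid integer bp grid (default 1:500).
#' @return object of class `ecdf_table`: list(grid, F).
#' @export
ecdf_table <- function(sample, grid = 1:500) {
  lens <- if (inherits(sample, "fragment_sample")) sample$lengths else sample
  if (length(lens) == 0L) stop("input error: empty sample")
  Fn <- stats::ecdf(lens)
  structure(list(grid = grid, F = Fn(grid)), class = "ecdf_table")
}

#' Pointwise median of empirical CDFs
#'
#' The grid-wise median of the input ECDFs, the standard way to summarise a
#' group's cumulative size profile.
#'
#' @param ecdfs list of `ecdf_table` on a common grid.
#' @return an `ecdf_table`.
#' @export
median_ecdf <- function(ecdfs) {
  if (length(ecdfs) == 0L) stop("input error: empty ECDF list")
  grids <- lapply(ecdfs, `[[`, "grid")
  if (!all(vapply(grids, identical, logical(1), grids[[1]])))
    stop("input error: ECDFs must share a common grid")
  Fm <- apply(vapply(ecdfs, `[[`, numeric(length(grids[[1]])), "F"), 1L,
              stats::median)
  structure(list(grid = grids[[1]], F = Fm), class = "ecdf_table")
}

#' Two-sample Kolmogorov-Smirnov distance
#'
#' `D` is the supremum over pooled observed values of |F_a - F_b|, computed
#' directly from the two empirical CDFs; `p` is the asymptotic two-sample KS
#' p-value (reported for context, ties make it approximate).
#'
#' @param a,b `fragment_sample`s or numeric vectors, both non-empty.
#' @return list(D, p).
#' @export
ks_distance <- function(a, b) {
  xa <- if (inherits(a, "fragment_sample")) a$lengths else a
  xb <- if (inherits(b, "fragment_sample")) b$lengths else b
  if (length(xa) == 0L || length(xb) == 0L) stop("input error: empty sample")
  pooled <- sort(unique(c(xa, xb)))
  Fa <- stats::ecdf(xa)(pooled)
  Fb <- stats::ecdf(xb)(pooled)
  D <- max(abs(Fa - Fb))
  n_eff <- as.numeric(length(xa)) * length(xb) / (length(xa) + length(xb))
  lambda <- (sqrt(n_eff) + 0.12 + 0.11 / sqrt(n_eff)) * D
  k <- 1:100
  p <- min(1, max(0, 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))))
  list(D = D, p = p)
}

#' Two-sided Wilcoxon rank-sum p-value
#'
#' Exact when both samples are small and tie-free, otherwise the normal
#' approximation with tie correction (the behaviour of
#' [stats::wilcox.test()]).
#'
#' @param a,b samples (fragment samples or numeric vectors), non-empty.
#' @return two-sided p-value.
#' @export
rank_sum_p <- function(a, b) {
  xa <- if (inherits(a, "fragment_sample")) a$lengths else a
  xb <- if (inherits(b, "fragment_sample")) b$lengths else b
  if (length(xa) == 0L || length(xb) == 0L) stop("input error: empty sample")
  if (length(xa) == 1L && length(xb) == 1L && xa == xb) return(1)
  suppressWarnings(stats::wilcox.test(xa, xb, alternative = "two.sided")$p.value)
}

#' Canonical peak/valley positions for the 10-bp oscillation
#'
#' Defaults are the field's averaged crest/trough positions in the 50-140 bp
#' window: maxima 58, 69, 80, 92, 102, 112, 122, 134 and minima 62, 73, 84,
#' 96, 106, 116, 126, 137.
#'
#' @param maxima,minima strictly increasing integer positions inside `window`.
#' @param window length-2 bp interval (default c(50, 140)).
#' @return a `peak_valley_spec` list.
#' @export
peak_valley_spec <- function(maxima = c(58, 69, 80, 92, 102, 112, 122, 134),
                             minima = c(62, 73, 84, 96, 106, 116, 126, 137),
                             window = c(50, 140)) {
  stopifnot(all(diff(maxima) > 0), all(diff(minima) > 0),
            all(maxima >= window[1] & maxima <= window[2]),
            all(minima >= window[1] & minima <= window[2]))
  structure(list(maxima = as.integer(maxima), minima = as.integer(minima),
                 window = window), class = "peak_valley_spec")
}

#' Detect local maxima and minima of a histogram in a window
#'
#' A position `y` is a maximum iff its height is the strictly largest over
#' `[y-2, y+2]` (clipped to the grid); minima analogously. On a flat plateau
#' that dominates its window, only the leftmost position is reported; a
#' constant stretch yields no extrema.
#'
#' @param hist a `frag_histogram` covering `window`.
#' @param window length-2 bp interval (default c(50, 140)).
#' @return list(maxima, minima): integer bp positions.
#' @export
detect_extrema <- function(hist, window = c(50, 140)) {
  stopifnot(inherits(hist, "frag_histogram"))
  if (window[1] < min(hist$grid) || window[2] > max(hist$grid))
    stop("input error: window outside histogram grid")
  g <- hist$grid; h <- hist$height
  is_ext <- function(y, sign) {
    i <- match(y, g)
    nb <- which(g >= y - 2 & g <= y + 2 & g != y)
    dv <- sign * (h[i] - h[nb])
    left <- g[nb] < y
    all(dv[left] > 0) && all(dv[!left] >= 0) && any(dv > 0)
  }
  ys <- g[g >= window[1] & g <= window[2]]
  list(maxima = ys[vapply(ys, is_ext, logical(1), sign = 1)],
       minima = ys[vapply(ys, is_ext, logical(1), sign = -1)])
}

#' Average extrema positions across samples
#'
#' Matches each sample's detected extrema by rank order within the window and
#' averages positions per rank, rounding to the nearest integer bp. Samples
#' contribute to a rank only if they detected that many extrema.
#'
#' @param extrema_list list of outputs of [detect_extrema()] (>= 1).
#' @param window passed through to the resulting spec.
#' @return a [peak_valley_spec()] with the averaged positions.
#' @export
average_positions <- function(extrema_list, window = c(50, 140)) {
  if (length(extrema_list) == 0L) stop("input error: no extrema supplied")
  avg <- function(field) {
    lst <- lapply(extrema_list, function(e) sort(e[[field]]))
    nmax <- max(vapply(lst, length, integer(1)))
    if (nmax == 0L) return(integer(0))
    out <- vapply(seq_len(nmax), function(r) {
      v <- unlist(lapply(lst, function(p) if (length(p) >= r) p[r] else NULL))
      round(mean(v))
    }, numeric(1))
    as.integer(out[!duplicated(out)])
  }
  mx <- avg("maxima"); mn <- avg("minima")
  peak_valley_spec(maxima = mx, minima = mn, window = window)
}

#' Oscillation amplitude statistic (OSC_10bp)
#'
#' Sum of histogram heights at the spec's maxima positions minus the sum at
#' its minima positions. Heights are fractions of all fragments, so the
#' statistic is invariant to sequencing depth; larger values mean more
#' distinct ~10 bp periodic peaks. May be negative.
#'
#' @param hist a `frag_histogram` whose grid covers all spec positions.
#' @param spec a [peak_valley_spec()] (default: canonical positions).
#' @return unitless amplitude.
#' @export
osc_amplitude <- function(hist, spec = peak_valley_spec()) {
  stopifnot(inherits(hist, "frag_histogram"), inherits(spec, "peak_valley_spec"))
  pos <- c(spec$maxima, spec$minima)
  idx <- match(pos, hist$grid)
  if (anyNA(idx)) stop("input error: spec position off the histogram grid")
  sum(hist$height[match(spec$maxima, hist$grid)]) -
    sum(hist$height[match(spec$minima, hist$grid)])
}

#' The 10 fragmentation features of one sample
#'
#' Nine 30-bp bin proportions plus the oscillation amplitude OSC_10bp.
#'
#' @param sample a `fragment_sample`.
#' @param spec a [peak_valley_spec()] for OSC_10bp.
#' @return named numeric vector of length 10.
#' @export
feature_vector <- function(sample, spec = peak_valley_spec()) {
  p <- bin_proportions(sample)
  h <- frag_histogram(sample, 1L, max(500L, max_len(sample)))
  c(p, OSC_10bp = osc_amplitude(h, spec))
}

max_len <- function(sample) {
  lens <- if (inherits(sample, "fragment_sample")) sample$lengths else sample
  max(lens)
}

#' Feature matrix for a cohort
#'
#' One row per sample: sample_id, patient_id, label, then the 10 features.
#'
#' @param samples named list of `fragment_sample`.
#' @param labels data.frame with columns sample_id, patient_id, label
#'   ("cancer"/"control") covering every sample.
#' @param spec a [peak_valley_spec()].
#' @return data.frame (rows in `labels` order).
#' @export
feature_matrix <- function(samples, labels, spec = peak_valley_spec()) {
  stopifnot(all(c("sample_id", "patient_id", "label") %in% names(labels)))
  miss <- setdiff(vapply(samples, `[[`, character(1), "sample_id"),
                  labels$sample_id)
  if (length(miss))
    stop("input error: label missing for sample(s) ", paste(miss, collapse = ", "))
  if (!all(labels$label %in% c("cancer", "control")))
    stop("input error: labels must be 'cancer' or 'control'")
  by_id <- stats::setNames(samples, vapply(samples, `[[`, character(1), "sample_id"))
  feats <- t(vapply(labels$sample_id,
                    function(id) feature_vector(by_id[[id]], spec),
                    numeric(10)))
  out <- cbind(labels[, c("sample_id", "patient_id", "label")],
               as.data.frame(feats))
  rownames(out) <- NULL
  out
}
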