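#' Construct a fragment sample
#'
#' A `fragment_sample` is one sample's multiset of cfDNA fragment lengths in
#' bp plus its metadata. Two samples are equal iff their length multisets and
#' metadata are equal; the order of lengths carries no meaning.
#'
#' @param lengths integer vector of fragment lengths (bp), all >= 1.
#' @param sample_id,patient_id identifiers.
#' @param group optional group label (e.g. a preset name).
#' @param fluid one of "csf", "plasma", "urine", "unknown".
#' @param timepoint one of "baseline", "followup", "unknown".
#' @return an object of class `fragment_sample`.
#' @export
fragment_sample <- function(lengths, sample_id = "sample", patient_id = sample_id,
                            group = NA_character_, fluid = "unknown",
                            timepoint = "unknown") {
  lengths <- as.integer(lengths)
  if (length(lengths) && any(lengths < 1L))
    stop("all fragment lengths must be >= 1 bp")
  fluid <- match.arg(fluid, c("csf", "plasma", "urine", "unknown"))
  timepoint <- match.arg(timepoint, c("baseline", "followup", "unknown"))
  structure(list(sample_id = sample_id, patient_id = patient_id,
                 group = group, fluid = fluid, timepoint = timepoint,
                 lengths = lengths),
            class = "fragment_sample")
}

#' @export
print.fragment_sample <- function(x, ...) {
  cat(sprintf("fragment_sample '%s' (patient %s, group %s): %d fragments, median %s bp\n",
              x$sample_id, x$patient_id, x$group, length(x$lengths),
              if (length(x$lengths)) format(stats::median(x$lengths)) else "NA"))
  invisible(x)
}

#' @export
length.fragment_sample <- function(x) length(x$lengths)

#' Draw i.i.d. fragment lengths from a size model
#'
#' @param model a `size_model` (or a `group_preset`, whose model is used).
#' @param n number of fragments, >= 1.
#' @param seed integer seed; identical (model, n, seed) give identical output.
#' @param ... metadata passed to [fragment_sample()].
#' @return a `fragment_sample` of `n` lengths.
#' @export
sample_fragments <- function(model, n, seed, ...) {
  if (inherits(model, "group_preset")) model <- model$model
  stopifnot(inherits(model, "size_model"))
  if (n < 1) stop("n must be >= 1")
  lens <- with_seed(seed, sample(model$support, n, replace = TRUE, prob = model$pmf))
  fragment_sample(lens, ...)
}

#' Down-sample a fragment sample without replacement
#'
#' Mirrors "when necessary" down-sampling to a fixed fragment count for
#' between-sample comparability: samples already at or below `n` are returned
#' unchanged.
#'
#' @param sample a `fragment_sample`.
#' @param n target number of fragments (>= 1).
#' @param seed integer seed; the draw is deterministic given the seed.
#' @return a `fragment_sample`.
#' @export
downsample <- function(sample, n, seed = 1L) {
  stopifnot(inherits(sample, "fragment_sample"))
  if (n < 1) stop("n must be >= 1")
  if (n >= length(sample$lengths)) return(sample)
  out <- sample
  out$lengths <- with_seed(seed, base::sample(sample$lengths, n, replace = FALSE))
  out
}

#' Write / read fragment-length tables
#'
#' TSV with header `sample_id, patient_id, group, length` and optional
#' `count` column (run-length form: each row stands for `count` fragments).
#' `read_fragment_table(write_fragment_table(x))` is the identity on multiset
#' content and metadata.
#'
#' @param samples list of `fragment_sample`.
#' @param path file path.
#' @return `read_fragment_table` returns a named list of `fragment_sample`.
#' @export
write_fragment_table <- function(samples, path) {
  if (inherits(samples, "fragment_sample")) samples <- list(samples)
  rows <- lapply(samples, function(s) {
    tab <- table(s$lengths)
    data.frame(sample_id = s$sample_id, patient_id = s$patient_id,
               group = s$group,
               length = as.integer(names(tab)), count = as.integer(tab),
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fragment_table
#' @export
read_fragment_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "patient_id", "group", "length")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("fragment table format error: missing column(s) ",
         paste(miss, collapse = ", "))
  if (!is.numeric(df$length) || any(df$length != floor(df$length)) ||
      any(df$length < 1)) {
    bad <- which(!is.finite(df$length) | df$length != floor(df$length) |
                   df$length < 1)[1]
    stop("fragment table format error: non-positive-integer length at row ", bad)
  }
  if (is.null(df$count)) df$count <- 1L
  if (any(df$count < 0)) stop("fragment table format error: negative count")
  out <- lapply(split(df, df$sample_id), function(d) {
    fragment_sample(rep(as.integer(d$length), d$count),
                    sample_id = d$sample_id[1], patient_id = d$patient_id[1],
                    group = as.character(d$group[1]))
  })
  out[unique(df$sample_id)]
}
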