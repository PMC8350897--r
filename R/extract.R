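#' Alignment filter specification
#'
#' Read-level filters applied before fragment lengths are counted, mirroring
#' standard sWGS practice: duplicates, supplementary and secondary alignments
#' are dropped, a minimum mapping quality is required (default 30; "low
#' mapping quality" is not pinned to a number in common pipelines, so it is
#' configurable), and templates outside a plausible length range are ignored.
#'
#' @param min_mapq minimum mapping quality (default 30).
#' @param exclude_duplicates drop duplicate-flagged records (default TRUE).
#' @param exclude_supplementary drop supplementary records (default TRUE).
#' @param require_proper_pair require the proper-pair flag (default TRUE).
#' @param length_range allowed |TLEN| interval in bp (default c(1, 1000)).
#' @return a `filter_spec` list.
#' @export
filter_spec <- function(min_mapq = 30L, exclude_duplicates = TRUE,
                        exclude_supplementary = TRUE,
                        require_proper_pair = TRUE,
                        length_range = c(1L, 1000L)) {
  stopifnot(length_range[1] >= 1, length_range[2] >= length_range[1])
  structure(list(min_mapq = min_mapq,
                 exclude_duplicates = exclude_duplicates,
                 exclude_supplementary = exclude_supplementary,
                 require_proper_pair = require_proper_pair,
                 length_range = length_range),
            class = "filter_spec")
}

#' Extract fragment lengths from a paired-end alignment file
#'
#' Counts each sequenced template exactly once: only the record with positive
#' template length (the leftmost mate) contributes, with fragment length
#' |TLEN|. Secondary alignments are always excluded; duplicates,
#' supplementary records, mapping quality and proper pairing follow the
#' `filter_spec`. Returns the kept lengths plus an audit of how many records
#' each filter discarded.
#'
#' @param path SAM or BAM file (SAM is converted on the fly).
#' @param spec a [filter_spec()].
#' @param ... metadata passed to [fragment_sample()].
#' @return a `fragment_sample` with attribute `filter_counts` (named integer
#'   vector of records discarded per reason, plus `kept`).
#' @export
extract_fragment_lengths <- function(path, spec = filter_spec(), ...) {
  stopifnot(inherits(spec, "filter_spec"))
  if (!file.exists(path)) stop("I/O error: no such file: ", path)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  rec <- Rsamtools::scanBam(
    bam, param = Rsamtools::ScanBamParam(
      what = c("qname", "flag", "mapq", "isize")))[[1]]
  flag <- rec$flag
  n <- length(flag)
  counts <- c(total_records = n)

  keep <- rep(TRUE, n)
  drop_by <- function(keep, cond, reason, counts) {
    hit <- keep & cond
    counts[reason] <- sum(hit)
    keep[hit] <- FALSE
    list(keep = keep, counts = counts)
  }
  bit <- function(flag, b) bitwAnd(flag, b) > 0L

  st <- drop_by(keep, !bit(flag, 1L), "unpaired", counts)
  st <- drop_by(st$keep, bit(flag, 4L) | bit(flag, 8L), "unmapped", st$counts)
  st <- drop_by(st$keep, bit(flag, 256L), "secondary", st$counts)
  if (spec$exclude_supplementary)
    st <- drop_by(st$keep, bit(flag, 2048L), "supplementary", st$counts)
  if (spec$exclude_duplicates)
    st <- drop_by(st$keep, bit(flag, 1024L), "duplicate", st$counts)
  if (spec$require_proper_pair)
    st <- drop_by(st$keep, !bit(flag, 2L), "not_proper_pair", st$counts)
  mapq_bad <- is.na(rec$mapq) | rec$mapq < spec$min_mapq
  st <- drop_by(st$keep, mapq_bad, "low_mapq", st$counts)
  # count each template once: keep the leftmost mate (TLEN > 0)
  tlen_bad <- is.na(rec$isize) | rec$isize <= 0L
  st <- drop_by(st$keep, tlen_bad, "mate_record_or_no_tlen", st$counts)
  lens <- abs(rec$isize[st$keep])
  range_bad <- lens < spec$length_range[1] | lens > spec$length_range[2]
  counts <- st$counts
  counts["out_of_length_range"] <- sum(range_bad)
  lens <- lens[!range_bad]
  counts["kept"] <- length(lens)

  if (length(lens) == 0L)
    warning("no templates passed the filters (unpaired-only or empty input?)")
  out <- fragment_sample(lens, ...)
  attr(out, "filter_counts") <- counts
  out
}
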