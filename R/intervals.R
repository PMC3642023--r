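#' Genomic intervals and region sets
#'
#' All coordinates in famprior are 1-based and inclusive: the interval
#' chr13:26048387-26099109 has length `end - start + 1` = 50,723 bp. BED
#' input/output converts to/from the 0-based half-open convention at the file
#' boundary only (see [read_bed()] / [write_bed()]).
#'
#' A *region set* is a plain `data.frame` with columns `chrom`, `start`,
#' `end`, normalised so that intervals are sorted by chromosome and start and
#' no two intervals on one chromosome overlap or abut (abutting intervals are
#' merged: segment sets coming out of IBD inference are maximal runs).
#'
#' @name intervals
NULL

#' Construct a normalised region set
#'
#' @param chrom character vector of chromosome names, or a data.frame with
#'   columns `chrom`, `start`, `end`.
#' @param start,end 1-based inclusive coordinates (ignored when `chrom` is a
#'   data.frame).
#' @return data.frame of class `region_set` with columns `chrom`, `start`,
#'   `end`, sorted and merged.
#' @examples
#' region_set(c("chr1", "chr1"), c(1, 90), c(100, 200))  # merges to chr1:1-200
#' @export
region_set <- function(chrom = character(), start = numeric(), end = numeric()) {
  if (is.data.frame(chrom)) {
    df <- chrom
    stopifnot(all(c("chrom", "start", "end") %in% names(df)))
    chrom <- as.character(df$chrom); start <- as.numeric(df$start); end <- as.numeric(df$end)
  }
  validate_intervals(chrom, start, end)
  if (length(chrom) == 0L) {
    out <- data.frame(chrom = character(), start = numeric(), end = numeric())
    class(out) <- c("region_set", "data.frame")
    return(out)
  }
  gr <- GenomicRanges::reduce(as_granges(chrom, start, end))  # merges overlaps and abutters
  out <- from_granges(gr)
  class(out) <- c("region_set", "data.frame")
  out
}

validate_intervals <- function(chrom, start, end) {
  if (length(chrom) != length(start) || length(chrom) != length(end))
    stop("chrom, start, end must have equal length")
  if (any(is.na(chrom)) || any(is.na(start)) || any(is.na(end)))
    stop("intervals may not contain NA")
  if (any(start < 1)) stop("interval start must be >= 1")
  bad <- which(end < start)
  if (length(bad))
    stop(sprintf("malformed interval (end < start): %s:%s-%s",
                 chrom[bad[1]], format(start[bad[1]], scientific = FALSE),
                 format(end[bad[1]], scientific = FALSE)))
  invisible(TRUE)
}

as_granges <- function(chrom, start, end) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start = start, end = end))
}

from_granges <- function(gr) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = as.numeric(GenomicRanges::start(gr)),
                   end = as.numeric(GenomicRanges::end(gr)),
                   stringsAsFactors = FALSE)
  df[order(df$chrom, df$start), , drop = FALSE]
}

rs_granges <- function(r) as_granges(r$chrom, r$start, r$end)

#' Length of genomic intervals in base pairs
#'
#' Inclusive length `end - start + 1`.
#'
#' @param chrom chromosome names or a data.frame with `chrom`,`start`,`end`.
#' @param start,end coordinates (when `chrom` is not a data.frame).
#' @return numeric vector of lengths in bp.
#' @examples
#' interval_length("chr13", 26048387, 26099109)  # 50723
#' @export
interval_length <- function(chrom, start = NULL, end = NULL) {
  if (is.data.frame(chrom)) {
    start <- chrom$start; end <- chrom$end; chrom <- as.character(chrom$chrom)
  }
  validate_intervals(chrom, start, end)
  as.numeric(end) - as.numeric(start) + 1
}

#' Region-set algebra
#'
#' `intersect_region_sets()` returns exactly the bases present in both sets;
#' `subtract_region_sets()` the bases of `a` not in `b`;
#' `union_region_sets()` the bases in either. All return normalised
#' region sets and satisfy `|a ∩ b| + |a − b| = |a|` in total bases.
#'
#' @param a,b region sets (or coercible data.frames).
#' @return a `region_set`.
#' @export
intersect_region_sets <- function(a, b) {
  a <- as_region_set(a); b <- as_region_set(b)
  if (nrow(a) == 0L || nrow(b) == 0L) return(region_set())
  # suppress the benign seqlevel-union warning when chromosome sets differ
  gr <- suppressWarnings(GenomicRanges::intersect(rs_granges(a), rs_granges(b)))
  region_set(from_granges(gr))
}

#' @rdname intersect_region_sets
#' @export
subtract_region_sets <- function(a, b) {
  a <- as_region_set(a); b <- as_region_set(b)
  if (nrow(a) == 0L) return(region_set())
  if (nrow(b) == 0L) return(a)
  gr <- suppressWarnings(GenomicRanges::setdiff(rs_granges(a), rs_granges(b)))
  region_set(from_granges(gr))
}

#' @rdname intersect_region_sets
#' @export
union_region_sets <- function(a, b) {
  a <- as_region_set(a); b <- as_region_set(b)
  region_set(rbind(as.data.frame(a)[c("chrom", "start", "end")],
                   as.data.frame(b)[c("chrom", "start", "end")]))
}

as_region_set <- function(x) {
  if (inherits(x, "region_set")) x else region_set(x)
}

#' Summarise a region set
#'
#' @param r a region set.
#' @return list with `count` (number of intervals) and `total_bp` (sum of
#'   inclusive lengths).
#' @export
summarize_region_set <- function(r) {
  r <- as_region_set(r)
  list(count = nrow(r),
       total_bp = if (nrow(r)) sum(interval_length(r)) else 0)
}

#' Fraction of an interval covered by a region set
#'
#' Used for CNV blacklist filtering: the fraction of the *call's* span covered
#' by the mask (not the converse), matching standard PennCNV post-filter
#' practice.
#'
#' @param chrom,start,end the query interval (single interval).
#' @param mask a region set.
#' @return fraction in \[0, 1\].
#' @export
overlap_fraction <- function(chrom, start, end, mask) {
  validate_intervals(chrom, start, end)
  stopifnot(length(chrom) == 1L)
  mask <- as_region_set(mask)
  if (nrow(mask) == 0L) return(0)
  hit <- intersect_region_sets(region_set(chrom, start, end), mask)
  cov <- if (nrow(hit)) sum(interval_length(hit)) else 0
  cov / interval_length(chrom, start, end)
}
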