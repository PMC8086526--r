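# Interval algebra on 0-based half-open intervals.
#
# All user-facing coordinates in this package follow the BED convention:
# 0-based, half-open [start, end). GFF (1-based inclusive) is converted at
# the file boundary. Internally the set operations are delegated to
# GenomicRanges, which uses 1-based closed integers; the two helpers below
# do the (+1, end) shift in one place.

.iv_validate <- function(x, arg = "intervals") {
  if (!is.data.frame(x) || !all(c("chrom", "start", "end") %in% names(x))) {
    stop(sprintf("%s must be a data frame with columns chrom, start, end", arg))
  }
  if (nrow(x) == 0) return(invisible(x))
  if (any(!is.finite(x$start)) || any(!is.finite(x$end))) {
    stop(sprintf("%s has non-finite coordinates", arg))
  }
  if (any(x$start < 0) || any(x$start >= x$end)) {
    stop(sprintf("%s has malformed intervals (need 0 <= start < end)", arg))
  }
  invisible(x)
}

.iv_to_gr <- function(x) {
  GenomicRanges::GRanges(
    seqnames = as.character(x$chrom),
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
}

.gr_to_iv <- function(gr) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

.iv_empty <- function() {
  data.frame(chrom = character(0), start = integer(0), end = integer(0),
             stringsAsFactors = FALSE)
}

.iv_sort <- function(x) {
  x <- x[order(x$chrom, x$start, x$end), , drop = FALSE]
  rownames(x) <- NULL
  x
}

#' Merge genomic intervals
#'
#' Collapses a set of 0-based half-open intervals into the minimal sorted set
#' of non-overlapping intervals. Abutting intervals (`[0,5)`, `[5,9)`) are
#' merged into one.
#'
#' @param x Data frame with columns `chrom`, `start`, `end` (0-based
#'   half-open).
#' @return Data frame of merged intervals, sorted by `(chrom, start)`.
#' @examples
#' merge_intervals(data.frame(chrom = "chr1", start = c(0, 5), end = c(5, 9)))
#' @export
merge_intervals <- function(x) {
  .iv_validate(x)
  if (nrow(x) == 0) return(.iv_empty())
  .iv_sort(.gr_to_iv(GenomicRanges::reduce(.iv_to_gr(x))))
}

.iv_binop <- function(x, y, fun) {
  .iv_validate(x, "x")
  .iv_validate(y, "y")
  grx <- .iv_to_gr(x)
  gry <- .iv_to_gr(y)
  lv <- union(GenomeInfoDb::seqlevels(grx), GenomeInfoDb::seqlevels(gry))
  GenomeInfoDb::seqlevels(grx) <- lv
  GenomeInfoDb::seqlevels(gry) <- lv
  .iv_sort(.gr_to_iv(fun(grx, gry)))
}

#' Subtract one interval set from another
#'
#' Removes every base of `y` from `x` (set difference on half-open
#' intervals). The result is merged and sorted.
#'
#' @param x,y Data frames with columns `chrom`, `start`, `end`.
#' @return Data frame of intervals covering `x \\ y`.
#' @examples
#' subtract_intervals(
#'   data.frame(chrom = "chr1", start = 0, end = 1000),
#'   data.frame(chrom = "chr1", start = 400, end = 600)
#' )
#' @export
subtract_intervals <- function(x, y) {
  if (nrow(x) == 0) return(.iv_empty())
  if (nrow(y) == 0) return(merge_intervals(x))
  .iv_binop(x, y, GenomicRanges::setdiff)
}

#' Intersect two interval sets
#'
#' @param x,y Data frames with columns `chrom`, `start`, `end`.
#' @return Data frame of intervals covering the bases present in both sets.
#' @export
intersect_intervals <- function(x, y) {
  if (nrow(x) == 0 || nrow(y) == 0) return(.iv_empty())
  .iv_binop(x, y, GenomicRanges::intersect)
}

#' Union of two interval sets
#'
#' @param x,y Data frames with columns `chrom`, `start`, `end`.
#' @return Merged data frame covering the bases present in either set.
#' @export
union_intervals <- function(x, y) {
  merge_intervals(rbind(x[, c("chrom", "start", "end")],
                        y[, c("chrom", "start", "end")]))
}

#' Total width of an interval set
#'
#' @param x Data frame with columns `chrom`, `start`, `end`. Intervals are
#'   merged first so overlapping input does not double-count bases.
#' @return Number of bases covered.
#' @export
interval_width <- function(x) {
  m <- merge_intervals(x)
  if (nrow(m) == 0) return(0)
  sum(m$end - m$start)
}
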