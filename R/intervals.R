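#' Genomic intervals
#'
#' Intervals are plain data frames with columns `chrom` (character),
#' `start` and `end` (integer-valued, 0-based half-open, BED convention).
#' All footprint arithmetic in the package runs on this representation;
#' conversion to 1-based closed coordinates happens only at the
#' GenomicRanges boundary.
#'
#' @param chrom,start,end vectors of equal length.
#' @return a validated interval data frame.
#' @export
genomic_intervals <- function(chrom = character(), start = integer(),
                              end = integer()) {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.numeric(start),
                   end = as.numeric(end),
                   stringsAsFactors = FALSE)
  validate_intervals(df)
  df
}

validate_intervals <- function(x) {
  stopifnot(is.data.frame(x), all(c("chrom", "start", "end") %in% names(x)))
  if (nrow(x) == 0L) return(invisible(x))
  bad <- which(x$end <= x$start | x$start < 0)
  if (length(bad)) {
    stop("invalid interval(s) at row(s) ", paste(utils::head(bad, 5L), collapse = ", "),
         ": require 0 <= start < end", call. = FALSE)
  }
  invisible(x)
}

intervals_to_granges <- function(x) {
  GenomicRanges::GRanges(x$chrom, IRanges::IRanges(x$start + 1L, x$end))
}

granges_to_intervals <- function(gr) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1,
                   end = GenomicRanges::end(gr),
                   stringsAsFactors = FALSE)
  df[order(df$chrom, df$start), , drop = FALSE]
}

#' Merge genomic intervals into a sorted, disjoint set
#'
#' Overlapping and book-ended (touching) intervals on the same chromosome
#' are fused so that every base is counted exactly once; this is the
#' operation that turns a bag of per-gene coding intervals into a panel
#' footprint.
#'
#' @param intervals interval data frame (`chrom`, `start`, `end`;
#'   0-based half-open).
#' @return interval data frame sorted by (chrom, start) with no two rows
#'   on one chromosome overlapping or touching.
#' @examples
#' merge_intervals(data.frame(chrom = "chr1", start = c(0, 5), end = c(10, 20)))
#' @export
merge_intervals <- function(intervals) {
  validate_intervals(intervals)
  if (nrow(intervals) == 0L) {
    return(genomic_intervals())
  }
  gr <- GenomicRanges::reduce(intervals_to_granges(intervals))
  out <- granges_to_intervals(gr)
  rownames(out) <- NULL
  out
}

#' Total length of an interval set in base pairs
#' @param intervals interval data frame; merged first so overlaps are not
#'   double-counted.
#' @return numeric scalar, base pairs.
#' @export
interval_bp <- function(intervals) {
  m <- merge_intervals(intervals)
  sum(m$end - m$start)
}

#' Write intervals as BED
#' @param intervals interval data frame (0-based half-open, as BED).
#' @param path output file.
#' @export
write_bed <- function(intervals, path) {
  validate_intervals(intervals)
  utils::write.table(intervals[, c("chrom", "start", "end")], path,
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
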