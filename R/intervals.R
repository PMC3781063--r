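#' 1-based inclusive genomic interval
#'
#' The package's coordinate convention is 1-based with both endpoints
#' included, matching VCF positions and the usual way candidate regions are
#' quoted (e.g. `ECA6:73640494-73848154`, a 207,661 bp interval). BED files
#' are converted at the boundary by [read_bed()] / [write_bed()].
#'
#' @param chrom Chromosome name.
#' @param start,end Integer positions, 1-based inclusive, `start <= end`.
#' @return An object of class `genomic_interval`.
#' @examples
#' ibd <- genomic_interval("chr6", 73640494, 73848154)
#' interval_length(ibd)
#' @export
genomic_interval <- function(chrom, start, end) {
  stopifnot(is.character(chrom), length(chrom) == 1L)
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (length(start) != 1L || length(end) != 1L || is.na(start) || is.na(end))
    stop("start and end must be single non-missing positions")
  if (start < 1) stop("start must be >= 1")
  if (start > end) stop("invalid interval: start (", start, ") > end (", end, ")")
  structure(list(chrom = chrom, start = start, end = end),
            class = "genomic_interval")
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat(sprintf("<genomic_interval> %s:%s-%s (%s bp)\n", x$chrom,
              format(x$start, scientific = FALSE),
              format(x$end, scientific = FALSE),
              format(interval_length(x), big.mark = ",")))
  invisible(x)
}

#' Length of a genomic interval in base pairs
#'
#' @param x A [genomic_interval()].
#' @return `end - start + 1`.
#' @export
interval_length <- function(x) {
  stopifnot(inherits(x, "genomic_interval"))
  x$end - x$start + 1
}

#' Test whether positions fall inside an interval
#'
#' @param x A [genomic_interval()].
#' @param pos Numeric vector of 1-based positions.
#' @return Logical vector.
#' @export
interval_contains <- function(x, pos) {
  stopifnot(inherits(x, "genomic_interval"))
  pos >= x$start & pos <= x$end
}

## GRanges bridge used internally for overlap machinery.
as_granges <- function(x) {
  if (inherits(x, "genomic_interval")) {
    GenomicRanges::GRanges(x$chrom, IRanges::IRanges(x$start, x$end))
  } else if (is.data.frame(x)) {
    GenomicRanges::GRanges(x$chrom, IRanges::IRanges(x$start, x$end))
  } else {
    stop("cannot coerce to GRanges")
  }
}

granges_to_df <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Read a BED file as 1-based inclusive intervals
#'
#' BED is 0-based half-open; `rtracklayer` performs the conversion.
#'
#' @param path Path to a BED file.
#' @return Data frame with columns `chrom`, `start`, `end` (1-based inclusive).
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  granges_to_df(gr)
}

#' Write 1-based inclusive intervals to a BED file
#'
#' @param intervals Data frame with `chrom`, `start`, `end` (1-based inclusive).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  rtracklayer::export(as_granges(intervals), path, format = "BED")
  invisible(path)
}
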