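#' Construct a peak set
#'
#' A peak set is a labelled collection of unstranded genomic intervals:
#' the peak calls for one antibody (`mark`) in one condition
#' (`group` x `timepoint`). Coordinates are 0-based half-open, the native
#' BED convention.
#'
#' @param peaks A `data.frame` with columns `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param mark One of `pipeline_vocab()$marks`.
#' @param group One of `pipeline_vocab()$groups`.
#' @param timepoint One of `pipeline_vocab()$timepoints`.
#' @return An object of class `peak_set`.
#' @export
#' @examples
#' ps <- peak_set(data.frame(chrom = "chr1", start = 100L, end = 200L),
#'                mark = "TF", group = "OIR", timepoint = "P14")
#' ps$mark
peak_set <- function(peaks, mark, group, timepoint) {
  stopifnot(is.data.frame(peaks), all(c("chrom", "start", "end") %in% names(peaks)))
  mark <- match.arg(mark, MARK_LEVELS)
  group <- match.arg(group, GROUP_LEVELS)
  timepoint <- match.arg(timepoint, TIMEPOINT_LEVELS)
  peaks <- data.frame(
    chrom = as.character(peaks$chrom),
    start = as.integer(peaks$start),
    end = as.integer(peaks$end),
    stringsAsFactors = FALSE
  )
  if (nrow(peaks) && any(peaks$start < 0L | peaks$end <= peaks$start)) {
    stop("invalid peak interval: need 0 <= start < end")
  }
  structure(
    list(mark = mark, group = group, timepoint = timepoint, peaks = peaks),
    class = "peak_set"
  )
}

#' @exportS3Method base::print
print.peak_set <- function(x, ...) {
  cat(sprintf("<peak_set> %s / %s %s: %d peaks\n",
              x$mark, x$group, x$timepoint, nrow(x$peaks)))
  invisible(x)
}

#' Read peak calls from BED3 or ENCODE narrowPeak
#'
#' Both dialects are 0-based half-open; intervals are preserved exactly.
#' narrowPeak's seven extra columns are tolerated and ignored. Column count
#' is detected from the first data line.
#'
#' @param path Path to a BED3 or narrowPeak file.
#' @inheritParams peak_set
#' @return A [peak_set()].
#' @export
read_peaks <- function(path, mark, group, timepoint) {
  mark <- match.arg(mark, MARK_LEVELS)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) {
    return(peak_set(data.frame(chrom = character(), start = integer(),
                               end = integer()), mark, group, timepoint))
  }
  ncol1 <- length(strsplit(first, "\t", fixed = TRUE)[[1L]])
  # validate coordinates before the rtracklayer import so end <= start gets
  # a clear error rather than a negative-width failure
  raw <- utils::read.table(path, sep = "\t", colClasses = c("character", "integer",
                           "integer", rep("NULL", max(0L, ncol1 - 3L))))
  if (any(raw[[3L]] <= raw[[2L]])) {
    bad <- which(raw[[3L]] <= raw[[2L]])[1L]
    stop("invalid interval at line ", bad, ": end <= start")
  }
  gr <- if (ncol1 >= 10L) {
    rtracklayer::import(path, format = "BED",
                        extraCols = c(signalValue = "numeric", pValue = "numeric",
                                      qValue = "numeric", peak = "integer"))
  } else {
    rtracklayer::import(path, format = "BED")
  }
  peak_set(
    data.frame(
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,  # back to BED 0-based
      end = GenomicRanges::end(gr),
      stringsAsFactors = FALSE
    ),
    mark, group, timepoint
  )
}

#' Write a peak set as BED3
#'
#' Inverse of [read_peaks()] for the BED3 dialect: three tab-separated
#' columns, 0-based half-open, no header.
#'
#' @param x A [peak_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(x, path) {
  stopifnot(inherits(x, "peak_set"))
  writeLines(sprintf("%s\t%d\t%d", x$peaks$chrom, x$peaks$start, x$peaks$end),
             path)
  invisible(path)
}

## GRanges view of a peak set (1-based for IRanges machinery)
peaks_as_granges <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$peaks$chrom,
    ranges = IRanges::IRanges(start = x$peaks$start + 1L, end = x$peaks$end),
    strand = "*"
  )
}
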