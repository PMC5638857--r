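#' Construct a table of genomic intervals
#'
#' All coordinate arithmetic in the package uses a single convention:
#' 0-based half-open `[start, end)` intervals, the BED convention. Coordinates
#' printed in genome browsers and papers (1-based, fully inclusive) are
#' converted at the I/O boundary by [printed_to_interval()] /
#' [interval_to_printed()].
#'
#' @param chrom Chromosome / scaffold name.
#' @param start 0-based inclusive start.
#' @param end 0-based exclusive end; must satisfy `start < end`.
#' @param strand One of `"+"`, `"-"`, `"*"` (unstranded).
#' @param name Optional feature name.
#' @return A tibble with columns `chrom`, `start`, `end`, `strand` (and `name`
#'   when supplied).
#' @export
#' @examples
#' genomic_interval("chr7", 102509689, 102511671)
genomic_interval <- function(chrom, start, end, strand = "*", name = NULL) {
  out <- tibble(chrom = as.character(chrom),
                start = as.numeric(start),
                end = as.numeric(end),
                strand = as.character(strand))
  if (!is.null(name)) out$name <- as.character(name)
  validate_intervals(out)
  out
}

validate_intervals <- function(x, what = "interval") {
  stopifnot(all(c("chrom", "start", "end") %in% names(x)))
  bad <- which(!(x$start >= 0 & x$start < x$end))
  if (length(bad) > 0) {
    abort(sprintf("invalid %s at row %d: need 0 <= start < end (got start=%s, end=%s)",
                  what, bad[1], format(x$start[bad[1]], scientific = FALSE),
                  format(x$end[bad[1]], scientific = FALSE)))
  }
  if ("strand" %in% names(x) && !all(x$strand %in% c("+", "-", "*", "."))) {
    abort(sprintf("invalid strand in %s", what))
  }
  invisible(x)
}

#' Convert printed (1-based inclusive) coordinates to internal intervals
#'
#' @param chrom Chromosome name.
#' @param start_1based,end_1based Printed 1-based inclusive coordinates.
#' @param strand Strand, default unstranded.
#' @return A tibble of internal 0-based half-open intervals.
#' @export
#' @examples
#' # the 1982-bp element deletion as printed for mm10
#' printed_to_interval("chr7", 102509690, 102511671)
printed_to_interval <- function(chrom, start_1based, end_1based, strand = "*") {
  if (any(start_1based > end_1based)) abort("printed start exceeds end")
  if (any(start_1based < 1)) abort("printed coordinates are 1-based; start must be >= 1")
  genomic_interval(chrom, start_1based - 1, end_1based, strand)
}

#' Convert internal intervals back to printed coordinates
#'
#' The inverse of [printed_to_interval()]: an involution together with it.
#'
#' @param intervals Tibble of internal intervals.
#' @return Tibble with `chrom`, `start_1based`, `end_1based`.
#' @export
interval_to_printed <- function(intervals) {
  validate_intervals(intervals)
  tibble(chrom = intervals$chrom,
         start_1based = intervals$start + 1,
         end_1based = intervals$end)
}

#' Length of an interval from printed 1-based inclusive coordinates
#'
#' @param start_1based,end_1based Printed coordinates (vectors allowed).
#' @return Integer length(s) `end - start + 1`.
#' @export
#' @examples
#' interval_length_from_printed(102509690, 102511671) # 1982
#' interval_length_from_printed(102509921, 102510350) # 430
interval_length_from_printed <- function(start_1based, end_1based) {
  if (any(start_1based > end_1based)) abort("start exceeds end in printed coordinates")
  end_1based - start_1based + 1
}

#' Interval lengths under the internal convention
#' @param intervals Tibble of intervals.
#' @return Numeric vector `end - start`.
#' @export
interval_length <- function(intervals) {
  intervals$end - intervals$start
}
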