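#' Read a BED3-BED6 file
#'
#' BED files are 0-based half-open, matching the package's internal
#' convention, so coordinates are preserved exactly. Lines starting with
#' `track`, `browser` or `#` are skipped.
#'
#' @param path Path to a BED file.
#' @return A tibble with columns `chrom`, `start`, `end` and, when present in
#'   the file, `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[!grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- unique(lengths(fields))
  if (length(ncol) != 1 || ncol[1] < 3 || ncol[1] > 6) {
    abort("BED input must have a constant 3-6 tab-separated columns")
  }
  ncol <- ncol[1]
  m <- do.call(rbind, fields)
  out <- tibble(chrom = m[, 1],
                start = as.numeric(m[, 2]),
                end = as.numeric(m[, 3]))
  if (ncol >= 4) out$name <- m[, 4]
  if (ncol >= 5) out$score <- suppressWarnings(as.numeric(m[, 5]))
  if (ncol >= 6) out$strand <- m[, 6]
  validate_intervals(out, what = "BED record")
  out
}

#' Write intervals to a BED file
#'
#' Writes BED3 to BED6 depending on which of `name`, `score`, `strand` are
#' present. Round-trips through [read_bed()] byte-equivalently.
#'
#' @param intervals Tibble of intervals.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_bed <- function(intervals, path) {
  validate_intervals(intervals, what = "BED record")
  cols <- list(intervals$chrom,
               format(intervals$start, scientific = FALSE, trim = TRUE),
               format(intervals$end, scientific = FALSE, trim = TRUE))
  if ("strand" %in% names(intervals)) {
    cols <- c(cols, list(
      if ("name" %in% names(intervals)) intervals$name else rep(".", nrow(intervals)),
      if ("score" %in% names(intervals)) {
        format(dplyr::coalesce(intervals$score, 0), scientific = FALSE, trim = TRUE)
      } else rep("0", nrow(intervals)),
      ifelse(intervals$strand %in% c("+", "-"), intervals$strand, ".")))
  } else if ("score" %in% names(intervals)) {
    cols <- c(cols, list(
      if ("name" %in% names(intervals)) intervals$name else rep(".", nrow(intervals)),
      format(dplyr::coalesce(intervals$score, 0), scientific = FALSE, trim = TRUE)))
  } else if ("name" %in% names(intervals)) {
    cols <- c(cols, list(intervals$name))
  }
  lines <- do.call(paste, c(cols, sep = "\t"))
  readr::write_lines(lines, path)
  invisible(path)
}
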