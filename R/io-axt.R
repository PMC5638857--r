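#' Read a UCSC AXT pairwise-alignment file
#'
#' The AXT dialect stores one block as a 9-field summary line
#' (`index refChrom refStart refEnd queryChrom queryStart queryEnd strand
#' score`), a gapped reference row and a gapped query row, followed by a blank
#' line. Coordinates are 1-based inclusive; for minus-strand blocks the query
#' coordinates are given in reverse-complement space. On read, all coordinates
#' are normalized to the internal 0-based half-open convention and
#' minus-strand query anchors are converted to forward-strand genome
#' coordinates (which requires `query_sizes`). Soft-masked (lower-case) bases
#' are preserved.
#'
#' @param path Path to an AXT file.
#' @param query_sizes Named numeric vector of query chromosome lengths,
#'   required when the file contains minus-strand blocks.
#' @return A tibble of alignment blocks with columns `ref_chrom`, `ref_start`,
#'   `ref_end`, `query_chrom`, `query_start`, `query_end` (forward strand,
#'   0-based half-open), `query_strand`, `score`, `ref_row`, `query_row`.
#' @export
read_axt <- function(path, query_sizes = NULL) {
  lines <- readr::read_lines(path)
  keep <- !grepl("^#", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  # strip trailing blank lines, then group into blocks of 3 separated by blanks
  nz <- nzchar(trimws(lines))
  recs <- list()
  i <- 1
  while (i <= length(lines)) {
    if (!nz[i]) { i <- i + 1; next }
    if (i + 2 > length(lines) || !nz[i + 1] || !nz[i + 2]) {
      abort(sprintf("malformed AXT block starting at line %d: expected header plus two sequence rows", lineno[i]))
    }
    hdr <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(hdr) != 9) {
      abort(sprintf("malformed AXT header at line %d: expected 9 fields, got %d", lineno[i], length(hdr)))
    }
    ref_row <- lines[i + 1]
    query_row <- lines[i + 2]
    if (nchar(ref_row) != nchar(query_row)) {
      abort(sprintf("AXT row-length mismatch at line %d: %d vs %d columns",
                    lineno[i + 1], nchar(ref_row), nchar(query_row)))
    }
    if (grepl("[^ACGTRYSWKMBDHVNacgtryswkmbdhvn.-]", ref_row)) {
      abort(sprintf("non-IUPAC character in AXT sequence at line %d", lineno[i + 1]))
    }
    if (grepl("[^ACGTRYSWKMBDHVNacgtryswkmbdhvn.-]", query_row)) {
      abort(sprintf("non-IUPAC character in AXT sequence at line %d", lineno[i + 2]))
    }
    recs[[length(recs) + 1]] <- list(hdr = hdr, ref_row = ref_row,
                                     query_row = query_row, line = lineno[i])
    i <- i + 3
  }
  if (length(recs) == 0) return(empty_blocks())
  blocks <- purrr::map_dfr(recs, function(r) {
    h <- r$hdr
    strand <- h[8]
    if (!strand %in% c("+", "-")) {
      abort(sprintf("invalid strand '%s' in AXT header at line %d", strand, r$line))
    }
    q_start1 <- as.numeric(h[6]); q_end1 <- as.numeric(h[7])
    if (strand == "-") {
      if (is.null(query_sizes) || is.na(query_sizes[h[5]])) {
        abort(sprintf(
          "minus-strand AXT block at line %d: query_sizes must supply the length of '%s' to convert to forward-strand coordinates",
          r$line, h[5]))
      }
      size <- query_sizes[[h[5]]]
      q_fwd_start <- size - q_end1       # 0-based
      q_fwd_end <- size - q_start1 + 1   # half-open
    } else {
      q_fwd_start <- q_start1 - 1
      q_fwd_end <- q_end1
    }
    tibble(ref_chrom = h[2], ref_start = as.numeric(h[3]) - 1, ref_end = as.numeric(h[4]),
           query_chrom = h[5], query_start = q_fwd_start, query_end = q_fwd_end,
           query_strand = strand, score = as.numeric(h[9]),
           ref_row = r$ref_row, query_row = r$query_row)
  })
  validate_blocks(blocks)
  blocks
}

empty_blocks <- function() {
  tibble(ref_chrom = character(), ref_start = numeric(), ref_end = numeric(),
         query_chrom = character(), query_start = numeric(), query_end = numeric(),
         query_strand = character(), score = numeric(),
         ref_row = character(), query_row = character())
}

validate_blocks <- function(blocks) {
  if (nrow(blocks) == 0) return(invisible(blocks))
  for (i in seq_len(nrow(blocks))) {
    rr <- blocks$ref_row[i]; qr <- blocks$query_row[i]
    if (nchar(rr) != nchar(qr)) abort(sprintf("block %d: unequal row lengths", i))
    rch <- str_chars(rr); qch <- str_chars(qr)
    if (any(is_gap(rch) & is_gap(qch))) abort(sprintf("block %d: column gapped in both rows", i))
    if (sum(!is_gap(rch)) != blocks$ref_end[i] - blocks$ref_start[i]) {
      abort(sprintf("block %d: reference row has %d bases but the interval spans %d",
                    i, sum(!is_gap(rch)), blocks$ref_end[i] - blocks$ref_start[i]))
    }
    if (sum(!is_gap(qch)) != blocks$query_end[i] - blocks$query_start[i]) {
      abort(sprintf("block %d: query row has %d bases but the interval spans %d",
                    i, sum(!is_gap(qch)), blocks$query_end[i] - blocks$query_start[i]))
    }
  }
  invisible(blocks)
}

#' Write alignment blocks to a UCSC AXT file
#'
#' The inverse of [read_axt()]: internal 0-based half-open coordinates are
#' converted back to the 1-based inclusive AXT dialect, and minus-strand query
#' anchors back to reverse-complement space (requiring `query_sizes`).
#'
#' @param blocks Tibble of alignment blocks as returned by [read_axt()].
#' @param path Output path.
#' @param query_sizes Named numeric vector of query chromosome lengths,
#'   required when minus-strand blocks are present.
#' @return The path, invisibly.
#' @export
write_axt <- function(blocks, path, query_sizes = NULL) {
  validate_blocks(blocks)
  out <- character(0)
  for (i in seq_len(nrow(blocks))) {
    b <- blocks[i, ]
    if (b$query_strand == "-") {
      if (is.null(query_sizes) || is.na(query_sizes[b$query_chrom])) {
        abort("query_sizes needed to write minus-strand blocks")
      }
      size <- query_sizes[[b$query_chrom]]
      q1 <- size - b$query_end + 1
      q2 <- size - b$query_start
    } else {
      q1 <- b$query_start + 1
      q2 <- b$query_end
    }
    hdr <- paste(i - 1, b$ref_chrom,
                 format(b$ref_start + 1, scientific = FALSE),
                 format(b$ref_end, scientific = FALSE),
                 b$query_chrom,
                 format(q1, scientific = FALSE), format(q2, scientific = FALSE),
                 b$query_strand, format(b$score, scientific = FALSE))
    out <- c(out, hdr, b$ref_row, b$query_row, "")
  }
  readr::write_lines(out, path)
  invisible(path)
}
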