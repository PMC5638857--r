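#' The default OR-enhancer motif set
#'
#' The four degenerate motifs recurrent in odorant-receptor enhancer
#' elements: the homeodomain site `TAATKR`, the O/E-like site `YYYCARRRR`,
#' the class I-specific site `AAACTTTTC`, and the extended homeodomain site
#' `AACTTTTTAATGA`.
#'
#' @return Tibble with columns `name` and `pattern`.
#' @export
default_motifs <- function() {
  tibble(name = c("homeodomain", "oe_like", "class1_specific",
                  "extended_homeodomain"),
         pattern = c("TAATKR", "YYYCARRRR", "AAACTTTTC", "AACTTTTTAATGA"))
}

iupac_regex <- function(pattern) {
  chars <- str_chars(toupper(pattern))
  bad <- setdiff(chars, names(IUPAC_CLASSES))
  if (length(bad) > 0) {
    abort(sprintf("invalid IUPAC character(s) in motif pattern: %s",
                  paste(unique(bad), collapse = ", ")))
  }
  paste(vapply(chars, function(ch) {
    cls <- IUPAC_CLASSES[[ch]]
    if (length(cls) == 1) cls else paste0("[", paste(cls, collapse = ""), "]")
  }, character(1)), collapse = "")
}

scan_one_strand <- function(seq_upper, regex) {
  # lookahead so overlapping occurrences are all reported
  m <- gregexpr(paste0("(?=", regex, ")"), seq_upper, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m)
}

#' Scan a sequence for degenerate (IUPAC) motifs on both strands
#'
#' Every position and strand where all of a pattern's IUPAC classes match is
#' reported exactly once, including overlapping occurrences. Matching is
#' case-insensitive; `N` in the target sequence matches nothing, while `N` in
#' a pattern matches any base. Minus-strand occurrences are found by matching
#' against the reverse complement and are reported in forward-strand
#' coordinates with the forward-strand spelling of the matched bases.
#'
#' @param sequence A single nucleotide string.
#' @param motifs Tibble with `name` and `pattern` columns
#'   (default [default_motifs()]).
#' @param both_strands Scan the minus strand too (default TRUE).
#' @return Tibble of hits: `motif_name`, `position` (0-based leftmost base on
#'   the forward strand), `strand`, `matched_sequence`.
#' @export
#' @examples
#' iupac_scan("AACTTTTTAATGA", default_motifs())
iupac_scan <- function(sequence, motifs = default_motifs(), both_strands = TRUE) {
  stopifnot(length(sequence) == 1)
  su <- toupper(sequence)
  L <- nchar(su)
  rc <- if (both_strands) toupper(revcomp(su)) else NULL
  hits <- purrr::map_dfr(seq_len(nrow(motifs)), function(i) {
    pat <- motifs$pattern[i]
    k <- nchar(pat)
    rx <- iupac_regex(pat)
    fwd <- scan_one_strand(su, rx) - 1L
    out <- tibble(motif_name = motifs$name[i], position = as.numeric(fwd),
                  strand = rep("+", length(fwd)))
    if (both_strands) {
      rpos <- scan_one_strand(rc, rx)            # 1-based on the reverse strand
      fpos <- L - (rpos - 1L) - k                # 0-based forward leftmost base
      out <- dplyr::bind_rows(out, tibble(motif_name = motifs$name[i],
                                          position = as.numeric(fpos),
                                          strand = rep("-", length(fpos))))
    }
    out$matched_sequence <- substr(rep(sequence, nrow(out)),
                                   out$position + 1, out$position + k)
    out
  })
  dplyr::arrange(hits, .data$position, .data$strand, .data$motif_name)
}

#' Locate the motif-dense core window of an element
#'
#' Finds the fixed-width window containing the largest number of motif hits,
#' requiring hits from at least `min_motif_classes` distinct motifs (by
#' default two, reflecting the clustering of homeodomain and O/E-like sites
#' that defines enhancer cores). Ties are broken by the leftmost window.
#'
#' @param hits Tibble of hits from [iupac_scan()].
#' @param sequence_length Length of the scanned sequence.
#' @param window Window width in bp (default 430).
#' @param min_motif_classes Minimum number of distinct motif names that must
#'   be represented (default 2).
#' @return A list with `interval` (tibble `start`, `end`) and `hits` (the
#'   contained hits), or `NULL` when no window qualifies.
#' @export
find_core_window <- function(hits, sequence_length, window = 430,
                             min_motif_classes = 2) {
  stopifnot(window <= sequence_length)
  if (nrow(hits) == 0) return(NULL)
  len <- nchar(hits$matched_sequence)
  clamp <- function(x) pmax(0, pmin(x, sequence_length - window))
  cand <- sort(unique(c(0, clamp(hits$position), clamp(hits$position + len - window))))
  best <- NULL
  for (s in cand) {
    inside <- hits$position >= s & (hits$position + len) <= s + window
    n_in <- sum(inside)
    n_classes <- length(unique(hits$motif_name[inside]))
    if (n_classes < min_motif_classes) next
    if (is.null(best) || n_in > best$n) {
      best <- list(s = s, n = n_in, inside = inside)
    }
  }
  if (is.null(best)) return(NULL)
  list(interval = tibble(start = best$s, end = best$s + window),
       hits = hits[best$inside, ])
}
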