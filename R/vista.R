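#' Sliding-window percent-identity profile of a pairwise alignment
#'
#' For every reference base of `region`, computes the percent identity over a
#' window of `window` consecutive reference bases centered on it (truncated at
#' the region edges, with the denominator shrunk accordingly). Reference bases
#' that are unaligned, opposite a query gap, or paired with an ambiguity code
#' count as mismatches, so coverage gaps depress the curve just as they do in
#' browser identity plots. With `mask_lowercase = TRUE`, soft-masked
#' (lower-case) reference bases also count as mismatches.
#'
#' The window of width `w` centered at position `p` spans
#' `[p - floor((w-1)/2), p + ceiling((w-1)/2)]` in reference coordinates.
#'
#' @param blocks Alignment blocks tibble.
#' @param region One-row tibble with `chrom`, `start`, `end`.
#' @param window Window width in reference bases (default 100).
#' @param mask_lowercase Treat soft-masked reference bases as unalignable.
#' @return An `identity_profile` object: a tibble with `chrom`, `ref_pos` and
#'   `identity_pct`, carrying the window as an attribute.
#' @export
windowed_identity <- function(blocks, region, window = 100, mask_lowercase = FALSE) {
  stopifnot(window >= 1)
  pairs <- extract_element_alignment(region, blocks)
  ru <- toupper(pairs$ref_char)
  qu <- toupper(pairs$query_char)
  m <- as.numeric(pairs$aligned &
                    ru %in% c("A", "C", "G", "T") & qu %in% c("A", "C", "G", "T") &
                    ru == qu)
  if (mask_lowercase) {
    soft <- !is.na(pairs$ref_char) & pairs$ref_char %in% c("a", "c", "g", "t", "n")
    m[soft] <- 0
  }
  m[is.na(m)] <- 0
  n <- length(m)
  left <- floor((window - 1) / 2)
  right <- window - 1 - left
  cs <- c(0, cumsum(m))
  i <- seq_len(n)
  lo <- pmax(1, i - left)
  hi <- pmin(n, i + right)
  pct <- 100 * (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  out <- tibble(chrom = region$chrom[1], ref_pos = pairs$ref_pos, identity_pct = pct)
  structure(out, window = window, class = c("identity_profile", class(out)))
}

#' Call conserved segments from an identity profile
#'
#' Maximal runs of consecutive positions whose windowed identity is at or
#' above `threshold_pct` are reported when the run is at least `min_width`
#' bp long. The defaults (70% identity, 100 bp window and minimum width)
#' are the standard browser settings for detecting conserved non-coding
#' elements; 50 bp for both is the sensitive variant used for distant
#' comparisons.
#'
#' @param profile An `identity_profile` from [windowed_identity()].
#' @param threshold_pct Identity threshold in percent (default 70).
#' @param min_width Minimum segment width in bp (default 100).
#' @return Tibble of segments: `chrom`, `start`, `end`, `mean_identity_pct`.
#' @export
call_conserved_segments <- function(profile, threshold_pct = 70, min_width = 100) {
  ok <- profile$identity_pct >= threshold_pct
  if (length(ok) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  mean_identity_pct = numeric()))
  }
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= min_width
  out <- purrr::map_dfr(which(keep), function(k) {
    idx <- starts[k]:ends[k]
    tibble(chrom = profile$chrom[1],
           start = profile$ref_pos[starts[k]],
           end = profile$ref_pos[ends[k]] + 1,
           mean_identity_pct = mean(profile$identity_pct[idx]))
  })
  if (nrow(out) == 0) {
    out <- tibble(chrom = character(), start = numeric(), end = numeric(),
                  mean_identity_pct = numeric())
  }
  out
}

#' Classify conserved segments by annotation overlap
#'
#' Assigns each segment the category with which it shares the most bases:
#' `coding_exon`, `noncoding_exon` or `intergenic`. Overlaps are computed on
#' the per-category union of annotation intervals; ties favour coding over
#' noncoding exons, and segments overlapping nothing are intergenic.
#'
#' @param segments Tibble of segments (`chrom`, `start`, `end`).
#' @param annotations Tibble with `chrom`, `start`, `end`, `feature_type`
#'   (values `coding_exon`, `noncoding_exon`, `gene_body`).
#' @return `segments` with a `category` column added.
#' @export
classify_segment <- function(segments, annotations) {
  overlap_with <- function(seg, ints) {
    if (nrow(ints) == 0) return(0)
    ints <- ints[ints$chrom == seg$chrom, , drop = FALSE]
    if (nrow(ints) == 0) return(0)
    # merge to a union so stacked annotations do not double-count
    ints <- ints[order(ints$start), ]
    merged_start <- ints$start[1]; merged_end <- ints$end[1]
    total <- 0
    flush <- function(s, e) max(0, min(e, seg$end) - max(s, seg$start))
    if (nrow(ints) > 1) {
      for (i in 2:nrow(ints)) {
        if (ints$start[i] <= merged_end) {
          merged_end <- max(merged_end, ints$end[i])
        } else {
          total <- total + flush(merged_start, merged_end)
          merged_start <- ints$start[i]; merged_end <- ints$end[i]
        }
      }
    }
    total + flush(merged_start, merged_end)
  }
  cat_of <- function(seg) {
    exonic <- annotations[annotations$feature_type %in% c("coding_exon", "noncoding_exon"), ]
    cod <- overlap_with(seg, annotations[annotations$feature_type == "coding_exon", ])
    non <- overlap_with(seg, annotations[annotations$feature_type == "noncoding_exon", ])
    inter <- (seg$end - seg$start) - overlap_with(seg, exonic)
    best <- max(cod, non, inter)
    # priority on ties: coding > noncoding > intergenic
    if (cod == best) "coding_exon" else if (non == best) "noncoding_exon" else "intergenic"
  }
  segments$category <- vapply(seq_len(nrow(segments)), function(i) {
    cat_of(segments[i, ])
  }, character(1))
  segments
}
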