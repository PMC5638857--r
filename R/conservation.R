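#' Per-column view of one alignment block
#'
#' Expands a gapped block into one row per alignment column, annotating each
#' column with the reference and query genome positions of its bases (NA at
#' gaps). Query positions are always forward-strand.
#'
#' @param block One-row tibble as produced by [read_axt()].
#' @return Tibble with `ref_pos`, `ref_char`, `query_char`, `query_pos`.
#' @keywords internal
block_columns <- function(block) {
  rch <- str_chars(block$ref_row)
  qch <- str_chars(block$query_row)
  ref_ng <- !is_gap(rch)
  q_ng <- !is_gap(qch)
  ref_pos <- rep(NA_real_, length(rch))
  ref_pos[ref_ng] <- block$ref_start + seq_len(sum(ref_ng)) - 1
  qidx <- cumsum(q_ng)
  query_pos <- rep(NA_real_, length(qch))
  if (block$query_strand == "+") {
    query_pos[q_ng] <- block$query_start + qidx[q_ng] - 1
  } else {
    # rows are in reverse-complement orientation: query coordinates descend
    query_pos[q_ng] <- block$query_end - qidx[q_ng]
  }
  tibble(ref_pos = ref_pos, ref_char = rch, query_char = qch,
         query_pos = query_pos)
}

#' Extract the aligned columns covering a reference element
#'
#' For each reference base of the element the aligned query character is
#' returned: a nucleotide, a gap (`-`) when the base aligns opposite a query
#' gap, or `NA` when no block covers it. When blocks overlap on the
#' reference, the first block in file order wins (UCSC net AXT files are
#' single-coverage so this rarely triggers); a message is emitted.
#'
#' @param element One-row tibble (or list) with `chrom`, `start`, `end`.
#' @param blocks Alignment blocks tibble.
#' @return Tibble with one row per element reference base: `ref_pos`,
#'   `ref_char`, `query_char`, `query_chrom`, `query_pos`, `aligned`.
#' @export
extract_element_alignment <- function(element, blocks) {
  el_start <- element$start[1]; el_end <- element$end[1]; el_chrom <- element$chrom[1]
  hit <- blocks[blocks$ref_chrom == el_chrom &
                  blocks$ref_end > el_start & blocks$ref_start < el_end, , drop = FALSE]
  all_pos <- tibble(ref_pos = seq(el_start, el_end - 1))
  if (nrow(hit) == 0) {
    return(dplyr::mutate(all_pos, ref_char = NA_character_,
                         query_char = NA_character_,
                         query_chrom = NA_character_, query_pos = NA_real_,
                         aligned = FALSE))
  }
  cols <- purrr::map_dfr(seq_len(nrow(hit)), function(i) {
    cc <- block_columns(hit[i, ])
    cc <- cc[!is.na(cc$ref_pos) & cc$ref_pos >= el_start & cc$ref_pos < el_end, ]
    cc$query_chrom <- hit$query_chrom[i]
    cc
  })
  if (anyDuplicated(cols$ref_pos)) {
    inform("overlapping alignment blocks: keeping the first block in file order per reference base")
    cols <- cols[!duplicated(cols$ref_pos), ]
  }
  out <- dplyr::left_join(all_pos, cols, by = "ref_pos")
  out$aligned <- !is.na(out$query_char) & !is_gap(out$query_char)
  out
}

#' Coverage and identity of an element from its aligned columns
#'
#' `A` counts element reference bases aligned to a query *nucleotide*
#' (bases opposite query gaps or outside every block are excluded).
#' Coverage is `A / L`; identity is the fraction of those `A` pairs that are
#' identical, compared case-insensitively. Pairs involving an ambiguity code
#' count as aligned but never as identical. Identity is undefined (`NA`) when
#' `A = 0`.
#'
#' @param pairs Output of [extract_element_alignment()].
#' @param L Element length in bp.
#' @return One-row tibble with `L`, `A`, `coverage`, `identity`.
#' @export
coverage_identity <- function(pairs, L) {
  stopifnot(L > 0)
  aligned <- !is.na(pairs$query_char) & !is_gap(pairs$query_char)
  A <- sum(aligned)
  ru <- toupper(pairs$ref_char)
  qu <- toupper(pairs$query_char)
  match <- aligned & ru %in% c("A", "C", "G", "T") & qu %in% c("A", "C", "G", "T") & ru == qu
  identity <- if (A > 0) sum(match) / A else NA_real_
  tibble(L = L, A = A, coverage = A / L, identity = identity)
}

#' Conservation index from coverage and identity
#'
#' The single-number conservation score for an element against one species:
#' `(coverage[%] x identity[%]) / 100`, ranging 0-100. When identity is
#' undefined (no aligned bases) the index is 0.
#'
#' @param coverage,identity Fractions in `[0, 1]` (vectors allowed).
#' @return Numeric vector in `[0, 100]`.
#' @export
#' @examples
#' conservation_index(0.8, 0.9) # 72
conservation_index <- function(coverage, identity) {
  stopifnot(all(coverage >= 0 & coverage <= 1),
            all(is.na(identity) | (identity >= 0 & identity <= 1)))
  idx <- (100 * coverage) * (100 * identity) / 100
  idx[is.na(identity)] <- 0
  idx
}

#' Score conservation of candidate elements across species
#'
#' Runs [extract_element_alignment()] and [coverage_identity()] for every
#' (element, species) pair, recording whether a syntenic region was found
#' (any aligned base) and the forward-strand span of the element's aligned
#' query region, which is used as the element's location in that species for
#' OR-gene linkage.
#'
#' @param elements Tibble of elements with `chrom`, `start`, `end`, `name`.
#' @param alignments Named list (by species) of alignment-block tibbles.
#' @return Tibble with one row per (element, species): `element_id`,
#'   `species`, `L`, `A`, `coverage`, `identity`, `conservation_index`,
#'   `syntenic_found`, `query_chrom`, `query_start`, `query_end`.
#' @export
score_conservation <- function(elements, alignments) {
  ids <- if ("name" %in% names(elements)) elements$name else
    sprintf("element_%03d", seq_len(nrow(elements)))
  purrr::map_dfr(seq_len(nrow(elements)), function(i) {
    el <- elements[i, ]
    purrr::map_dfr(names(alignments), function(sp) {
      pairs <- extract_element_alignment(el, alignments[[sp]])
      ci <- coverage_identity(pairs, el$end - el$start)
      apos <- pairs$query_pos[pairs$aligned]
      achr <- pairs$query_chrom[pairs$aligned]
      tibble(element_id = ids[i], species = sp,
             L = ci$L, A = ci$A, coverage = ci$coverage, identity = ci$identity,
             conservation_index = conservation_index(ci$coverage, ci$identity),
             syntenic_found = ci$A > 0,
             query_chrom = if (ci$A > 0) achr[1] else NA_character_,
             query_start = if (ci$A > 0) min(apos) else NA_real_,
             query_end = if (ci$A > 0) max(apos) + 1 else NA_real_)
    })
  })
}

#' Retain elements with a syntenic region in every species
#'
#' An element is eliminated as poorly conserved if its syntenic region is
#' missing from even one of the pairwise alignments. A missing
#' (element, species) record counts as not found and is reported.
#'
#' @param records Conservation records from [score_conservation()].
#' @param species_list Character vector of required species.
#' @return Character vector of retained element ids.
#' @export
filter_all_species <- function(records, species_list) {
  ids <- unique(records$element_id)
  grid <- tidyr::expand_grid(element_id = ids, species = species_list)
  merged <- dplyr::left_join(grid,
                             records[, c("element_id", "species", "syntenic_found")],
                             by = c("element_id", "species"))
  if (anyNA(merged$syntenic_found)) {
    miss <- merged[is.na(merged$syntenic_found), ]
    inform(sprintf("%d missing (element, species) records treated as syntenic_found = FALSE (e.g. %s / %s)",
                   nrow(miss), miss$element_id[1], miss$species[1]))
    merged$syntenic_found[is.na(merged$syntenic_found)] <- FALSE
  }
  keep <- dplyr::summarise(dplyr::group_by(merged, .data$element_id),
                           all_found = all(.data$syntenic_found))
  sort(keep$element_id[keep$all_found])
}

#' Link elements to their nearest OR gene per species
#'
#' An element is linked in a species when an OR gene lies within
#' `max_distance` (edge-to-edge, overlap = 0; the boundary is inclusive) on
#' the same chromosome or scaffold of that species' assembly.
#'
#' @param element_locations Tibble with `element_id`, `species`, `query_chrom`,
#'   `query_start`, `query_end` (as produced by [score_conservation()]).
#' @param or_genes Named list (by species) of OR-gene tibbles with `chrom`,
#'   `start`, `end`, `name`.
#' @param max_distance Linkage threshold in bp (default 1 Mb).
#' @return Tibble with `element_id`, `species`, `nearest_or`, `distance`,
#'   `linked`.
#' @export
link_nearest_or <- function(element_locations, or_genes, max_distance = 1e6) {
  purrr::map_dfr(seq_len(nrow(element_locations)), function(i) {
    el <- element_locations[i, ]
    res <- tibble(element_id = el$element_id, species = el$species,
                  nearest_or = NA_character_, distance = NA_real_, linked = FALSE)
    genes <- or_genes[[el$species]]
    if (is.null(genes) || is.na(el$query_chrom)) return(res)
    genes <- genes[genes$chrom == el$query_chrom, , drop = FALSE]
    if (nrow(genes) == 0) return(res)
    d <- pmax(0, genes$start - el$query_end, el$query_start - genes$end)
    j <- which.min(d)
    res$nearest_or <- if ("name" %in% names(genes)) genes$name[j] else sprintf("OR_%d", j)
    res$distance <- d[j]
    res$linked <- d[j] <= max_distance
    res
  })
}

#' Rank elements by conservation index
#'
#' Summarises each element's per-species conservation indices by their mean
#' and minimum across species and sorts descending by mean index, ties broken
#' by element id.
#'
#' @param records Conservation records from [score_conservation()].
#' @param element_ids Optional subset of element ids (e.g. the filtered set).
#' @return Tibble with `element_id`, `mean_index`, `min_index`, `n_species`,
#'   `rank_mean`, `rank_min`.
#' @export
rank_elements <- function(records, element_ids = NULL) {
  if (!is.null(element_ids)) records <- records[records$element_id %in% element_ids, ]
  out <- dplyr::summarise(dplyr::group_by(records, .data$element_id),
                          mean_index = mean(.data$conservation_index),
                          min_index = min(.data$conservation_index),
                          n_species = dplyr::n(), .groups = "drop")
  out <- dplyr::arrange(out, dplyr::desc(.data$mean_index), .data$element_id)
  out$rank_mean <- seq_len(nrow(out))
  out$rank_min <- order(order(-out$min_index, out$element_id))
  out
}
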