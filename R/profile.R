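#' Build an ungapped log-odds profile from a multiple alignment
#'
#' Columns with more than 50% gaps are dropped (the match-column rule); in
#' each retained column, nucleotide frequencies with pseudocounts are
#' converted to log2 odds against a background composition (by default the
#' composition observed across retained columns). The resulting model plays
#' the role of a profile HMM for retrieving the single best orthologous
#' placement of a short, indel-poor element in another genome.
#'
#' @param aligned Named character vector of equal-length aligned sequences,
#'   or a path to an aligned FASTA file. At least two records.
#' @param pseudocount Pseudocount added per nucleotide (default 1).
#' @param background Optional numeric vector of background probabilities
#'   named A, C, G, T; defaults to the observed composition.
#' @return A `profile_model` object.
#' @export
build_profile <- function(aligned, pseudocount = 1.0, background = NULL) {
  if (is.character(aligned) && length(aligned) == 1 && file.exists(aligned)) {
    src <- aligned
    aligned <- read_alignment_fasta(aligned)
  } else {
    src <- "in-memory alignment"
  }
  if (length(aligned) < 2) abort("need at least two aligned records")
  if (length(unique(nchar(aligned))) != 1) abort("aligned records have unequal lengths")
  mat <- do.call(rbind, lapply(toupper(aligned), str_chars))
  gap_frac <- colMeans(mat == "-" | mat == ".")
  mat <- mat[, gap_frac <= 0.5, drop = FALSE]
  if (ncol(mat) == 0) abort("no columns retained after the match-column rule")
  bases <- c("A", "C", "G", "T")
  counts <- vapply(bases, function(b) colSums(mat == b), numeric(ncol(mat)))
  counts <- matrix(counts, ncol = 4, dimnames = list(NULL, bases))
  if (is.null(background)) {
    tot <- colSums(counts) + pseudocount
    background <- tot / sum(tot)
  }
  background <- background[bases] / sum(background[bases])
  probs <- (counts + pseudocount) / (rowSums(counts) + 4 * pseudocount)
  log_odds <- log2(sweep(probs, 2, background, "/"))
  consensus <- paste(bases[max.col(probs, ties.method = "first")], collapse = "")
  structure(list(log_odds = log_odds, probs = probs, background = background,
                 pseudocount = pseudocount, length = nrow(log_odds),
                 n_seqs = length(aligned), consensus = consensus,
                 source_alignment_id = src),
            class = "profile_model")
}

#' @export
print.profile_model <- function(x, ...) {
  cat(sprintf("<profile_model> %d positions from %d sequences (%s)\n",
              x$length, x$n_seqs, x$source_alignment_id))
  cat("consensus:", x$consensus, "\n")
  invisible(x)
}

score_placements <- function(model, seq_upper) {
  bases <- c("A", "C", "G", "T")
  s <- match(str_chars(seq_upper), bases)       # NA for ambiguity codes
  m <- model$length
  L <- length(s)
  if (L < m) abort("sequence shorter than the profile")
  n <- L - m + 1
  scores <- numeric(n)
  for (j in seq_len(m)) {
    row <- c(model$log_odds[j, ], 0)            # ambiguity scores 0 (neutral)
    idx <- s[j:(j + n - 1)]
    idx[is.na(idx)] <- 5L
    scores <- scores + row[idx]
  }
  unname(scores)
}

#' Best-scoring placement of a profile model in a sequence
#'
#' Scores every ungapped placement of the model on both strands and returns
#' the highest scorer. Ties are resolved deterministically: leftmost forward
#' position first, `+` before `-`. Ambiguity codes in the target contribute a
#' neutral score of 0.
#'
#' @param model A `profile_model` from [build_profile()].
#' @param sequence Target nucleotide string.
#' @param both_strands Also scan the reverse complement (default TRUE).
#' @return One-row tibble with `position` (0-based forward-strand leftmost
#'   base), `strand` and `score`.
#' @export
profile_top_hit <- function(model, sequence, both_strands = TRUE) {
  su <- toupper(sequence)
  L <- nchar(su)
  m <- model$length
  fwd <- score_placements(model, su)
  cand <- tibble(position = seq_along(fwd) - 1, strand = "+", score = fwd)
  if (both_strands) {
    rev_scores <- score_placements(model, toupper(revcomp(su)))
    # placement q (0-based on the reverse strand) covers forward [L - q - m, ...)
    cand <- dplyr::bind_rows(cand, tibble(position = L - (seq_along(rev_scores) - 1) - m,
                                          strand = "-", score = rev_scores))
  }
  cand <- dplyr::arrange(cand, dplyr::desc(.data$score), .data$position, .data$strand)
  cand[1, ]
}

#' @method tidy profile_model
#' @export
tidy.profile_model <- function(x, ...) {
  lo <- as_tibble(x$log_odds)
  lo$position <- seq_len(nrow(lo)) - 1
  tidyr::pivot_longer(lo, cols = c("A", "C", "G", "T"),
                      names_to = "base", values_to = "log_odds")
}
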