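# Independent brute-force oracles. These deliberately re-derive everything
# from first principles (own IUPAC table, per-column walks, hypergeometric
# enumeration, sums of squares) so they share no code path with the package.

ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  ch <- rev(strsplit(toupper(s), "")[[1]])
  paste(comp[ch], collapse = "")
}

# tests every (position, strand) window independently
oracle_iupac_scan <- function(sequence, motifs) {
  su <- toupper(sequence)
  L <- nchar(su)
  window_ok <- function(s, pat) {
    sc <- strsplit(s, "")[[1]]
    pc <- strsplit(pat, "")[[1]]
    all(vapply(seq_along(pc), function(j) sc[j] %in% ORACLE_IUPAC[[pc[j]]],
               logical(1)))
  }
  out <- list()
  for (i in seq_len(nrow(motifs))) {
    pat <- motifs$pattern[i]; k <- nchar(pat)
    if (k > L) next
    for (pos in 0:(L - k)) {
      w <- substr(su, pos + 1, pos + k)
      if (window_ok(w, pat)) {
        out[[length(out) + 1]] <- data.frame(motif_name = motifs$name[i],
                                             position = pos, strand = "+")
      }
      if (window_ok(oracle_revcomp(w), pat)) {
        out[[length(out) + 1]] <- data.frame(motif_name = motifs$name[i],
                                             position = pos, strand = "-")
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(motif_name = character(), position = numeric(),
                      strand = character()))
  }
  res <- do.call(rbind, out)
  res[order(res$position, res$strand, res$motif_name), ]
}

# per-reference-base match flags recomputed by walking block rows column by
# column, then an O(n*w) per-window recount
oracle_match_vector <- function(blocks, region_start, region_end) {
  n <- region_end - region_start
  m <- rep(0, n)
  seen <- rep(FALSE, n)
  for (b in seq_len(nrow(blocks))) {
    rr <- strsplit(blocks$ref_row[b], "")[[1]]
    qr <- strsplit(blocks$query_row[b], "")[[1]]
    pos <- blocks$ref_start[b]
    for (j in seq_along(rr)) {
      if (rr[j] != "-") {
        idx <- pos - region_start + 1
        if (pos >= region_start && pos < region_end && !seen[idx]) {
          seen[idx] <- TRUE
          m[idx] <- as.numeric(toupper(rr[j]) == toupper(qr[j]) &&
                                 toupper(rr[j]) %in% c("A", "C", "G", "T") &&
                                 toupper(qr[j]) %in% c("A", "C", "G", "T"))
        }
        pos <- pos + 1
      }
    }
  }
  m
}

oracle_windowed_pct <- function(m, window) {
  n <- length(m)
  left <- floor((window - 1) / 2)
  vapply(seq_len(n), function(i) {
    idx <- max(1, i - left):min(n, i + (window - 1 - left))
    100 * mean(m[idx])
  }, numeric(1))
}

# two-sided Fisher p by full hypergeometric enumeration over fixed margins
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  xs <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(xs, r1, r2, c1)
  pobs <- dhyper(a, r1, r2, c1)
  sum(probs[probs <= pobs * (1 + 1e-7)])
}

# step-up BH computed by the textbook recipe
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# one-way ANOVA + Tukey HSD from sums of squares and the studentized range
oracle_anova_tukey <- function(groups) {
  k <- length(groups)
  ns <- lengths(groups)
  means <- vapply(groups, mean, numeric(1))
  grand <- sum(unlist(groups)) / sum(ns)
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  dfb <- k - 1; dfw <- sum(ns) - k
  msw <- ssw / dfw
  F <- (ssb / dfb) / msw
  p <- pf(F, dfb, dfw, lower.tail = FALSE)
  pairs <- combn(k, 2)
  tukey_p <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    se <- sqrt(msw / 2 * (1 / ns[i] + 1 / ns[j]))
    q <- abs(means[i] - means[j]) / se
    ptukey(q, k, dfw, lower.tail = FALSE)
  })
  list(F = F, p = p, tukey_p = tukey_p,
       comparison = apply(pairs, 2, function(ij)
         paste(names(groups)[ij[2]], names(groups)[ij[1]], sep = "-")))
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# hand-built alignment block from two gapped rows
make_block <- function(ref_row, query_row, ref_chrom = "chr1", ref_start = 0,
                       query_chrom = "chrQ", query_start = 0,
                       query_strand = "+") {
  rlen <- sum(strsplit(ref_row, "")[[1]] != "-")
  qlen <- sum(strsplit(query_row, "")[[1]] != "-")
  tibble::tibble(ref_chrom = ref_chrom, ref_start = ref_start,
                 ref_end = ref_start + rlen,
                 query_chrom = query_chrom, query_start = query_start,
                 query_end = query_start + qlen,
                 query_strand = query_strand, score = 0,
                 ref_row = ref_row, query_row = query_row)
}
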