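#' Percentile-shift normalization of a log2 intensity matrix
#'
#' Subtracts each sample's `q`-quantile so that, after normalization, every
#' sample's `q`-quantile is exactly zero. The default `q = 0.75` is the 75%
#' percentile shift commonly applied to expression-array intensities.
#'
#' @param intensities Numeric genes-by-samples matrix on the log2 scale.
#' @param q Quantile to shift to zero (default 0.75).
#' @return The normalized matrix.
#' @export
percentile_shift_normalize <- function(intensities, q = 0.75) {
  stopifnot(is.matrix(intensities), all(is.finite(intensities)))
  shifts <- apply(intensities, 2, quantile, probs = q, names = FALSE)
  sweep(intensities, 2, shifts, "-")
}

#' Two-sample test for one gene
#'
#' Computes the log2 fold change (mutant minus wild-type mean) and a
#' two-sided p-value from the pooled-variance two-sample t statistic. With
#' `moderated = TRUE` the gene's pooled variance is shrunk toward a prior
#' variance with `prior_df` pseudo-degrees of freedom and the residual
#' degrees of freedom increased accordingly — a simple fixed-weight
#' moderation suited to small replicate numbers. When `prior_var` is not
#' supplied the gene's own variance is used, making moderation a no-op;
#' matrix-level drivers pass the across-gene mean residual variance.
#'
#' @param values_wt,values_mut Numeric vectors (log2), at least 2 each.
#' @param moderated Apply variance moderation (default FALSE: the classical
#'   pooled t).
#' @param prior_df Prior degrees of freedom for moderation (default 4).
#' @param prior_var Prior variance toward which to shrink.
#' @return One-row tibble with `log2fc`, `t`, `df`, `p`.
#' @export
test_gene <- function(values_wt, values_mut, moderated = FALSE,
                      prior_df = 4, prior_var = NULL) {
  n1 <- length(values_wt); n2 <- length(values_mut)
  stopifnot(n1 >= 2, n2 >= 2)
  log2fc <- mean(values_mut) - mean(values_wt)
  df <- n1 + n2 - 2
  s2 <- ((n1 - 1) * stats::var(values_wt) + (n2 - 1) * stats::var(values_mut)) / df
  if (moderated) {
    if (is.null(prior_var)) prior_var <- s2
    s2 <- (prior_df * prior_var + df * s2) / (prior_df + df)
    df <- df + prior_df
  }
  se <- sqrt(s2 * (1 / n1 + 1 / n2))
  if (se == 0) {
    if (log2fc == 0) return(tibble(log2fc = 0, t = 0, df = df, p = 1))
    warn("zero pooled variance with unequal means: p set to 0 (degenerate)")
    return(tibble(log2fc = log2fc, t = Inf * sign(log2fc), df = df, p = 0))
  }
  t <- log2fc / se
  tibble(log2fc = log2fc, t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Standard step-up adjustment with monotonicity enforcement, capped at 1.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  p.adjust(p, method = "BH")
}

#' Classify a gene's differential-expression call
#'
#' Applies the signed fold-change convention of expression-array software
#' (signed FC = ratio when ratio >= 1, else -1/ratio), so "fold change
#' < -1.3" is equivalent to `log2fc <= -log2(1.3)`. Categories:
#' `decreased` / `increased` (beyond the threshold with `p < alpha`),
#' `tending_decreased` (beyond the negative threshold with `p >= alpha`),
#' else `unchanged`.
#'
#' @param log2fc Numeric vector of log2 fold changes (mutant vs wild-type).
#' @param p Raw p-values.
#' @param fc_threshold Linear fold-change threshold > 1 (default 1.3).
#' @param alpha Significance level applied to the raw p (default 0.05).
#' @return Character vector of categories.
#' @export
classify_de <- function(log2fc, p, fc_threshold = 1.3, alpha = 0.05) {
  stopifnot(fc_threshold > 1)
  thr <- log2(fc_threshold)
  dplyr::case_when(
    log2fc <= -thr & p < alpha ~ "decreased",
    log2fc >= thr & p < alpha ~ "increased",
    log2fc <= -thr & p >= alpha ~ "tending_decreased",
    TRUE ~ "unchanged")
}

#' Correlation of expression change with distance from a focal element
#'
#' Pearson correlation of per-gene log2 fold change against the unsigned
#' genomic distance of the gene midpoint from the element position, with the
#' two-sided p-value from the t transform.
#'
#' @param calls Tibble with `log2fc` and either `distance_bp` or `midpoint`.
#' @param element_position Focal element midpoint (bp); needed when
#'   `distance_bp` is absent.
#' @return One-row tibble with `r`, `p`, `n`.
#' @export
distance_correlation <- function(calls, element_position = NULL) {
  if (!"distance_bp" %in% names(calls)) {
    stopifnot(!is.null(element_position))
    calls$distance_bp <- abs(calls$midpoint - element_position)
  }
  stopifnot(nrow(calls) >= 3)
  if (sd(calls$log2fc) == 0 || sd(calls$distance_bp) == 0) {
    warn("zero variance: distance correlation undefined")
    return(tibble(r = NA_real_, p = NA_real_, n = nrow(calls)))
  }
  ct <- cor.test(calls$log2fc, calls$distance_bp, method = "pearson")
  tibble(r = unname(ct$estimate), p = ct$p.value, n = nrow(calls))
}

#' Fold change from in situ hybridization cell counts
#'
#' The per-gene ISH fold change is the mean positive-cell count per section
#' in mutants divided by that in wild-types; its log2 is used when checking
#' agreement with array fold changes.
#'
#' @param counts_mut,counts_wt Numeric vectors of per-section counts.
#' @return One-row tibble with `fold_change` and `log2fc`.
#' @export
ish_fold_change <- function(counts_mut, counts_wt) {
  stopifnot(length(counts_mut) >= 1, length(counts_wt) >= 1)
  mwt <- mean(counts_wt)
  if (mwt == 0) {
    warn("wild-type mean count is zero: fold change undefined")
    return(tibble(fold_change = NA_real_, log2fc = NA_real_))
  }
  fc <- mean(counts_mut) / mwt
  tibble(fold_change = fc, log2fc = log2(fc))
}

#' Differential-expression analysis of a clustered gene family
#'
#' The full analysis applied to an element-deletion expression experiment:
#' percentile-shift normalization, per-gene pooled (optionally moderated)
#' t-tests, Benjamini-Hochberg adjustment across all tested genes,
#' fold-change classification, and the correlation of log2 fold change with
#' genomic distance from the focal element.
#'
#' @param intensities Genes-by-samples log2 matrix (rownames = gene ids).
#' @param groups Character vector per sample, values `wildtype` / `mutant`.
#' @param genes Tibble with `gene_id`, `chrom`, `start`, `end` (and
#'   optionally `gene_class`).
#' @param element One-row tibble with `chrom`, `start`, `end` of the focal
#'   element.
#' @param normalize Apply [percentile_shift_normalize()] first (default TRUE).
#' @param q Quantile for normalization.
#' @param moderated Use the moderated t (default FALSE).
#' @param prior_df Moderation prior degrees of freedom.
#' @param fc_threshold,alpha Classification thresholds.
#' @return A `de_result` object with elements `calls` (per-gene tibble),
#'   `summary` (category counts and the distance correlation) and `params`.
#' @export
de_analyze <- function(intensities, groups, genes, element,
                       normalize = TRUE, q = 0.75,
                       moderated = FALSE, prior_df = 4,
                       fc_threshold = 1.3, alpha = 0.05) {
  stopifnot(is.matrix(intensities), ncol(intensities) == length(groups),
            all(groups %in% c("wildtype", "mutant")),
            sum(groups == "wildtype") >= 2, sum(groups == "mutant") >= 2)
  if (normalize) intensities <- percentile_shift_normalize(intensities, q = q)
  wt <- intensities[, groups == "wildtype", drop = FALSE]
  mut <- intensities[, groups == "mutant", drop = FALSE]
  n1 <- ncol(wt); n2 <- ncol(mut)
  df <- n1 + n2 - 2
  v1 <- apply(wt, 1, stats::var)
  v2 <- apply(mut, 1, stats::var)
  s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
  log2fc <- rowMeans(mut) - rowMeans(wt)
  if (moderated) {
    prior_var <- mean(s2)
    s2 <- (prior_df * prior_var + df * s2) / (prior_df + df)
    df <- df + prior_df
  }
  se <- sqrt(s2 * (1 / n1 + 1 / n2))
  t <- ifelse(se == 0, ifelse(log2fc == 0, 0, Inf * sign(log2fc)), log2fc / se)
  p <- ifelse(is.infinite(t), 0, 2 * pt(-abs(t), df))
  p[se == 0 & log2fc == 0] <- 1
  calls <- tibble(gene_id = rownames(intensities), log2fc = log2fc,
                  t = t, p = p, p_adj = bh_adjust(p))
  calls <- dplyr::left_join(calls, genes, by = "gene_id")
  el_mid <- (element$start[1] + element$end[1]) / 2
  calls$midpoint <- (calls$start + calls$end) / 2
  calls$distance_bp <- abs(calls$midpoint - el_mid)
  calls$category <- classify_de(calls$log2fc, calls$p,
                                fc_threshold = fc_threshold, alpha = alpha)
  corr <- distance_correlation(calls)
  counts <- table(factor(calls$category,
                         levels = c("decreased", "increased",
                                    "tending_decreased", "unchanged")))
  structure(list(calls = calls,
                 summary = list(n_genes = nrow(calls),
                                counts = as.list(counts),
                                distance_r = corr$r, distance_p = corr$p),
                 params = list(normalize = normalize, q = q,
                               moderated = moderated, prior_df = prior_df,
                               fc_threshold = fc_threshold, alpha = alpha,
                               element_midpoint = el_mid)),
            class = "de_result")
}

#' @export
print.de_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<de_result> %d genes: %d decreased, %d increased, %d tending decreased, %d unchanged\n",
              s$n_genes, s$counts$decreased, s$counts$increased,
              s$counts$tending_decreased, s$counts$unchanged))
  cat(sprintf("log2FC vs distance: Pearson r = %.3f, p = %.3g\n",
              s$distance_r, s$distance_p))
  invisible(x)
}

#' @method tidy de_result
#' @export
tidy.de_result <- function(x, ...) x$calls

#' @method glance de_result
#' @export
glance.de_result <- function(x, ...) {
  s <- x$summary
  tibble(n_genes = s$n_genes,
         n_decreased = s$counts$decreased, n_increased = s$counts$increased,
         n_tending_decreased = s$counts$tending_decreased,
         n_unchanged = s$counts$unchanged,
         distance_r = s$distance_r, distance_p = s$distance_p)
}
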