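#' Pooled two-sample t-test from summary statistics
#'
#' Student's pooled-variance unpaired t-test computed directly from group
#' means, standard errors of the mean, and sample sizes — the form in which
#' cell-count comparisons are usually reported (`mean +/- s.e.m., n`).
#'
#' @param mean1,sem1,n1 Summary of group 1.
#' @param mean2,sem2,n2 Summary of group 2.
#' @return One-row tibble with `t`, `df`, `p`, `mean_diff` (group 2 minus
#'   group 1) and `degenerate` (TRUE when the pooled s.e. is zero with
#'   unequal means).
#' @export
#' @examples
#' pooled_t_from_summary(148, 13.8, 6, 306, 43.5, 5)
pooled_t_from_summary <- function(mean1, sem1, n1, mean2, sem2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, sem1 >= 0, sem2 >= 0)
  sd1 <- sem1 * sqrt(n1)
  sd2 <- sem2 * sqrt(n2)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  diff <- mean2 - mean1
  if (se == 0) {
    if (diff == 0) return(tibble(t = 0, df = df, p = 1, mean_diff = 0, degenerate = FALSE))
    warn("zero pooled standard error with unequal means: degenerate p = 0")
    return(tibble(t = Inf * sign(diff), df = df, p = 0, mean_diff = diff, degenerate = TRUE))
  }
  t <- diff / se
  tibble(t = t, df = df, p = 2 * pt(-abs(t), df), mean_diff = diff, degenerate = FALSE)
}

#' Pooled two-sample t-test from raw values
#'
#' Computes each group's summary and delegates to
#' [pooled_t_from_summary()], so the raw and summary routes agree exactly.
#'
#' @param values1,values2 Numeric vectors, at least 2 values each.
#' @return As [pooled_t_from_summary()].
#' @export
t_from_raw <- function(values1, values2) {
  n1 <- length(values1); n2 <- length(values2)
  stopifnot(n1 >= 2, n2 >= 2)
  pooled_t_from_summary(mean(values1), sd(values1) / sqrt(n1), n1,
                        mean(values2), sd(values2) / sqrt(n2), n2)
}

#' Fisher's exact test for a 2x2 contingency table
#'
#' Two-sided p-value by the summed small-probability rule (hypergeometric
#' probabilities no larger than that of the observed table). The reported
#' odds ratio is the sample odds ratio `a*d / (b*c)`.
#'
#' @param a,b,c,d Cell counts; rows are categories, columns co-labeled vs
#'   not. Alternatively `a` may be a 2x2 matrix.
#' @return One-row tibble with `odds_ratio`, `p` and `degenerate` (TRUE when
#'   a margin is zero, in which case `p = 1` and the odds ratio undefined).
#' @export
#' @examples
#' fisher_exact_2x2(258, 2854, 4, 3248)
fisher_exact_2x2 <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    m <- a
  } else {
    m <- matrix(c(a, c, b, d), nrow = 2)
  }
  stopifnot(all(m >= 0), sum(m) > 0)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    return(tibble(odds_ratio = NA_real_, p = 1, degenerate = TRUE))
  }
  p <- fisher.test(m)$p.value
  or <- (m[1, 1] * m[2, 2]) / (m[1, 2] * m[2, 1])
  tibble(odds_ratio = or, p = p, degenerate = FALSE)
}

#' Co-expression rate as a percentage
#'
#' @param co_labeled Number of co-labeled cells.
#' @param total Total cells scored; must be positive.
#' @return The percentage `100 * co_labeled / total`.
#' @export
#' @examples
#' coexpression_rate(258, 3112) # 8.29...%, printed as 8.3%
coexpression_rate <- function(co_labeled, total) {
  if (any(total <= 0)) abort("total must be positive")
  stopifnot(all(co_labeled >= 0), all(co_labeled <= total))
  100 * co_labeled / total
}

#' One-way ANOVA with Tukey HSD post hoc comparisons
#'
#' Classical one-way ANOVA across three or more groups followed by Tukey's
#' honestly-significant-difference pairwise comparisons via the studentized
#' range distribution.
#'
#' @param data Tibble with a grouping column and a value column.
#' @param group,value Column names (default `"group"`, `"value"`).
#' @return An `anova_tukey` object: list with `F`, `df_between`, `df_within`,
#'   `p` and `tukey` (tibble of pairwise comparisons with adjusted p).
#' @export
anova_tukey <- function(data, group = "group", value = "value") {
  g <- factor(data[[group]])
  y <- data[[value]]
  stopifnot(nlevels(g) >= 3, all(table(g) >= 2))
  fit <- aov(y ~ g)
  an <- summary(fit)[[1]]
  Fv <- an$`F value`[1]
  pv <- an$`Pr(>F)`[1]
  if (max(y) == min(y) || is.na(Fv) || is.nan(Fv)) {
    # no within- or between-group variance at all: nothing to detect
    Fv <- 0; pv <- 1
    tk <- tibble(comparison = combn(levels(g), 2, paste, collapse = "-"),
                 diff = 0, lwr = 0, upr = 0, p_adj = 1)
  } else {
    th <- TukeyHSD(fit)$g
    tk <- tibble(comparison = rownames(th), diff = th[, "diff"],
                 lwr = th[, "lwr"], upr = th[, "upr"], p_adj = th[, "p adj"])
  }
  structure(list(F = Fv, df_between = an$Df[1], df_within = an$Df[2],
                 p = pv, tukey = tk),
            class = "anova_tukey")
}

#' @export
print.anova_tukey <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df_between, x$df_within, x$F, x$p))
  print(x$tukey)
  invisible(x)
}

#' @method tidy anova_tukey
#' @export
tidy.anova_tukey <- function(x, ...) x$tukey

#' @method glance anova_tukey
#' @export
glance.anova_tukey <- function(x, ...) {
  tibble(F = x$F, df_between = x$df_between, df_within = x$df_within, p = x$p)
}
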