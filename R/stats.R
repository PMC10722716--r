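#' Wilcoxon rank-sum test
#'
#' Two-sided rank-sum comparison. The exact null distribution is used when
#' both samples have at most `exact_below` observations and there are no
#' ties; otherwise the normal approximation with tie and continuity
#' correction is used. If all pooled values are identical, p = 1 with a
#' warning.
#'
#' @param x,y Numeric samples (nonempty).
#' @param exact_below Sample-size bound for the exact branch (default 10).
#' @return A `test_result` list: `statistic` (rank-sum W of `x`), `p`,
#'   `method`, `n` (per-sample sizes), `exact`.
#' @export
wilcoxon_ranksum <- function(x, y, exact_below = 10) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  if (length(unique(c(x, y))) == 1) {
    warning("all pooled values identical; p = 1")
    return(test_result(statistic = length(x) * length(y) / 2, p = 1,
                       method = "Wilcoxon rank-sum", n = c(length(x), length(y)),
                       exact = FALSE))
  }
  ties <- any(duplicated(c(x, y)))
  exact <- length(x) <= exact_below && length(y) <= exact_below && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE))
  test_result(statistic = unname(wt$statistic), p = wt$p.value,
              method = "Wilcoxon rank-sum", n = c(length(x), length(y)),
              exact = exact)
}

#' Pearson chi-squared test for a 2 x 2 table
#'
#' Yates continuity correction is applied by default, which reproduces the
#' reference analysis's printed p-values from its printed counts.
#'
#' @param tab 2 x 2 matrix of nonnegative integer counts.
#' @param continuity Apply the continuity correction (default TRUE).
#' @return A `test_result` with `statistic` (X-squared, df = 1) and `p`.
#' @export
chisq_2x2 <- function(tab, continuity = TRUE) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2, 2)), all(tab >= 0),
            all(abs(tab - round(tab)) < 1e-9))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("chi-squared test undefined: a table marginal is zero")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = continuity))
  test_result(statistic = unname(ct$statistic), p = ct$p.value,
              method = if (continuity) "Pearson chi-squared (Yates)" else
                "Pearson chi-squared", n = sum(tab))
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties; the p-value uses the
#' t-distribution approximation with n - 2 degrees of freedom.
#'
#' @param x,y Paired numeric samples, n >= 3.
#' @return A `test_result` with `statistic` (Rs) and `p`.
#' @export
spearman_cor <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    warning("zero variance in ranks; correlation undefined")
    return(test_result(statistic = NA_real_, p = NA_real_,
                       method = "Spearman", n = length(x)))
  }
  rs <- stats::cor(rx, ry)
  n <- length(x)
  tv <- rs * sqrt((n - 2) / (1 - rs^2))
  p <- if (abs(rs) >= 1) 0 else 2 * stats::pt(-abs(tv), df = n - 2)
  test_result(statistic = rs, p = p, method = "Spearman", n = n)
}

#' Shapiro-Wilk normality test
#'
#' Used to annotate reports; the pipeline's group comparisons are
#' nonparametric regardless of the outcome, matching the reference analysis.
#'
#' @param x Numeric sample, 3 <= n <= 5000.
#' @return A `test_result` with `statistic` (W) and `p`.
#' @export
shapiro_wilk <- function(x) {
  if (length(x) < 3 || length(x) > 5000)
    stop("Shapiro-Wilk requires 3 <= n <= 5000")
  sw <- stats::shapiro.test(x)
  test_result(statistic = unname(sw$statistic), p = sw$p.value,
              method = "Shapiro-Wilk", n = length(x))
}

#' Bonferroni correction
#'
#' Each corrected p is `min(1, p * family_size)`. With the 6-test ERP family
#' the working significance level is 0.05 / 6 (about 0.008).
#'
#' @param pvals Numeric vector of p-values.
#' @param family_size Number of tests in the family (>= length(pvals)).
#' @return Corrected p-values.
#' @export
bonferroni <- function(pvals, family_size = length(pvals)) {
  stopifnot(family_size >= length(pvals))
  pmin(1, pvals * family_size)
}

test_result <- function(statistic, p, method, n, exact = NA,
                        corrected_p = NULL, family_size = NULL) {
  structure(list(statistic = statistic, p = p, method = method, n = n,
                 exact = exact, corrected_p = corrected_p,
                 family_size = family_size),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat("<", x$method, "> statistic = ", signif(x$statistic, 4),
      ", p = ", signif(x$p, 4), "\n", sep = "")
  invisible(x)
}

#' Group comparison table
#'
#' Builds a report-shaped summary of a subject table: median (IQR) and a
#' Wilcoxon rank-sum p for numeric variables, count (%) and a continuity-
#' corrected chi-squared p for binary categorical variables, with optional
#' Bonferroni correction.
#'
#' @param subjects A data.frame with a group column.
#' @param group_col Name of the group column (levels HC / MCI).
#' @param variables Variables to compare (default: all others).
#' @param family_size Bonferroni family size; `NULL` for no correction.
#' @return A data.frame, one row per variable.
#' @export
group_comparison_table <- function(subjects, group_col = "group",
                                   variables = NULL, family_size = NULL) {
  g <- subjects[[group_col]]
  stopifnot(!is.null(g))
  if (is.null(variables))
    variables <- setdiff(names(subjects), c(group_col, "subject"))
  rows <- lapply(variables, function(v) {
    x <- subjects[[v]]
    if (is.numeric(x)) {
      qa <- stats::quantile(x[g == "HC"], c(0.25, 0.5, 0.75), type = 7)
      qb <- stats::quantile(x[g == "MCI"], c(0.25, 0.5, 0.75), type = 7)
      p <- wilcoxon_ranksum(x[g == "HC"], x[g == "MCI"])$p
      data.frame(variable = v, test = "wilcoxon",
                 hc = sprintf("%.3g (%.3g-%.3g)", qa[2], qa[1], qa[3]),
                 mci = sprintf("%.3g (%.3g-%.3g)", qb[2], qb[1], qb[3]),
                 p = p)
    } else {
      lev <- sort(unique(as.character(x)))
      tab <- table(factor(as.character(x), levels = lev),
                   factor(g, levels = c("HC", "MCI")))
      if (nrow(tab) != 2) return(NULL)
      p <- chisq_2x2(tab)$p
      data.frame(variable = v, test = "chisq",
                 hc = sprintf("%d (%.1f%%)", tab[1, 1],
                              100 * tab[1, 1] / sum(tab[, 1])),
                 mci = sprintf("%d (%.1f%%)", tab[1, 2],
                               100 * tab[1, 2] / sum(tab[, 2])),
                 p = p)
    }
  })
  out <- do.call(rbind, rows)
  if (!is.null(family_size)) out$corrected_p <- bonferroni(out$p, family_size)
  out
}
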