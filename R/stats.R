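#' Pooled-variance two-sample t test
#'
#' Independent-samples two-tailed t test with the pooled variance estimate
#' and `df = n1 + n2 - 2`, computable directly from printed group summaries
#' (means, SDs, sizes) or from raw samples. With zero pooled variance the
#' statistic is 0 for equal means and `Inf` (flagged) otherwise.
#'
#' @param mean1,sd1,n1 summary of group 1 (or `x`, a raw sample).
#' @param mean2,sd2,n2 summary of group 2 (or `y`, a raw sample).
#' @param x,y optional raw samples overriding the summaries.
#' @return List of class `oculomark_test`: `statistic`, `df`, `p_value`,
#'   `method`, and per-group summaries.
#' @examples
#' pooled_t_test(103.02, 13.25, 122, 99.01, 15.02, 94)$statistic  # ~2.08
#' @export
pooled_t_test <- function(mean1, sd1, n1, mean2, sd2, n2,
                          x = NULL, y = NULL) {
  if (!is.null(x)) { mean1 <- mean(x); sd1 <- stats::sd(x); n1 <- length(x) }
  if (!is.null(y)) { mean2 <- mean(y); sd2 <- stats::sd(y); n2 <- length(y) }
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  if (se == 0) {
    stat <- if (mean1 == mean2) 0 else Inf * sign(mean1 - mean2)
    p <- if (mean1 == mean2) 1 else 0
  } else {
    stat <- (mean1 - mean2) / se
    p <- 2 * stats::pt(-abs(stat), df)
  }
  structure(list(statistic = stat, df = df, p_value = p,
                 method = "pooled two-sample t test",
                 group1 = c(mean = mean1, sd = sd1, n = n1),
                 group2 = c(mean = mean2, sd = sd2, n = n2)),
            class = "oculomark_test")
}

#' @export
print.oculomark_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g%s, p = %.3g\n", x$method, x$statistic,
              if (!is.null(x$df) && !is.na(x$df))
                sprintf(" (df = %g)", x$df) else "", x$p_value))
  invisible(x)
}

#' Pearson chi-square test on a contingency table
#'
#' Pearson's chi-square without continuity correction,
#' `df = (r - 1)(c - 1)`.
#'
#' @param tab contingency table (matrix of nonnegative counts).
#' @return An `oculomark_test` list.
#' @examples
#' chi_square_test(rbind(TD = c(61, 61), ADHD = c(84, 10)))  # chi2 ~ 37.28
#' @export
chi_square_test <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || sum(tab) <= 0) stop("counts must be nonnegative with positive total")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("zero marginal in contingency table")
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  structure(list(statistic = unname(ct$statistic), df = unname(ct$parameter),
                 p_value = ct$p.value, method = "Pearson chi-square test",
                 observed = tab, expected = ct$expected),
            class = "oculomark_test")
}

#' Wilcoxon Mann-Whitney U test
#'
#' Rank-sum test with the U statistic for the first sample,
#' `U = sum of ranks of x - n1 (n1 + 1) / 2`. P-values use exact enumeration
#' (via the null Wilcoxon distribution) for untied samples with both sizes
#' at most `exact_limit`, and the tie-corrected normal approximation
#' otherwise. When the pooled sample is constant the p-value is 1.
#'
#' @param x,y numeric samples.
#' @param exact_limit maximum group size for the exact p-value.
#' @return An `oculomark_test` list with `statistic` = U.
#' @export
mann_whitney_u <- function(x, y, exact_limit = 20) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (!n1 || !n2) stop("both samples must be nonempty")
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(pooled))
  N <- n1 + n2
  if (!ties && n1 <= exact_limit && n2 <= exact_limit) {
    mu <- n1 * n2 / 2
    p <- if (U > mu) {
      2 * stats::pwilcox(U - 1, n1, n2, lower.tail = FALSE)
    } else {
      2 * stats::pwilcox(U, n1, n2)
    }
    p <- min(1, p)
    method <- "Mann-Whitney U test (exact)"
  } else {
    tie_tab <- table(pooled)
    sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (U - n1 * n2 / 2) / sqrt(sigma2)
      p <- 2 * stats::pnorm(-abs(z))
    }
    method <- "Mann-Whitney U test (normal approximation)"
  }
  structure(list(statistic = U, df = NA_real_, p_value = p, method = method,
                 n1 = n1, n2 = n2),
            class = "oculomark_test")
}

#' Kruskal-Wallis rank-sum test across multiple groups
#'
#' Tie-corrected Kruskal-Wallis H test (delegates to
#' [stats::kruskal.test()]).
#'
#' @param values numeric vector.
#' @param groups grouping factor of the same length.
#' @return An `oculomark_test` list.
#' @export
kruskal_wallis <- function(values, groups) {
  kt <- stats::kruskal.test(values, as.factor(groups))
  structure(list(statistic = unname(kt$statistic),
                 df = unname(kt$parameter), p_value = kt$p.value,
                 method = "Kruskal-Wallis test"),
            class = "oculomark_test")
}

#' Bonferroni adjustment
#'
#' Multiplies p-values by the number of comparisons, capped at 1.
#'
#' @param pvals numeric p-values.
#' @param m number of comparisons (default `length(pvals)`).
#' @return Adjusted p-values.
#' @export
bonferroni <- function(pvals, m = length(pvals)) {
  pmin(1, pvals * m)
}

#' Filter feature columns by group difference
#'
#' Retains feature columns whose two-sided Mann-Whitney p-value between the
#' two label groups is below `alpha`; used to drop uninformative variables
#' before classifier training. If nothing survives, all columns are kept
#' with a warning.
#'
#' @param x numeric feature matrix.
#' @param labels 0/1 group labels per row.
#' @param alpha significance threshold.
#' @return Integer indices of retained columns, with attribute `p_values`.
#' @export
filter_variables <- function(x, labels, alpha = 0.05) {
  stopifnot(nrow(x) == length(labels))
  g1 <- labels == 1
  p <- vapply(seq_len(ncol(x)), function(j) {
    xj <- x[, j]
    a <- xj[g1 & !is.na(xj)]
    b <- xj[!g1 & !is.na(xj)]
    if (!length(a) || !length(b)) return(1)
    if (length(unique(c(a, b))) == 1) return(1)
    mann_whitney_u(a, b)$p_value
  }, 0)
  keep <- which(p < alpha)
  if (!length(keep)) {
    warning("no variables pass the filter; keeping all columns")
    keep <- seq_len(ncol(x))
  }
  attr(keep, "p_values") <- p
  keep
}

#' Per-variable group comparison of a feature table
#'
#' Runs the Mann-Whitney U test for every feature column between the ADHD
#' and TD groups and reports the statistic, raw p and Bonferroni-adjusted p.
#'
#' @param ft a `feature_table` with a `label` column.
#' @return Data frame: `variable`, `U`, `p_value`, `p_adjusted`.
#' @export
compare_groups <- function(ft) {
  x <- feature_matrix(ft)
  labels <- ft$label
  res <- lapply(colnames(x), function(cn) {
    xj <- x[, cn]
    a <- xj[labels == 1 & !is.na(xj)]
    b <- xj[labels == 0 & !is.na(xj)]
    if (!length(a) || !length(b) || length(unique(c(a, b))) == 1) {
      return(data.frame(variable = cn, U = NA_real_, p_value = 1))
    }
    mt <- mann_whitney_u(a, b)
    data.frame(variable = cn, U = mt$statistic, p_value = mt$p_value)
  })
  out <- do.call(rbind, res)
  out$p_adjusted <- bonferroni(out$p_value, nrow(out))
  out
}
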