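#' Compare a continuous variable between survivors and non-survivors
#'
#' Welch's t-test by default (`pooled = TRUE` gives the classical
#' equal-variance form); `method = "auto"` runs a Shapiro-Wilk normality
#' pre-check in each group at the 0.05 level and falls back to the
#' Mann-Whitney (Wilcoxon rank-sum) test when either group fails it.
#'
#' @param values numeric vector.
#' @param groups two-level factor/vector (e.g. survived/died) parallel to
#'   `values`.
#' @param method `"auto"`, `"t"` or `"mann_whitney"`.
#' @param pooled use the pooled-variance t-test instead of Welch.
#' @return An object of class `msofa_comparison`: variable summaries per
#'   group (mean, sd, median, IQR, n), `test` actually used, `statistic`,
#'   `p_value`, and for `"auto"` the normality p-values that drove the
#'   choice.
#' @export
group_compare_continuous <- function(values, groups,
                                     method = c("auto", "t", "mann_whitney"),
                                     pooled = FALSE) {
  method <- match.arg(method)
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- as.character(groups)[keep]
  lev <- unique(groups)
  if (length(lev) != 2) stop("exactly two groups required, got: ",
                             paste(lev, collapse = ", "))
  g1 <- values[groups == lev[1]]; g2 <- values[groups == lev[2]]
  if (!length(g1) || !length(g2))
    stop("group '", lev[!c(length(g1), length(g2))][1], "' is empty")
  normality <- NULL
  if (method == "auto") {
    shap <- function(x) {
      x <- x[!is.na(x)]
      if (length(unique(x)) < 3 || length(x) < 3 || length(x) > 5000) return(NA_real_)
      stats::shapiro.test(x)$p.value
    }
    normality <- c(shap(g1), shap(g2))
    method <- if (any(normality < 0.05, na.rm = TRUE)) "mann_whitney" else "t"
  }
  if (method == "t") {
    if (length(g1) < 2 || length(g2) < 2)
      stop("t-test needs >= 2 observations per group")
    if (stats::sd(g1) == 0 && stats::sd(g2) == 0) {
      # degenerate but well-defined: identical constants differ not at all,
      # different constants differ completely
      eq <- isTRUE(all.equal(mean(g1), mean(g2)))
      ht <- list(statistic = if (eq) 0 else sign(mean(g1) - mean(g2)) * Inf,
                 p.value = if (eq) 1 else 0)
    } else {
      ht <- stats::t.test(g1, g2, var.equal = pooled)
    }
  } else {
    ht <- suppressWarnings(stats::wilcox.test(g1, g2, exact = FALSE))
  }
  smry <- function(x) c(n = length(x), mean = mean(x), sd = stats::sd(x),
                        median = stats::median(x),
                        q1 = unname(stats::quantile(x, 0.25)),
                        q3 = unname(stats::quantile(x, 0.75)))
  structure(list(groups = stats::setNames(list(smry(g1), smry(g2)), lev),
                 test = method, statistic = unname(ht$statistic),
                 p_value = ht$p.value, normality_p = normality),
            class = "msofa_comparison")
}

#' Compare a categorical variable across outcome groups
#'
#' Pearson chi-square test (no continuity correction) on a 2 x k count
#' table. Empty columns are dropped with a warning, reducing the degrees of
#' freedom.
#'
#' @param counts 2 x k matrix of non-negative integer counts (rows =
#'   outcome groups, columns = categories).
#' @return An `msofa_comparison` with `test = "chi_square"`, `statistic`,
#'   `df` and `p_value`.
#' @export
group_compare_categorical <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("counts must be non-negative integers")
  if (sum(counts) == 0) stop("all-zero contingency table")
  empty <- colSums(counts) == 0
  if (any(empty)) {
    warning("dropping ", sum(empty), " empty column(s); df reduced")
    counts <- counts[, !empty, drop = FALSE]
  }
  if (ncol(counts) < 2) stop("at least two non-empty categories required")
  ht <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  structure(list(counts = counts, test = "chi_square",
                 statistic = unname(ht$statistic),
                 df = unname(ht$parameter), p_value = ht$p.value),
            class = "msofa_comparison")
}

#' @export
print.msofa_comparison <- function(x, ...) {
  cat("Group comparison (", x$test, "): statistic = ",
      signif(x$statistic, 4), ", p = ", signif(x$p_value, 3), "\n", sep = "")
  invisible(x)
}

#' Odds ratio from a 2 x 2 table
#'
#' `OR = ad/bc` with a Woolf (log-scale normal) confidence interval. When
#' any cell is zero the Haldane-Anscombe correction adds 0.5 to every cell,
#' and the result is flagged `corrected`.
#'
#' @param table 2 x 2 matrix: rows = exposure, columns = outcome.
#' @param level confidence level (default 0.95).
#' @return List with `odds_ratio`, `ci_low`, `ci_high`, `level`,
#'   `corrected`.
#' @examples
#' contingency_odds_ratio(matrix(c(24, 31, 4, 59), 2))  # ~ 11.42
#' @export
contingency_odds_ratio <- function(table, level = 0.95) {
  tab <- as.matrix(table)
  stopifnot(all(dim(tab) == c(2, 2)), all(tab >= 0))
  corrected <- any(tab == 0)
  if (corrected) tab <- tab + 0.5
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  se <- sqrt(sum(1 / tab))
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(odds_ratio = or,
       ci_low = exp(log(or) - z * se), ci_high = exp(log(or) + z * se),
       level = level, corrected = corrected)
}
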