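# Significance tests for 2x2 outcome-by-group tables.

as_table_2x2 <- function(table) {
  if (is.data.frame(table)) table <- as.matrix(table)
  if (is.numeric(table) && length(table) == 4L && is.null(dim(table))) {
    table <- matrix(table, nrow = 2, byrow = TRUE)
  }
  if (!is.matrix(table) || !all(dim(table) == c(2L, 2L))) {
    stop("expected a 2x2 table (matrix, or 4 counts a,b,c,d by row)")
  }
  storage.mode(table) <- "double"
  if (anyNA(table) || any(table < 0) || any(table != round(table))) {
    stop("counts must be non-negative integers")
  }
  table
}

#' Pearson chi-squared test on a 2x2 table
#'
#' The plain Pearson statistic `sum((O-E)^2/E)` on one degree of
#' freedom, with the upper-tail p value. The Yates continuity
#' correction is off by default and exposed as a flag.
#'
#' @param table 2x2 matrix of counts, or 4 counts `a,b,c,d` in row
#'   order.
#' @param yates apply the continuity correction.
#' @return list with `statistic`, `p_value`, `df` (always 1).
#' @examples
#' chi_squared_2x2(c(90, 10, 50, 50))
#' @export
chi_squared_2x2 <- function(table, yates = FALSE) {
  tab <- as_table_2x2(table)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("zero row or column margin; use fisher_exact_2x2 instead")
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = yates))
  list(statistic = unname(ht$statistic), p_value = unname(ht$p.value),
       df = 1L)
}

#' Fisher exact test on a 2x2 table
#'
#' Exact p value from the hypergeometric distribution of the top-left
#' cell given fixed margins. The two-sided p value sums the
#' probabilities of all tables as or less probable than the observed
#' one; the one-sided value is the upper tail of the top-left cell.
#'
#' @param table 2x2 matrix of counts, or 4 counts `a,b,c,d` in row
#'   order.
#' @param sided `"two"` (default) or `"one"`.
#' @return the p value.
#' @examples
#' fisher_exact_2x2(c(5, 0, 0, 5), sided = "one")
#' @export
fisher_exact_2x2 <- function(table, sided = c("two", "one")) {
  sided <- match.arg(sided)
  tab <- as_table_2x2(table)
  if (sum(tab) < 1) stop("table has no observations")
  alt <- if (sided == "one") "greater" else "two.sided"
  unname(stats::fisher.test(tab, alternative = alt)$p.value)
}
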