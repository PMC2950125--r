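#' Contingency table constructor
#'
#' Builds a validated contingency table of non-negative integer counts, the
#' input shared by all enrichment tests in the package (X vs autosome against
#' bias classes, presence/absence, strata membership, ...).
#'
#' @param counts Numeric matrix of non-negative counts, at least 2 x 2.
#' @param row_labels,col_labels Optional character labels; default to existing
#'   dimnames or generated names.
#' @return An integer matrix of class `"contingency_table"`.
#' @examples
#' contingency_table(rbind(X = c(28, 35, 27), autosome = c(187, 137, 409)),
#'                   col_labels = c("male", "female", "unbiased"))
#' @export
contingency_table <- function(counts, row_labels = NULL, col_labels = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2L || ncol(counts) < 2L)
    stop("contingency table must have at least 2 rows and 2 columns")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and non-negative")
  if (any(abs(counts - round(counts)) > 1e-8))
    stop("counts must be integers")
  if (sum(counts) <= 0)
    stop("grand total of the contingency table is zero")
  counts <- round(counts)
  storage.mode(counts) <- "integer"
  if (!is.null(row_labels)) rownames(counts) <- row_labels
  if (!is.null(col_labels)) colnames(counts) <- col_labels
  if (is.null(rownames(counts))) rownames(counts) <- paste0("row", seq_len(nrow(counts)))
  if (is.null(colnames(counts))) colnames(counts) <- paste0("col", seq_len(ncol(counts)))
  class(counts) <- c("contingency_table", class(counts))
  counts
}

as_contingency <- function(table) {
  if (inherits(table, "contingency_table")) return(table)
  contingency_table(table)
}

#' Hypothesis test result
#'
#' Light container for a test statistic, its degrees of freedom (when
#' defined), the p-value and the sidedness of the alternative.
#'
#' @param statistic Real-valued statistic (may be `NA` for exact tests that
#'   report no natural statistic).
#' @param df Integer degrees of freedom or `NULL`.
#' @param p_value p-value in \[0, 1\].
#' @param sided One of `"two"`, `"one_greater"`, `"one_less"`.
#' @param method Short description of the test.
#' @return A list of class `"gea_test"`.
#' @export
test_result <- function(statistic, df = NULL, p_value, sided = "two",
                        method = "test") {
  sided <- match.arg(sided, c("two", "one_greater", "one_less"))
  if (!is.na(p_value) && (p_value < 0 || p_value > 1))
    stop("p_value outside [0, 1]")
  if (!is.null(df) && !is.na(df) && df < 1)
    stop("df must be >= 1 when defined")
  structure(list(statistic = unname(statistic),
                 df = if (is.null(df)) NULL else as.integer(df),
                 p_value = unname(p_value), sided = sided, method = method),
            class = "gea_test")
}

#' @export
print.gea_test <- function(x, ...) {
  cat(x$method, "\n")
  cat("  statistic =", format(x$statistic, digits = 6),
      if (!is.null(x$df)) paste0("(df = ", x$df, ")") else "",
      "\n  p =", format(x$p_value, digits = 4),
      paste0("(", x$sided, "-sided)"), "\n")
  invisible(x)
}

#' @export
format.gea_test <- function(x, ...) {
  paste0("p=", format(x$p_value, digits = 4))
}

#' Pearson chi-square test of independence
#'
#' Pearson chi-square test on an r x c contingency table with
#' df = (r-1)(c-1), no continuity correction, p-value from the upper tail of
#' the chi-square distribution. Used for the X-vs-autosome bias and
#' presence comparisons.
#'
#' @param table A [contingency_table()] or coercible matrix.
#' @return A [test_result()].
#' @examples
#' chi_square_independence(rbind(c(28, 35, 27), c(187, 137, 409)))
#' @export
chi_square_independence <- function(table) {
  tab <- as_contingency(table)
  rs <- rowSums(tab); cs <- colSums(tab)
  if (any(rs == 0))
    stop("degenerate input: zero margin in row '", rownames(tab)[which(rs == 0)[1]], "'")
  if (any(cs == 0))
    stop("degenerate input: zero margin in column '", colnames(tab)[which(cs == 0)[1]], "'")
  res <- suppressWarnings(stats::chisq.test(unclass(tab), correct = FALSE))
  test_result(statistic = res$statistic, df = res$parameter,
              p_value = res$p.value, sided = "two",
              method = "Pearson chi-square test of independence")
}

#' Fisher's exact test for 2 x 2 tables
#'
#' Exact hypergeometric test. The two-sided p-value sums the probabilities of
#' all tables (with the observed margins) no more likely than the observed
#' one (minimum-likelihood convention); one-sided alternatives take the
#' upper (`one_greater`, odds ratio > 1) or lower (`one_less`) tail.
#'
#' @param table 2 x 2 [contingency_table()] or coercible matrix.
#' @param sided `"two"`, `"one_greater"` or `"one_less"`.
#' @return A [test_result()]; the statistic slot carries the conditional MLE
#'   odds ratio.
#' @examples
#' fisher_exact(rbind(c(9, 4), c(9, 30)))                  # two-sided
#' fisher_exact(rbind(c(12, 3), c(41, 24)), "one_greater") # upper tail
#' @export
fisher_exact <- function(table, sided = "two") {
  tab <- as_contingency(table)
  if (nrow(tab) != 2L || ncol(tab) != 2L)
    stop("fisher_exact requires a 2 x 2 table")
  sided <- match.arg(sided, c("two", "one_greater", "one_less"))
  alt <- switch(sided, two = "two.sided", one_greater = "greater", one_less = "less")
  res <- stats::fisher.test(unclass(tab), alternative = alt)
  # the two-sided minimum-likelihood sum can exceed 1 by rounding error
  test_result(statistic = res$estimate, df = NULL,
              p_value = min(1, res$p.value),
              sided = sided, method = "Fisher's exact test")
}

#' Wilcoxon rank-sum test
#'
#' Two-sample rank-sum test. Uses exact enumeration when both samples are
#' small (min(n, m) <= 12) and tie-free, otherwise the tie-corrected normal
#' approximation without continuity correction.
#'
#' @param x,y Non-empty numeric samples.
#' @param sided `"two"`, `"one_greater"` (x stochastically larger) or
#'   `"one_less"`.
#' @param exact_max Largest min(n, m) for which the exact distribution is
#'   enumerated (default 12).
#' @return A [test_result()] whose statistic is the Mann-Whitney W for `x`.
#' @examples
#' wilcoxon_rank_sum(c(4, 5, 6), c(1, 2, 3), "one_greater") # p = 1/20
#' @export
wilcoxon_rank_sum <- function(x, y, sided = "two", exact_max = 12L) {
  if (length(x) == 0 || length(y) == 0)
    stop("both samples must be non-empty")
  sided <- match.arg(sided, c("two", "one_greater", "one_less"))
  alt <- switch(sided, two = "two.sided", one_greater = "greater", one_less = "less")
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- !ties && min(length(x), length(y)) <= exact_max
  res <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = alt, exact = use_exact,
                       correct = FALSE))
  test_result(statistic = res$statistic, df = NULL, p_value = res$p.value,
              sided = sided,
              method = paste0("Wilcoxon rank-sum test (",
                              if (use_exact) "exact" else "normal approximation", ")"))
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up FDR adjustment; output is pointwise no smaller than the input and
#' permutation-equivariant.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted values in \[0, 1\], same order as the input.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}
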