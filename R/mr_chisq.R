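# Modified and corrected chi-squared test of association for
# multiple-response contingency tables, after Decady and Thomas.
#
# In a shift-by-condition table each subject contributes one response per
# column, so the grand total is n_subjects * n_columns and responses are
# correlated within subjects. The classical Pearson test on the marginal
# table is then invalid: its expected counts derive from an inflated grand
# total and its independence assumption is violated. The modified statistic
# keeps the Pearson form on the marginal table but is referred, after
# division by a design correction factor, to r(c-1) degrees of freedom.

#' Naive (modified) Pearson statistic on a marginal multiple-response table
#'
#' Computes the Pearson chi-squared form on the marginal table: expected
#' cell (i, j) = row total x column total / grand total, statistic =
#' sum over cells of (observed - expected)^2 / expected. For an r x c
#' multiple-response table the relevant degrees of freedom are `r * (c - 1)`,
#' not the classical `(r - 1) * (c - 1)`.
#'
#' @param table an [mr_table()].
#' @return list with `statistic` and `df`.
#' @export
naive_pearson <- function(table) {
  stopifnot(inherits(table, "mr_table"))
  m <- table$counts
  rt <- rowSums(m)
  if (any(rt == 0))
    stop("degenerate table: shift category '",
         rownames(m)[rt == 0][1], "' has zero total")
  ct <- colSums(m)
  E <- outer(rt, ct) / sum(m)
  list(statistic = sum((m - E)^2 / E),
       df = nrow(m) * (ncol(m) - 1L))
}

#' Correction factor for the one-of-r multiple-response design
#'
#' Under the design in which every subject selects exactly one of the `r`
#' shift categories in every column, the first-order correction factor of
#' the modified chi-squared test has the closed form `delta = (r - 1) / r`.
#' With three shift categories this is 2/3, whatever the number of columns.
#'
#' @param table an [mr_table()].
#' @return the correction factor, a number in (0, 1].
#' @export
correction_factor <- function(table) {
  stopifnot(inherits(table, "mr_table"))
  r <- nrow(table$counts)
  if (r < 2L) stop("need at least two shift categories")
  (r - 1) / r
}

#' Modified and corrected chi-squared test for a multiple-response table
#'
#' Computes the naive Pearson statistic on the marginal table
#' (chi2_modified), divides it by the design correction factor `delta`
#' (chi2_corrected = chi2_modified / delta; since `delta < 1` the correction
#' strictly increases the statistic), and refers the corrected statistic to
#' the chi-squared law with `r(c-1)` degrees of freedom.
#'
#' @param table an [mr_table()].
#' @return an `mr_chisq` object: `chi2_modified`, `delta`,
#'   `chi2_corrected`, `df`, `p_value`.
#' @export
corrected_test <- function(table) {
  np <- naive_pearson(table)
  delta <- correction_factor(table)
  chi2_c <- np$statistic / delta
  structure(list(chi2_modified = np$statistic,
                 delta = delta,
                 chi2_corrected = chi2_c,
                 df = np$df,
                 p_value = stats::pchisq(chi2_c, np$df, lower.tail = FALSE)),
            class = "mr_chisq")
}

#' @export
print.mr_chisq <- function(x, digits = 3, ...) {
  cat(sprintf(paste0(
    "Modified chi-squared test for multiple-response tables\n",
    "  modified chi2(%d) = %.*f, correction factor delta = %.*f\n",
    "  corrected chi2(%d) = %.*f, p = %.*f\n"),
    x$df, digits, x$chi2_modified, digits, x$delta,
    x$df, digits, x$chi2_corrected, digits, x$p_value))
  invisible(x)
}
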