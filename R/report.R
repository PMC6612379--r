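# End-to-end pipeline: recordings -> indices -> classification -> tables ->
# modified chi-squared tests -> correspondence analysis, plus crosstab-style
# percentage tables and on-disk report rendering.

round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Within-condition percentage table with row-margin totals
#'
#' Converts a count table to the display form used for crosstabulations:
#' each cell is `100 * count / column total`, and a final `Total` column
#' gives `100 * row total / grand total`. Percentages are rounded half-up
#' to one decimal place, so every column sums to 100 within rounding slack.
#'
#' @param counts an [mr_table()].
#' @return numeric matrix, rows as in `counts`, columns as in `counts` plus
#'   `"Total"`.
#' @export
percentage_table <- function(counts) {
  stopifnot(inherits(counts, "mr_table"))
  m <- counts$counts
  pct <- sweep(100 * m, 2, colSums(m), `/`)
  out <- cbind(pct, Total = 100 * rowSums(m) / sum(m))
  round_half_up(out, 1)
}

#' Run the full association pipeline
#'
#' Either processes a cohort of recordings (indices, classification against
#' rest, tabulation) or starts from pre-tabulated count tables, then runs
#' the corrected chi-squared test on each table, renders within-condition
#' percentage tables, and fits a correspondence analysis only to tables
#' whose corrected test is significant at `alpha` (the map is a display of
#' a significant association, not a test in itself).
#'
#' @param cohort list of `ppr_recording` covering all four conditions for
#'   every subject (e.g. from [generate_cohort()]); ignored when `tables`
#'   is given.
#' @param tables optional list with elements `lateral` and/or `ap`, each an
#'   [mr_table()], to analyse directly (skipping classification).
#' @param epsilon_pp no-change tolerance for classification.
#' @param alpha significance level gating the correspondence analysis.
#' @param aggregate time-aggregation for [compute_distribution()].
#' @param out_dir optional directory; when given, the report is persisted
#'   as CSV/JSON files (see [write_report()]).
#' @return a `study_report` list: `indices` (NULL when starting from
#'   tables), `tables`, `percentages`, `tests`, `ca` (per analysed table:
#'   a `ca_result` or NULL when not significant), `alpha`, `epsilon_pp`.
#' @export
run_pipeline <- function(cohort = NULL, tables = NULL, epsilon_pp = 0.5,
                         alpha = 0.05, aggregate = "mean", out_dir = NULL) {
  indices <- NULL
  if (is.null(tables)) {
    if (is.null(cohort)) stop("provide either 'cohort' or 'tables'")
    indices <- index_table(cohort, aggregate = aggregate)
    labels <- classify_cohort(indices, epsilon_pp)
    tables <- list(lateral = tabulate_lateral(labels$lateral),
                   ap = tabulate_ap(labels$ap))
  }
  stopifnot(all(vapply(tables, inherits, TRUE, "mr_table")))
  # a table with an empty shift category (e.g. a noiseless null cohort where
  # nobody shifts) has no well-defined test; it is reported without one
  tests <- lapply(tables, function(tb)
    if (all(rowSums(tb$counts) > 0)) corrected_test(tb) else NULL)
  percentages <- lapply(tables, percentage_table)
  ca <- lapply(names(tables), function(nm)
    if (!is.null(tests[[nm]]) && tests[[nm]]$p_value < alpha)
      correspondence_analysis(tables[[nm]]) else NULL)
  names(ca) <- names(tables)
  report <- structure(list(indices = indices, tables = tables,
                           percentages = percentages, tests = tests,
                           ca = ca, alpha = alpha, epsilon_pp = epsilon_pp),
                      class = "study_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("Study report:", paste(names(x$tables), collapse = ", "), "analyses\n")
  for (nm in names(x$tables)) {
    cat("\n==", nm, "shift x condition ==\n")
    print(x$tables[[nm]]$counts)
    if (is.null(x$tests[[nm]])) {
      cat("  no test: a shift category is empty\n")
      next
    }
    print(x$tests[[nm]])
    if (!is.null(x$ca[[nm]]))
      cat(sprintf("  significant at alpha = %g; CA axes explain %s%% of inertia\n",
                  x$alpha,
                  paste(sprintf("%.1f", x$ca[[nm]]$axis_inertia_pct),
                        collapse = " / ")))
    else
      cat(sprintf("  not significant at alpha = %g; no CA fitted\n", x$alpha))
  }
  invisible(x)
}

#' Persist a study report as CSV and JSON files
#'
#' Writes, per analysed table, the counts (`table_<name>.csv`), the
#' percentage crosstabulation (`percentages_<name>.csv`) and, when fitted,
#' the factorial-plane coordinates (`ca_<name>.csv`); per-recording indices
#' go to `indices.csv` and all test statistics to `tests.json`. Output is a
#' deterministic function of the report, so regenerating a report from the
#' same inputs reproduces the files byte for byte.
#'
#' @param report a `study_report`.
#' @param out_dir directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(report$indices))
    utils::write.csv(report$indices, file.path(out_dir, "indices.csv"),
                     row.names = FALSE, quote = FALSE)
  for (nm in names(report$tables)) {
    write_count_table(report$tables[[nm]],
                      file.path(out_dir, paste0("table_", nm, ".csv")))
    p <- report$percentages[[nm]]
    utils::write.csv(data.frame(Shift = rownames(p), p, check.names = FALSE),
                     file.path(out_dir, paste0("percentages_", nm, ".csv")),
                     row.names = FALSE, quote = FALSE)
    if (!is.null(report$ca[[nm]])) {
      k <- length(report$ca[[nm]]$singular_values)
      pl <- factorial_plane(report$ca[[nm]], 1, min(2, k))
      utils::write.csv(pl, file.path(out_dir, paste0("ca_", nm, ".csv")),
                       row.names = FALSE, quote = FALSE)
    }
  }
  tests <- lapply(report$tests, function(t)
    if (is.null(t)) NULL
    else t[c("chi2_modified", "delta", "chi2_corrected", "df", "p_value")])
  jsonlite::write_json(list(alpha = report$alpha,
                            epsilon_pp = report$epsilon_pp,
                            tests = tests),
                       file.path(out_dir, "tests.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
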