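#' Yates-corrected chi-square test on a 2x2 table
#'
#' Pearson chi-square with Yates continuity correction on a 2x2
#' contingency table (rows = groups, columns = outcomes), 1 degree of
#' freedom, p-value from the upper tail. The correction is clamped so the
#' statistic is 0 (p = 1) when the |O - E| adjustment would cross zero.
#' A validity note is attached when any expected cell count is below 5.
#'
#' @param tbl 2x2 matrix of non-negative counts.
#' @return list with `statistic`, `p_value`, `df` (= 1), and logical
#'   `expected_lt_5`.
#' @export
yates_chi2 <- function(tbl) {
  tbl <- as.matrix(tbl)
  if (!all(dim(tbl) == c(2, 2))) stop("table must be 2x2", call. = FALSE)
  if (any(tbl < 0) || sum(tbl) == 0) stop("invalid counts", call. = FALSE)
  if (any(rowSums(tbl) == 0) || any(colSums(tbl) == 0)) {
    stop("zero row or column marginal", call. = FALSE)
  }
  expected <- outer(rowSums(tbl), colSums(tbl)) / sum(tbl)
  ct <- suppressWarnings(chisq.test(tbl, correct = TRUE))
  list(statistic = unname(ct$statistic), p_value = unname(ct$p.value),
       df = 1L, expected_lt_5 = any(expected < 5))
}

#' Subgroup accuracy report with a chi-square homogeneity test
#'
#' Splits the evaluated samples by a two-level attribute, reports
#' correct/incorrect prediction counts and accuracy per level, and tests
#' whether accuracy differs between the levels with [yates_chi2()] on the
#' 2x2 (level x correct/incorrect) table. When the attribute does not have
#' exactly two observed levels the table is still reported but the p-value
#' is `NA` (with a warning).
#'
#' @param records data.frame with an `nrs_score` column and the attribute
#'   column.
#' @param predictions factor of predicted classes aligned with `records`
#'   (levels as in [nrs_class()]).
#' @param attribute name of the grouping column, e.g. `"age_group"`,
#'   `"gender"`, or `"site"`.
#' @return list with `attribute`, `levels` (data.frame: level, correct,
#'   incorrect, total, accuracy), `chi2`, `p_value`, `correction`.
#' @export
subgroup_report <- function(records, predictions, attribute) {
  stopifnot(attribute %in% names(records),
            nrow(records) == length(predictions))
  truth <- nrs_class(records$nrs_score)
  ok <- predictions == truth
  lev <- sort(unique(as.character(records[[attribute]])))
  tab <- data.frame(
    level = lev,
    correct = vapply(lev, function(l)
      sum(ok & records[[attribute]] == l), numeric(1)),
    incorrect = vapply(lev, function(l)
      sum(!ok & records[[attribute]] == l), numeric(1)),
    row.names = NULL
  )
  tab$total <- tab$correct + tab$incorrect
  tab$accuracy <- tab$correct / tab$total
  chi2 <- NA_real_; p <- NA_real_
  if (length(lev) == 2 && all(tab$total > 0) &&
      sum(tab$correct) > 0 && sum(tab$incorrect) > 0) {
    ct <- yates_chi2(as.matrix(tab[, c("correct", "incorrect")]))
    chi2 <- ct$statistic; p <- ct$p_value
  } else {
    warning("attribute does not form a valid 2x2 table; p-value unavailable")
  }
  list(attribute = attribute, levels = tab, chi2 = chi2, p_value = p,
       correction = "yates")
}

#' Format a subgroup report as a compact table
#'
#' Accuracies are rounded to one decimal place (percent); the full
#' precision remains available in the report object.
#'
#' @param report output of [subgroup_report()].
#' @return data.frame mirroring the report layout.
#' @export
format_subgroup_report <- function(report) {
  df <- report$levels
  df$accuracy_pct <- round(100 * df$accuracy, 1)
  df$p_value <- c(round(report$p_value, 3), rep(NA, nrow(df) - 1))
  df
}
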