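#' Format a count with its group percentage
#'
#' Renders categorical cells as `"count (pct%)"` with the percentage to one
#' decimal and the group size as denominator, e.g. `134` of `156` gives
#' `"134 (85.9%)"`.
#'
#' @param count numerator.
#' @param n group size.
#' @return Character scalar.
#' @export
format_count_pct <- function(count, n) {
  pct <- if (n > 0) 100 * count / n else 0
  sprintf("%d (%.1f%%)", count, pct)
}

#' Descriptive table by group
#'
#' Per-group descriptives in the conventional layout: mean (SD) for
#' continuous variables, count (percentage of the group n, one decimal) for
#' flags, and category counts/percentages for the three-way laterality
#' outcome. Only variables present in the table are summarized.
#'
#' @param cohort analysis table (one row per child).
#' @param group name of the grouping column.
#' @return Data frame with one row per variable and one character column
#'   per group level.
#' @export
summarize_cohort <- function(cohort, group = "group") {
  g <- factor(cohort[[group]])
  continuous <- intersect(
    c("age", "performance_iq", battery_norms()$measure[battery_norms()$language],
      "ehi_li", "qhp_score", "li", "pct_left", "pct_right", "mean_words",
      "n_valid"),
    names(cohort))
  flags <- intersect(c("ehi_right", "qhp_right", "consistent"), names(cohort))
  rows <- list()
  add <- function(name, cells) rows[[length(rows) + 1L]] <<-
    c(list(variable = name), as.list(cells))

  if ("sex" %in% names(cohort))
    add("sex_male", tapply(seq_along(g), g, function(i)
      format_count_pct(sum(cohort$sex[i] == "M"), length(i))))
  for (v in continuous)
    add(v, tapply(cohort[[v]], g, function(x)
      sprintf("%.1f (%.1f)", mean(x, na.rm = TRUE), stats::sd(x, na.rm = TRUE))))
  for (v in flags)
    add(v, tapply(seq_along(g), g, function(i)
      format_count_pct(sum(cohort[[v]][i], na.rm = TRUE), length(i))))
  if ("category" %in% names(cohort))
    for (lv in c("left", "bilateral", "right"))
      add(paste0("laterality_", lv), tapply(seq_along(g), g, function(i)
        format_count_pct(sum(cohort$category[i] == lv, na.rm = TRUE),
                         length(i))))
  out <- do.call(rbind, lapply(rows, as.data.frame))
  names(out) <- c("variable", levels(g))
  out
}
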