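#' Replicated Spearman correlation screen between laterality and language
#'
#' The laterality index is not normally distributed, so rank correlations
#' are used. To respect the non-independence of twins, correlations are
#' computed separately in the twin-1 and twin-2 subsamples. Within each
#' subsample the family of tests (13 language measures plus performance IQ)
#' is Holm-adjusted, and a correlation counts as replicated only if its
#' adjusted p-value is below `alpha` in *both* subsamples. The screen is
#' typically run twice: on the signed LI and on its absolute value
#' (strength of laterality).
#'
#' @param cohort data frame with the target, measure and `twin_label`
#'   columns.
#' @param target name of the laterality column (e.g. `"li"`), or a numeric
#'   vector aligned with `cohort`.
#' @param measures character vector of measure column names; defaults to
#'   the full battery of [battery_norms()].
#' @param twin name of the twin-label column.
#' @param alpha significance level, default 0.05.
#' @return Data frame: one row per measure with `rho1`, `p1`, `p_adj1`,
#'   `rho2`, `p2`, `p_adj2`, `replicated`. Measures with fewer than 3
#'   complete observations in a subsample are omitted with a warning.
#' @export
spearman_replication <- function(cohort, target = "li",
                                 measures = battery_norms()$measure,
                                 twin = "twin_label", alpha = 0.05) {
  tv <- if (is.character(target)) cohort[[target]] else target
  one_sample <- function(sel) {
    res <- lapply(measures, function(m) {
      x <- tv[sel]; y <- cohort[[m]][sel]
      ok <- !is.na(x) & !is.na(y)
      if (sum(ok) < 3) return(NULL)
      ct <- stats::cor.test(x[ok], y[ok], method = "spearman", exact = FALSE)
      data.frame(measure = m, rho = unname(ct$estimate), p = ct$p.value)
    })
    drop <- vapply(res, is.null, logical(1))
    if (any(drop))
      warning("omitted (fewer than 3 complete observations): ",
              paste(measures[drop], collapse = ", "))
    out <- do.call(rbind, res)
    out$p_adj <- stats::p.adjust(out$p, method = "holm")
    out
  }
  s1 <- one_sample(cohort[[twin]] == 1)
  s2 <- one_sample(cohort[[twin]] == 2)
  tab <- merge(s1, s2, by = "measure", suffixes = c("1", "2"))
  tab$replicated <- tab$p_adj1 < alpha & tab$p_adj2 < alpha
  tab[match(measures[measures %in% tab$measure], tab$measure), ]
}

#' Cohen's d for a two-group difference
#'
#' Standardized mean difference using the unweighted root-mean of the two
#' group variances as the pooling denominator.
#'
#' @param mean1,sd1 mean and SD of group 1.
#' @param mean2,sd2 mean and SD of group 2.
#' @return Cohen's d (group 1 minus group 2).
#' @export
cohens_d <- function(mean1, sd1, mean2, sd2) {
  stopifnot(sd1 > 0, sd2 > 0)
  (mean1 - mean2) / sqrt((sd1^2 + sd2^2) / 2)
}
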