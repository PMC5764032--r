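#' Linear mixed model with a twin-pair random intercept
#'
#' Fits `outcome ~ fixed effects + (1 | pair)` by REML, with Satterthwaite
#' degrees of freedom for the fixed-effect t-tests and estimated marginal
#' means (at balanced factor levels) with 95% CIs for the first fixed
#' factor. This is the workhorse for every continuous between-group
#' comparison in a twin cohort, where pair membership induces
#' non-independence.
#'
#' @param data data frame.
#' @param outcome name of the continuous outcome column.
#' @param fixed character vector of fixed-effect column names (first one is
#'   the focus term for marginal means), default `"group"`.
#' @param pair name of the pair-id column, default `"pair_id"`.
#' @return An `ftcd_model` list: `kind`, `formula`, `coef` (estimate, SE,
#'   Satterthwaite df, t, p per fixed term), `emmeans`, `varcomp` (pair and
#'   residual variances), `singular`, `n`, `fit` (the lmerTest object).
#' @export
fit_lmm <- function(data, outcome, fixed = "group", pair = "pair_id") {
  data <- stats::na.omit(data[c(outcome, setdiff(fixed, "1"), pair)])
  if (length(unique(data[[pair]])) < 2) stop("need at least 2 pairs")
  fml <- stats::as.formula(paste(outcome, "~", paste(fixed, collapse = " + "),
                                 "+ (1 |", pair, ")"))
  fit <- suppressMessages(lmerTest::lmer(fml, data = data))
  sm <- summary(fit, ddf = "Satterthwaite")
  co <- as.data.frame(sm$coefficients)
  names(co) <- c("estimate", "se", "df", "t", "p")
  vc <- as.data.frame(lme4::VarCorr(fit))
  em <- NULL
  if (is.factor(data[[fixed[1]]]) || is.character(data[[fixed[1]]])) {
    em <- as.data.frame(emmeans::emmeans(fit, stats::as.formula(
      paste("~", fixed[1]))))
  }
  structure(list(kind = "lmm", formula = deparse(fml), coef = co,
                 emmeans = em,
                 varcomp = stats::setNames(vc$vcov, vc$grp),
                 singular = lme4::isSingular(fit),
                 n = nrow(data), fit = fit),
            class = "ftcd_model")
}

#' Multilevel binary logistic regression with a pair random intercept
#'
#' Fits `outcome ~ group + (1 | pair)` by Laplace-approximate ML and reports
#' the odds ratio for the group term with profile-likelihood 95% CIs,
#' falling back to Wald CIs (with a note) if profiling fails. Complete
#' separation is flagged and no OR is reported.
#'
#' @param data data frame.
#' @param outcome name of a logical/0-1 outcome column.
#' @param group name of the binary predictor, default `"group"`.
#' @param pair name of the pair-id column, default `"pair_id"`.
#' @return An `ftcd_model` list with `coef` (log-odds scale), `or`,
#'   `or_ci95`, `ci_method`, `separation`, `n`, `fit`.
#' @export
fit_multilevel_logistic <- function(data, outcome, group = "group",
                                    pair = "pair_id") {
  data <- stats::na.omit(data[c(outcome, group, pair)])
  y <- data[[outcome]]
  if (length(unique(as.integer(as.logical(y)))) < 2)
    stop("both outcome levels must be present")
  fml <- stats::as.formula(paste(outcome, "~", group, "+ (1 |", pair, ")"))
  fit <- suppressMessages(lme4::glmer(fml, data = data, family = stats::binomial))
  sm <- summary(fit)
  co <- as.data.frame(sm$coefficients)
  names(co) <- c("estimate", "se", "z", "p")
  b <- co$estimate[2]
  separation <- abs(b) > 10 || co$se[2] > 50
  or <- or_ci <- NULL
  ci_method <- NA_character_
  if (!separation) {
    or <- exp(b)
    prof <- tryCatch(
      suppressMessages(stats::confint(fit, parm = rownames(co)[2],
                                      method = "profile", quiet = TRUE)),
      error = function(e) NULL, warning = function(w) NULL)
    if (!is.null(prof) && all(is.finite(prof))) {
      or_ci <- exp(as.numeric(prof))
      ci_method <- "profile"
    } else {
      or_ci <- exp(b + c(-1.96, 1.96) * co$se[2])
      ci_method <- "wald (profile failed)"
    }
  }
  structure(list(kind = "logistic", formula = deparse(fml), coef = co,
                 or = or, or_ci95 = or_ci, ci_method = ci_method,
                 separation = separation,
                 singular = lme4::isSingular(fit),
                 n = nrow(data), fit = fit),
            class = "ftcd_model")
}

#' Variance explained over and above the pair random effect
#'
#' Proportional reduction in residual variance from a reduced to a full
#' linear mixed model sharing the same random-effect structure and differing
#' only in the fixed predictor, floored at 0.
#'
#' @param full,reduced `ftcd_model` objects from [fit_lmm()].
#' @return Pseudo-R-squared value.
#' @export
pseudo_r2 <- function(full, reduced) {
  if (!identical(full$kind, "lmm") || !identical(reduced$kind, "lmm"))
    stop("both models must be linear mixed models")
  vf <- full$varcomp[["Residual"]]
  vr <- reduced$varcomp[["Residual"]]
  max((vr - vf) / vr, 0)
}

#' Mixed model for right-reach probability across spatial positions
#'
#' Models the per-position right-reach proportion from the card-reaching
#' task with spatial position (numeric 1-7) as a within-child factor, group
#' as a between factor, their interaction, and random intercepts for twin
#' pair and for child nested in pair (each child contributes seven rows).
#' Reports Satterthwaite t-tests for the three terms.
#'
#' @param cohort data frame with `qhp_pos1`..`qhp_pos7`, a group column and
#'   pair/child ids.
#' @param group,pair,child column names.
#' @return An `ftcd_model` list; `coef` has rows for position, group and
#'   the interaction.
#' @export
qhp_position_model <- function(cohort, group = "group", pair = "pair_id",
                               child = "child_id") {
  pc <- paste0("qhp_pos", 1:7)
  stopifnot(all(pc %in% names(cohort)))
  long <- data.frame(
    child_id = rep(cohort[[child]], each = 7),
    pair_id = rep(cohort[[pair]], each = 7),
    group = rep(cohort[[group]], each = 7),
    position = rep(1:7, nrow(cohort)),
    prop = as.vector(t(as.matrix(cohort[pc]))))
  fit <- lmerTest::lmer(prop ~ position * group + (1 | pair_id / child_id),
                        data = long)
  sm <- summary(fit, ddf = "Satterthwaite")
  co <- as.data.frame(sm$coefficients)
  names(co) <- c("estimate", "se", "df", "t", "p")
  structure(list(kind = "lmm", formula = "prop ~ position * group + (1 | pair/child)",
                 coef = co, varcomp = NULL,
                 singular = lme4::isSingular(fit),
                 n = nrow(long), fit = fit),
            class = "ftcd_model")
}

#' @export
print.ftcd_model <- function(x, ...) {
  cat(sprintf("<ftcd_model> %s: %s (n = %d)\n", x$kind, x$formula, x$n))
  print(round(x$coef, 4))
  if (!is.null(x$or))
    cat(sprintf("OR = %.3f [%.3f, %.3f] (%s)\n", x$or, x$or_ci95[1],
                x$or_ci95[2], x$ci_method))
  invisible(x)
}
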