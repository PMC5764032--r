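#' Expected rate of the >=2-of-13 flag rule under the norm model
#'
#' Brute-force Monte-Carlo estimate of the probability that a child whose 13
#' standardized language scores follow an equicorrelated normal model (with
#' a common latent shift subtracted) is flagged on two or more measures,
#' where a flag means falling strictly more than 1 SD below the norm.
#' Serves as the calibration oracle for the cohort generator's DLD
#' prevalence.
#'
#' @param shift latent shift in SD units (0 for the unshifted norm model).
#' @param rho inter-measure correlation.
#' @param n_measures number of measures (default 13).
#' @param n_sim Monte-Carlo draws.
#' @return Estimated probability.
#' @export
expected_dld_rate <- function(shift, rho, n_measures = 13, n_sim = 4000) {
  f <- stats::rnorm(n_sim)
  e <- matrix(stats::rnorm(n_sim * n_measures), n_sim)
  z <- sqrt(rho) * f + sqrt(1 - rho) * e - shift
  mean(rowSums(z < -1) >= 2)
}

#' Generate normed language and cognitive scores for a cohort
#'
#' Scores on the 13 language/literacy measures follow an equicorrelated
#' multivariate normal on each measure's norm scale. Children destined for
#' the DLD class receive a common negative latent shift so the downstream
#' >=2-of-13 flag classifier reproduces the target prevalence; they also
#' receive a (smaller) performance-IQ disadvantage, mirroring the typical
#' nonverbal gap between groups.
#'
#' @param truth ground-truth table from [generate_cohort()] (needs
#'   `destined_dld`).
#' @param params list with `rho`, `dld_latent_shift`, `iq_group_shift` and
#'   `norms` (defaults to [battery_norms()]).
#' @param seed integer seed; `NULL` continues the current stream.
#' @return Data frame, one row per child, columns named as in
#'   [battery_norms()].
#' @export
generate_language_scores <- function(truth, params, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  norms <- params$norms
  if (is.null(norms)) norms <- battery_norms()
  rho <- params$rho
  if (rho < 0 || rho >= 1)
    stop("inter-measure correlation target not positive definite")
  lang <- norms[norms$language, ]
  nm <- nrow(lang)
  n <- nrow(truth)
  f <- stats::rnorm(n)
  z <- sqrt(rho) * f + sqrt(1 - rho) * matrix(stats::rnorm(n * nm), n)
  z <- z - params$dld_latent_shift * truth$destined_dld
  scores <- sweep(sweep(z, 2, lang$norm_sd, `*`), 2, lang$norm_mean, `+`)
  colnames(scores) <- lang$measure
  iqn <- norms[norms$measure == "performance_iq", ]
  iq <- iqn$norm_mean + iqn$norm_sd *
    (stats::rnorm(n) - params$iq_group_shift * truth$destined_dld)
  out <- as.data.frame(scores)
  out$performance_iq <- iq
  out
}

#' Generate handedness behaviour for a cohort
#'
#' Each child's handedness latent drives both instruments. EHI items are
#' drawn from a three-way choice: "both" with a small fixed probability,
#' otherwise "right" with probability `plogis(item_slope * latent)`. QHP
#' reaches (3 per position, positions 1-7) are right-handed with probability
#' `plogis(qhp_latent_slope * latent + qhp_pos_slope * (position - 4))`, a
#' monotone link making right reaches hardest in left hemispace. A child
#' with latent 0 has an expected QHP score of 10.5 by symmetry of the link
#' around the midline position.
#'
#' @param truth ground-truth table (needs `child_id`, `hand_latent`).
#' @param params list with `item_slope`, `both_rate`, `qhp_latent_slope`,
#'   `qhp_pos_slope`.
#' @param seed integer seed; `NULL` continues the current stream.
#' @return List with `ehi_items` (data frame: `child_id` + `item1`..`item10`)
#'   and `qhp_reaches` (long data frame: `child_id`, `position`, `hand`).
#' @export
generate_handedness <- function(truth, params, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(truth)
  h <- truth$hand_latent

  p_right <- stats::plogis(params$item_slope * h)
  items <- matrix("", n, 10)
  for (j in 1:10) {
    u <- stats::runif(n)
    items[, j] <- ifelse(u < params$both_rate, "both",
                         ifelse(stats::runif(n) < p_right, "right", "left"))
  }
  ehi <- data.frame(child_id = truth$child_id, items)
  names(ehi) <- c("child_id", paste0("item", 1:10))

  pos <- rep(rep(1:7, each = 3), n)
  child <- rep(truth$child_id, each = 21)
  pr <- stats::plogis(params$qhp_latent_slope * rep(h, each = 21) +
                        params$qhp_pos_slope * (pos - 4))
  qhp <- data.frame(child_id = child, position = pos,
                    hand = ifelse(stats::runif(n * 21) < pr, "right", "left"))
  list(ehi_items = ehi, qhp_reaches = qhp)
}
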