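#' Grand-average curves over accepted trials
#'
#' Pointwise means of the left and right MCA signals across all accepted
#' epochs, plus the left-minus-right difference curve that carries the
#' lateralised response.
#'
#' @param epochs `ftcd_epochs`, baseline-corrected.
#' @return List with `rel_time`, `left`, `right`, `diff` (left − right) and
#'   `n` (number of accepted epochs averaged).
#' @export
grand_average <- function(epochs) {
  acc <- accepted_epochs(epochs)
  if (!length(acc)) stop("zero accepted epochs")
  L <- rowMeans(do.call(cbind, lapply(acc, `[[`, "left")))
  R <- rowMeans(do.call(cbind, lapply(acc, `[[`, "right")))
  list(rel_time = acc[[1]]$rel_time, left = L, right = R, diff = L - R,
       n = length(acc))
}

#' Laterality index from the grand-average difference curve
#'
#' Within the period of interest the time point with the greatest absolute
#' left-right difference is located (earliest sample on ties, so that
#' right-dominant children with a negative difference get a meaningful
#' peak), a window of `window_width` seconds centred on it is constructed
#' (clipped to the epoch's extent), and the LI is the signed mean of the
#' difference curve over that window.
#'
#' @param ga grand-average list from [grand_average()].
#' @param poi period of interest in seconds relative to talk onset, closed
#'   at sample resolution; default `c(4, 14)` (commences 4 s into the talk
#'   phase, lasts 10 s).
#' @param window_width peak window width in seconds, default 2.
#' @return List with `li`, `peak_time`, `window` (length-2 numeric).
#' @export
compute_li <- function(ga, poi = c(4, 14), window_width = 2) {
  t <- ga$rel_time
  eps <- 1e-9
  if (poi[1] < min(t) - eps || poi[2] > max(t) + eps)
    stop("POI outside epoch window")
  in_poi <- which(t >= poi[1] - eps & t <= poi[2] + eps)
  pk <- in_poi[which.max(abs(ga$diff[in_poi]))]
  peak_time <- t[pk]
  half <- window_width / 2
  win <- c(max(peak_time - half, min(t)), min(peak_time + half, max(t)))
  sel <- t >= win[1] - eps & t <= win[2] + eps
  list(li = mean(ga$diff[sel]), peak_time = peak_time, window = win)
}

#' Trial-wise LIs, standard error and 95% confidence interval
#'
#' Trial-by-trial LIs are the mean left-minus-right difference over the peak
#' window fixed by [compute_li()], one per accepted trial. The standard
#' error is their standard deviation (n − 1 denominator) divided by the
#' square root of the number of valid trials; the 95% CI is the overall LI
#' plus/minus `ci_mult` times the SE.
#'
#' @param epochs baseline-corrected `ftcd_epochs`.
#' @param window peak window from [compute_li()].
#' @param li the grand-average LI the CI is centred on.
#' @param ci_mult CI multiplier, default 1.96 (normal 95%).
#' @return List with `trial_lis`, `se`, `ci95`.
#' @export
li_se_ci <- function(epochs, window, li, ci_mult = 1.96) {
  acc <- accepted_epochs(epochs)
  if (length(acc) < 2) stop("need at least 2 accepted epochs")
  trial_lis <- vapply(acc, function(e) {
    sel <- e$rel_time >= window[1] - 1e-9 & e$rel_time <= window[2] + 1e-9
    mean(e$left[sel] - e$right[sel])
  }, numeric(1))
  se <- stats::sd(trial_lis) / sqrt(length(trial_lis))
  list(trial_lis = trial_lis, se = se,
       ci95 = c(li - ci_mult * se, li + ci_mult * se))
}

#' Categorise laterality from the LI confidence interval
#'
#' Left if the CI lies entirely above zero, right if entirely below, and
#' bilateral if the CI crosses zero — read inclusively, so an endpoint
#' exactly at zero counts as crossing.
#'
#' @param li laterality index (unused beyond sign consistency; kept for a
#'   self-describing call signature).
#' @param ci95 numeric length-2 confidence interval.
#' @return `"left"`, `"bilateral"` or `"right"`.
#' @export
categorise_laterality <- function(li, ci95) {
  if (ci95[1] > 0) "left" else if (ci95[2] < 0) "right" else "bilateral"
}

#' Usability of a child's laterality data
#'
#' A child's fTCD data are usable only with at least `min_trials` accepted
#' trials (the LI is unreliable on fewer) and a non-extreme LI
#' (|LI| <= `li_cap`).
#'
#' @param n_valid number of accepted trials.
#' @param li laterality index.
#' @param min_trials minimum accepted trials, default 12.
#' @param li_cap extreme-LI exclusion bound, default 10.
#' @return List with `usable` (logical) and `reason` (`NA` if usable).
#' @export
usability <- function(n_valid, li, min_trials = 12, li_cap = 10) {
  if (n_valid < min_trials) return(list(usable = FALSE, reason = "too few trials"))
  if (abs(li) > li_cap) return(list(usable = FALSE, reason = "extreme LI"))
  list(usable = TRUE, reason = NA_character_)
}

#' Split-half LIs from odd and even trials
#'
#' Accepted epochs are split by 1-based order into odd and even halves and
#' the full grand-average + peak-window LI procedure is re-run independently
#' in each half (each half finds its own peak and window).
#'
#' @param epochs baseline-corrected `ftcd_epochs`.
#' @inheritParams compute_li
#' @return List with `li_odd`, `li_even` (either `NA` if its half is empty).
#' @export
split_half <- function(epochs, poi = c(4, 14), window_width = 2) {
  acc <- accepted_epochs(epochs)
  half_li <- function(idx) {
    if (!length(idx)) return(NA_real_)
    h <- structure(acc[idx], class = "ftcd_epochs")
    compute_li(grand_average(h), poi, window_width)$li
  }
  k <- seq_along(acc)
  list(li_odd = half_li(k[k %% 2 == 1]), li_even = half_li(k[k %% 2 == 0]))
}

#' Split-half reliability across a cohort
#'
#' Pearson correlation between odd- and even-trial LIs across usable
#' children; children with an empty half are omitted with a warning.
#'
#' @param results list of laterality results from [process_recording()].
#' @return Correlation coefficient.
#' @export
cohort_reliability <- function(results) {
  odd <- vapply(results, `[[`, numeric(1), "li_odd")
  even <- vapply(results, `[[`, numeric(1), "li_even")
  usable <- vapply(results, `[[`, logical(1), "usable")
  ok <- usable & !is.na(odd) & !is.na(even)
  if (any(usable & !ok))
    warning(sprintf("%d usable children omitted from reliability (empty half)",
                    sum(usable & !ok)))
  stats::cor(odd[ok], even[ok])
}

#' Percent change in blood flow during the period of interest
#'
#' For each MCA, the mean of the baseline-corrected, normalized signal over
#' the period of interest, averaged over accepted trials. Because channels
#' are normalized to mean 100 and baseline-corrected, a positive value is a
#' percent increase over baseline and a negative value a percent decrease.
#'
#' @param epochs baseline-corrected `ftcd_epochs`.
#' @param poi period of interest, default `c(4, 14)`.
#' @return List with `pct_left`, `pct_right`.
#' @export
percent_change <- function(epochs, poi = c(4, 14)) {
  ga <- grand_average(epochs)
  sel <- ga$rel_time >= poi[1] - 1e-9 & ga$rel_time <= poi[2] + 1e-9
  list(pct_left = mean(ga$left[sel]), pct_right = mean(ga$right[sel]))
}

#' Default fTCD processing parameters
#'
#' Bundles every tunable of the laterality pipeline with its conventional
#' value: epoch window −12..+15 s, 12 s baseline, POI 4–14 s, 2 s peak
#' window, 1.96 CI multiplier, 12-trial usability minimum, |LI| cap 10,
#' normalized-range artefact bounds 60–140, dropout rule (4 scaled MADs,
#' single-sample runs), heart-rate band 40–200 bpm.
#'
#' @param ... overrides of any listed parameter.
#' @return Named list of parameters.
#' @export
ftcd_params <- function(...) {
  p <- list(epoch_window = c(-12, 15), baseline = c(-12, 0), poi = c(4, 14),
            window_width = 2, ci_mult = 1.96, min_trials = 12, li_cap = 10,
            artefact_bounds = c(60, 140), mad_k = 4, max_run = 1,
            min_rate = 40, max_rate = 200)
  ov <- list(...)
  bad <- setdiff(names(ov), names(p))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  p[names(ov)] <- ov
  p
}

#' Run the full laterality pipeline on one recording
#'
#' Processing chain: heart-cycle integration, provisional epoching, dropout
#' imputation, normalisation (constant computed from the retained epoched
#' samples), range-based artefact rejection, baseline correction, then
#' grand-averaging, the peak-window LI, its SE/CI and category, usability
#' screening, split-half LIs and per-MCA percent change. Imputation needs
#' trial context and must precede normalisation, hence epoching happens
#' before the normalisation step; the two orderings are equivalent because
#' normalisation is a single linear rescale.
#'
#' @param rec an [ftcd_recording()].
#' @param params parameter list from [ftcd_params()].
#' @return A `laterality_result` list: `child_id`, `li`, `peak_time`,
#'   `window`, `trial_lis`, `se`, `ci95`, `category`, `n_valid`, `usable`,
#'   `reason`, `pct_left`, `pct_right`, `li_odd`, `li_even`, `mean_words`,
#'   `n_markers`, `n_rejected`, `reject_reasons`, `n_imputed`.
#' @export
process_recording <- function(rec, params = ftcd_params()) {
  p <- params
  # dropout repair needs trial context and must see the raw signal (an
  # aberrant point would otherwise corrupt its heart-cycle mean and the
  # normalisation constant): provisional epoching -> imputation -> write
  # the repaired samples back, then integrate and epoch definitively.
  eps0 <- epoch_trials(rec, p$epoch_window)
  eps0 <- impute_dropouts(eps0, p$mad_k, p$max_run)
  rec <- write_back_epochs(rec, eps0, p$epoch_window)
  rec <- integrate_heart_cycles(rec, p$min_rate, p$max_rate)
  eps <- suppressWarnings(epoch_trials(rec, p$epoch_window))
  for (i in seq_along(eps)) {
    eps[[i]]$imputed <- eps0[[i]]$imputed
    if (eps0[[i]]$status == "rejected" && eps[[i]]$status == "accepted") {
      eps[[i]]$status <- "rejected"
      eps[[i]]$reason <- eps0[[i]]$reason
    }
  }
  eps <- normalise(eps)
  eps <- reject_artefact_trials(eps, p$artefact_bounds)
  eps <- baseline_correct(eps, p$baseline)

  acc <- accepted_epochs(eps)
  n_valid <- length(acc)
  reasons <- table(vapply(Filter(function(e) e$status == "rejected", eps),
                          `[[`, character(1), "reason"))
  res <- list(child_id = rec$child_id, n_valid = n_valid,
              n_markers = nrow(rec$markers),
              n_rejected = length(eps) - n_valid,
              reject_reasons = reasons,
              n_imputed = sum(vapply(eps, `[[`, integer(1), "imputed")))
  if (n_valid < 2) {
    res <- c(res, list(li = NA_real_, peak_time = NA_real_, window = NULL,
                       trial_lis = numeric(0), se = NA_real_, ci95 = NULL,
                       category = NA_character_, usable = FALSE,
                       reason = "too few trials", pct_left = NA_real_,
                       pct_right = NA_real_, li_odd = NA_real_,
                       li_even = NA_real_, mean_words = NA_real_))
    class(res) <- "laterality_result"
    return(res)
  }
  ga <- grand_average(eps)
  peak <- compute_li(ga, p$poi, p$window_width)
  sec <- li_se_ci(eps, peak$window, peak$li, p$ci_mult)
  use <- usability(n_valid, peak$li, p$min_trials, p$li_cap)
  sh <- split_half(eps, p$poi, p$window_width)
  pc <- percent_change(eps, p$poi)
  words <- vapply(acc, `[[`, numeric(1), "word_count")
  res <- c(res, list(
    li = peak$li, peak_time = peak$peak_time, window = peak$window,
    trial_lis = sec$trial_lis, se = sec$se, ci95 = sec$ci95,
    category = categorise_laterality(peak$li, sec$ci95),
    usable = use$usable, reason = use$reason,
    pct_left = pc$pct_left, pct_right = pc$pct_right,
    li_odd = sh$li_odd, li_even = sh$li_even,
    mean_words = mean(words)))
  class(res) <- "laterality_result"
  res
}

#' @export
print.laterality_result <- function(x, ...) {
  cat(sprintf("<laterality_result> child %s: LI = %.2f (SE %.2f), %s, %d/%d trials%s\n",
              x$child_id, x$li, x$se, x$category, x$n_valid, x$n_markers,
              if (isTRUE(x$usable)) "" else sprintf(" [unusable: %s]", x$reason)))
  invisible(x)
}
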