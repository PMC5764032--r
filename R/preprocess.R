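#' Cut a recording into trial epochs
#'
#' One epoch is produced per trial marker, on a relative time axis with 0 at
#' talk onset. The window is half-open (`[from, to)`) and sample-aligned.
#' Epochs that would extend outside the recording are dropped with a warning.
#' Trials flagged behaviourally invalid by the examiner (speaking during a
#' silent period, failing to talk during the talk phase) are kept but carry
#' status `rejected` with reason `"behaviour"`.
#'
#' @param rec an [ftcd_recording()].
#' @param window numeric length-2, epoch window in seconds relative to talk
#'   onset; default `c(-12, 15)` covering the 12 s viewing baseline, the 10 s
#'   talk phase and the post-talk gap.
#' @return A list of epochs (class `ftcd_epochs`). Each epoch has elements
#'   `trial`, `rel_time`, `left`, `right`, `status` (`"accepted"` or
#'   `"rejected"`), `reason`, `imputed`, `word_count`.
#' @export
epoch_trials <- function(rec, window = c(-12, 15)) {
  stopifnot(inherits(rec, "ftcd_recording"))
  if (nrow(rec$markers) == 0) stop("no trials")
  fs <- rec$sampling_rate
  n_samp <- round((window[2] - window[1]) * fs)
  rel_time <- window[1] + (seq_len(n_samp) - 1) / fs
  n <- length(rec$time)
  out <- list()
  for (k in seq_len(nrow(rec$markers))) {
    m <- rec$markers[k, ]
    i0 <- round((m$onset_s - rec$time[1] + window[1]) * fs) + 1L
    if (i0 < 1L || i0 + n_samp - 1L > n) {
      warning(sprintf("trial %d dropped: epoch extends outside recording",
                      m$trial))
      next
    }
    sel <- i0:(i0 + n_samp - 1L)
    ep <- list(trial = m$trial, rel_time = rel_time,
               left = rec$left[sel], right = rec$right[sel],
               status = if (isTRUE(m$valid)) "accepted" else "rejected",
               reason = if (isTRUE(m$valid)) NA_character_ else "behaviour",
               imputed = 0L, word_count = m$word_count)
    out[[length(out) + 1L]] <- ep
  }
  structure(out, class = "ftcd_epochs")
}

# dropout candidates: non-physiological values (<= 0) or gross deviations
# from the trial median in scaled-MAD units
dropout_candidates <- function(x, mad_k) {
  med <- stats::median(x)
  s <- stats::mad(x)
  x <= 0 | (s > 0 & abs(x - med) > mad_k * s)
}

impute_channel <- function(x, mad_k, max_run) {
  cand <- dropout_candidates(x, mad_k)
  if (all(cand)) return(list(x = x, n = NA_integer_))  # flat/dropout trial
  if (!any(cand)) return(list(x = x, n = 0L))
  fill <- mean(x[!cand])
  r <- rle(cand)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  n_imp <- 0L
  for (j in which(r$values & r$lengths <= max_run)) {
    x[starts[j]:ends[j]] <- fill
    n_imp <- n_imp + r$lengths[j]
  }
  list(x = x, n = n_imp)
}

#' Detect and impute brief signal dropouts within each trial
#'
#' Very brief dropouts (typically probe movement) appear as isolated aberrant
#' samples. A sample is a dropout candidate if its value is non-positive or
#' deviates from the trial median by more than `mad_k` scaled
#' median-absolute-deviations. Candidate runs of length at most `max_run`
#' are replaced by the mean of the trial's non-candidate samples; longer runs
#' are left for range-based artefact rejection. Imputation precedes
#' normalisation so that a single extreme value cannot distort the
#' normalisation constant. A trial whose samples are all candidates is
#' rejected with reason `"flat/dropout"`.
#'
#' @param epochs an `ftcd_epochs` list.
#' @param mad_k deviation threshold in scaled MAD units (default 4).
#' @param max_run longest candidate run to impute, in samples (default 1).
#' @return The epochs with imputed samples and per-epoch `imputed` counts
#'   updated.
#' @export
impute_dropouts <- function(epochs, mad_k = 4, max_run = 1) {
  for (i in seq_along(epochs)) {
    ep <- epochs[[i]]
    if (length(ep$left) < 10) stop("trial has fewer than 10 samples")
    l <- impute_channel(ep$left, mad_k, max_run)
    r <- impute_channel(ep$right, mad_k, max_run)
    if (is.na(l$n) || is.na(r$n)) {
      if (ep$status == "accepted") {
        ep$status <- "rejected"; ep$reason <- "flat/dropout"
      }
    } else {
      ep$left <- l$x; ep$right <- r$x
      ep$imputed <- ep$imputed + l$n + r$n
    }
    epochs[[i]] <- ep
  }
  epochs
}

#' Normalise velocity channels to a mean of 100
#'
#' Each channel is linearly rescaled so that its mean over all retained
#' samples is exactly 100, putting both MCAs on a common percent scale.
#' Works on a whole recording or on an epoch list (where the normalisation
#' constant is computed from all epoched samples after dropout imputation,
#' and the same per-channel constant is applied to every epoch).
#'
#' @param x an [ftcd_recording()] or `ftcd_epochs` list.
#' @return Object of the same class in normalized units.
#' @export
normalise <- function(x) UseMethod("normalise")

#' @export
normalise.ftcd_recording <- function(x) {
  ml <- mean(x$left); mr <- mean(x$right)
  if (ml <= 0 || mr <= 0) stop("non-positive channel mean")
  x$left <- x$left * (100 / ml)
  x$right <- x$right * (100 / mr)
  x
}

#' @export
normalise.ftcd_epochs <- function(x) {
  ml <- mean(unlist(lapply(x, `[[`, "left")))
  mr <- mean(unlist(lapply(x, `[[`, "right")))
  if (ml <= 0 || mr <= 0) stop("non-positive channel mean")
  for (i in seq_along(x)) {
    x[[i]]$left <- x[[i]]$left * (100 / ml)
    x[[i]]$right <- x[[i]]$right * (100 / mr)
  }
  x
}

#' Reject trials containing out-of-range samples
#'
#' After normalisation, any accepted epoch containing a sample outside
#' `bounds` on either channel is rejected with reason `"range"`. Epochs
#' already rejected (behaviour, flat/dropout) keep their original status.
#'
#' @param epochs normalized `ftcd_epochs`.
#' @param bounds numeric length-2 acceptance band in normalized units,
#'   default `c(60, 140)`.
#' @return Epochs with statuses updated.
#' @export
reject_artefact_trials <- function(epochs, bounds = c(60, 140)) {
  for (i in seq_along(epochs)) {
    ep <- epochs[[i]]
    if (ep$status != "accepted") next
    v <- c(ep$left, ep$right)
    if (any(v < bounds[1] | v > bounds[2])) {
      ep$status <- "rejected"; ep$reason <- "range"
      epochs[[i]] <- ep
    }
  }
  epochs
}

#' Baseline-correct epochs
#'
#' Subtracts, per channel and per epoch, the mean over the baseline window
#' (relative time `[-12, 0)`, the animation-viewing interval immediately
#' before the talk phase). Idempotent.
#'
#' @param epochs `ftcd_epochs`.
#' @param baseline numeric length-2 baseline window (half-open), default
#'   `c(-12, 0)`.
#' @return Baseline-corrected epochs.
#' @export
baseline_correct <- function(epochs, baseline = c(-12, 0)) {
  for (i in seq_along(epochs)) {
    ep <- epochs[[i]]
    sel <- ep$rel_time >= baseline[1] & ep$rel_time < baseline[2]
    if (!any(sel)) stop("empty baseline window")
    ep$left <- ep$left - mean(ep$left[sel])
    ep$right <- ep$right - mean(ep$right[sel])
    epochs[[i]] <- ep
  }
  epochs
}

accepted_epochs <- function(epochs) {
  Filter(function(e) e$status == "accepted", epochs)
}

# Write (possibly imputed) epoch samples back into the recording channels.
# Inverse of epoch_trials for the trials that produced full epochs.
write_back_epochs <- function(rec, epochs, window = c(-12, 15)) {
  fs <- rec$sampling_rate
  n_samp <- round((window[2] - window[1]) * fs)
  for (ep in epochs) {
    m <- rec$markers[rec$markers$trial == ep$trial, ]
    i0 <- round((m$onset_s - rec$time[1] + window[1]) * fs) + 1L
    sel <- i0:(i0 + n_samp - 1L)
    rec$left[sel] <- ep$left
    rec$right[sel] <- ep$right
  }
  rec
}
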