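#' Construct a raw fTCD recording
#'
#' A raw recording holds simultaneously sampled blood-flow velocity in the
#' left and right middle cerebral arteries (MCAs), a uniform time grid, and a
#' marker table giving the onset of each talk phase together with the
#' behavioural validity flag and word count noted by the examiner.
#'
#' @param child_id character scalar identifying the child.
#' @param sampling_rate sampling rate in Hz.
#' @param time numeric vector of sample times in seconds, strictly increasing
#'   and uniform.
#' @param left,right numeric vectors of velocity (cm/s), same length as
#'   `time`.
#' @param markers data frame with columns `trial`, `onset_s`, `valid`
#'   (logical), `word_count`; one row per administered trial, `onset_s` the
#'   talk-phase onset in seconds.
#' @return An object of class `ftcd_recording`.
#' @export
ftcd_recording <- function(child_id, sampling_rate, time, left, right, markers) {
  stopifnot(is.character(child_id), length(child_id) == 1L)
  if (!is.numeric(sampling_rate) || sampling_rate < 10)
    stop("sampling_rate must be numeric and >= 10 Hz")
  n <- length(time)
  if (length(left) != n || length(right) != n)
    stop("left/right channels must match the time grid length")
  if (n > 1) {
    dt <- diff(time)
    if (any(dt <= 0) || max(dt) - min(dt) > 1e-6)
      stop("time must be strictly increasing and uniform within 1e-6 s")
  }
  if (!all(is.finite(left)) || !all(is.finite(right)))
    stop("velocities must be finite")
  req <- c("trial", "onset_s", "valid", "word_count")
  if (!is.data.frame(markers) || !all(req %in% names(markers)))
    stop("markers must be a data frame with columns ",
         paste(req, collapse = ", "))
  if (nrow(markers) &&
      (min(markers$onset_s) < time[1] || max(markers$onset_s) > time[n]))
    stop("markers must lie within the recording span")
  structure(
    list(child_id = child_id, sampling_rate = sampling_rate,
         time = as.numeric(time), left = as.numeric(left),
         right = as.numeric(right), markers = markers),
    class = "ftcd_recording")
}

#' @export
print.ftcd_recording <- function(x, ...) {
  cat(sprintf("<ftcd_recording> child %s: %.1f s at %g Hz, %d trial markers\n",
              x$child_id, diff(range(x$time)), x$sampling_rate,
              nrow(x$markers)))
  invisible(x)
}

# Local maxima with a greedy minimum-distance constraint: candidates are
# strict local peaks, kept in decreasing height order provided they are at
# least min_dist samples from every already-kept peak.
find_systolic_peaks <- function(x, min_dist) {
  n <- length(x)
  if (n < 3) return(integer(0))
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  if (!length(cand)) return(integer(0))
  cand <- cand[order(x[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (i in cand) {
    if (!length(kept) || all(abs(kept - i) >= min_dist)) kept <- c(kept, i)
  }
  sort(kept)
}

#' Remove cardiac pulsatility by heart-cycle integration
#'
#' Systolic peaks are detected on the sum of the two channels (the cardiac
#' waveform is common to both MCAs), with a minimum inter-peak interval of
#' `60 / max_rate` seconds. Within each cardiac cycle `[p_i, p_{i+1})` every
#' sample of each channel is replaced by that cycle's per-channel mean;
#' samples before the first peak and from the last peak onward take the
#' nearest cycle's mean. The operation is exactly symmetric in the two
#' channels.
#'
#' @param rec an [ftcd_recording()].
#' @param min_rate,max_rate plausible heart-rate bounds in beats per minute;
#'   `max_rate` sets the minimum inter-peak interval.
#' @return The recording with pulsatility integrated out.
#' @export
integrate_heart_cycles <- function(rec, min_rate = 40, max_rate = 200) {
  stopifnot(inherits(rec, "ftcd_recording"))
  span <- diff(range(rec$time))
  if (span < 2 * 60 / min_rate)
    stop("recording too short: need at least 2 cardiac cycles at min_rate")
  min_dist <- max(1L, floor(60 / max_rate * rec$sampling_rate))
  peaks <- find_systolic_peaks(rec$left + rec$right, min_dist)
  if (length(peaks) < 2) stop("no cardiac signal")
  n <- length(rec$time)
  K <- length(peaks)
  # interval 0 = before first peak, k = [p_k, p_{k+1}), K = from last peak on;
  # full cycles are 1..K-1; head/tail samples take the nearest cycle's mean
  # but do not contribute to it. Putative cycles longer than one beat at
  # min_rate cannot be cardiac (e.g. a recording with no pulsatility, where
  # slow activation maxima masquerade as peaks); their samples pass through
  # unchanged.
  iv <- findInterval(seq_len(n), peaks)
  assign_to <- pmin(pmax(iv, 1L), K - 1L)
  max_len <- 60 / min_rate * rec$sampling_rate
  plausible <- diff(peaks) <= max_len
  cyc <- function(x) {
    m <- vapply(seq_len(K - 1L), function(k) mean(x[iv == k]), numeric(1))
    out <- m[assign_to]
    keep <- !plausible[assign_to]
    out[keep] <- x[keep]
    out
  }
  rec$left <- cyc(rec$left)
  rec$right <- cyc(rec$right)
  rec
}
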