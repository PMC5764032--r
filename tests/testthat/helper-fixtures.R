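# Builders for tiny hand-constructed fixtures used across test files.

# An epoch with fully specified channels on the standard [-12, 15) axis.
make_epoch <- function(left, right, fs = 25, window = c(-12, 15),
                       trial = 1L, status = "accepted",
                       reason = NA_character_, word_count = 20) {
  n <- round((window[2] - window[1]) * fs)
  stopifnot(length(left) %in% c(1L, n), length(right) %in% c(1L, n))
  list(trial = trial, rel_time = window[1] + (seq_len(n) - 1) / fs,
       left = rep_len(left, n), right = rep_len(right, n),
       status = status, reason = reason, imputed = 0L,
       word_count = word_count)
}

make_epochs <- function(...) structure(list(...), class = "ftcd_epochs")

# An epoch with a flat baseline at 100 and a left-minus-right difference of
# exactly `d` from 2 s after talk onset onward (covering the period of
# interest and any peak window inside it); survives baseline correction.
make_diff_epoch <- function(d, fs = 25, ...) {
  ep <- make_epoch(100, 100, fs = fs, ...)
  on <- ep$rel_time >= 2
  ep$left[on] <- 100 + d / 2
  ep$right[on] <- 100 - d / 2
  ep
}

# A minimal recording: constant base channels plus an injected sinusoidal
# "cardiac" waveform, markers every 27 s.
make_recording <- function(n_trials = 2, fs = 25, base_left = 60,
                           base_right = 50, cardiac_amp = 8,
                           cardiac_hz = 1.2, valid = TRUE,
                           child_id = "T01") {
  dur <- 27 * n_trials
  t <- (seq_len(dur * fs) - 1) / fs
  card <- cardiac_amp * sin(2 * pi * cardiac_hz * t)
  markers <- data.frame(trial = seq_len(n_trials),
                        onset_s = 12 + 27 * (seq_len(n_trials) - 1),
                        valid = rep_len(valid, n_trials),
                        word_count = 20)
  ftcd_recording(child_id, fs, t, base_left + card, base_right + card,
                 markers)
}

# Swap the two channels of a recording (used for antisymmetry checks).
swap_channels <- function(rec) {
  tmp <- rec$left; rec$left <- rec$right; rec$right <- tmp
  rec
}

# Low-noise simulation config for ground-truth recovery checks.
recovery_config <- function(...) {
  simulation_config(artefact_rate = 0, dropout_rate = 0,
                    invalid_trial_rate = 0, trial_li_sd = 0.3,
                    sample_noise_sd = 0.5, ...)
}
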