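test_that("epoching produces sample-exact half-open windows", {
  # marker at t = 20 s at 25 Hz: epoch spans absolute [8, 35), 675 samples
  fs <- 25
  t <- (seq_len(40 * fs) - 1) / fs
  rec <- ftcd_recording("A", fs, t, rep(60, length(t)), rep(50, length(t)),
                        data.frame(trial = 1, onset_s = 20, valid = TRUE,
                                   word_count = 15))
  eps <- epoch_trials(rec)
  expect_length(eps, 1)
  expect_length(eps[[1]]$left, (15 + 12) * fs)
  expect_equal(eps[[1]]$rel_time[1], -12)
  expect_equal(max(eps[[1]]$rel_time), 15 - 1 / fs)
  expect_equal(eps[[1]]$status, "accepted")
})

test_that("epochs without full pre-marker data are dropped with a warning", {
  fs <- 25
  t <- (seq_len(40 * fs) - 1) / fs
  rec <- ftcd_recording("A", fs, t, rep(60, length(t)), rep(50, length(t)),
                        data.frame(trial = 1:2, onset_s = c(5, 20),
                                   valid = TRUE, word_count = 15))
  expect_warning(eps <- epoch_trials(rec), "outside recording")
  expect_length(eps, 1)
  expect_equal(eps[[1]]$trial, 2)
})

test_that("behaviourally invalid trials are rejected and markers required", {
  rec <- make_recording(n_trials = 2, valid = c(TRUE, FALSE))
  eps <- epoch_trials(rec)
  expect_equal(eps[[2]]$status, "rejected")
  expect_equal(eps[[2]]$reason, "behaviour")
  rec$markers <- rec$markers[0, ]
  expect_error(epoch_trials(rec), "no trials")
})

test_that("single dropouts are imputed with the trial mean of clean samples", {
  base <- rep(100, 675)
  base[300] <- 0
  eps <- make_epochs(make_epoch(base, rep(98, 675)))
  out <- impute_dropouts(eps)
  clean_mean <- mean(base[-300])
  expect_equal(out[[1]]$left[300], clean_mean)
  expect_equal(out[[1]]$imputed, 1L)
  # untouched epochs report zero imputations
  out2 <- impute_dropouts(make_epochs(make_epoch(100, 98)))
  expect_equal(out2[[1]]$imputed, 0L)
  expect_equal(out2[[1]]$left, rep(100, 675))
})

test_that("dropout runs longer than max_run are left for artefact rejection", {
  base <- rep(100, 675) + sin(1:675)  # non-degenerate MAD
  base[300:302] <- 0
  eps <- make_epochs(make_epoch(base, rep(98, 675)))
  out <- impute_dropouts(eps, max_run = 1)
  expect_equal(out[[1]]$left[300:302], c(0, 0, 0))
  expect_equal(out[[1]]$imputed, 0L)
  # downstream: the zeros put the trial out of range after normalisation
  norm <- normalise(out)
  rej <- reject_artefact_trials(norm)
  expect_equal(rej[[1]]$status, "rejected")
  expect_equal(rej[[1]]$reason, "range")
})

test_that("an all-candidate trial is rejected as flat/dropout", {
  eps <- make_epochs(make_epoch(0, 98))
  out <- impute_dropouts(eps)
  expect_equal(out[[1]]$status, "rejected")
  expect_equal(out[[1]]$reason, "flat/dropout")
})

test_that("normalisation fixes each channel mean at 100 and is scale invariant", {
  rec <- make_recording(n_trials = 1, base_left = 57.3, base_right = 44,
                        cardiac_amp = 3)
  out <- normalise(rec)
  expect_equal(mean(out$left), 100, tolerance = 1e-9)
  expect_equal(mean(out$right), 100, tolerance = 1e-9)
  # pre-multiplying both channels leaves the normalized signal unchanged
  rec2 <- rec
  rec2$left <- rec2$left * 2
  rec2$right <- rec2$right * 2
  out2 <- normalise(rec2)
  expect_equal(out2$left, out$left, tolerance = 1e-12)
  expect_equal(out2$right, out$right, tolerance = 1e-12)
  # shape preserved up to scale
  expect_equal(out$left, rec$left * (100 / mean(rec$left)), tolerance = 1e-12)
  rec$left <- rec$left - 100  # negative mean
  expect_error(normalise(rec), "non-positive")
})

test_that("range rejection respects bounds and status precedence", {
  good <- make_epoch(100, 100)
  bad <- make_epoch(100, 100, trial = 2L)
  bad$left[5] <- 145
  behav <- make_epoch(100, 100, trial = 3L, status = "rejected",
                      reason = "behaviour")
  out <- reject_artefact_trials(make_epochs(good, bad, behav))
  expect_equal(out[[1]]$status, "accepted")
  expect_equal(out[[2]]$reason, "range")
  expect_equal(out[[3]]$reason, "behaviour")
})

test_that("baseline correction zeroes the baseline mean and is idempotent", {
  ep <- make_epoch(100, 100)
  poi <- ep$rel_time >= 0
  ep$left[poi] <- 102   # baseline 100, talk-phase 102
  eps <- baseline_correct(make_epochs(ep))
  bl <- eps[[1]]$rel_time < 0
  expect_equal(mean(eps[[1]]$left[bl]), 0, tolerance = 1e-9)
  expect_equal(mean(eps[[1]]$right[bl]), 0, tolerance = 1e-9)
  expect_equal(unique(eps[[1]]$left[poi]), 2)
  again <- baseline_correct(eps)
  expect_equal(again[[1]]$left, eps[[1]]$left, tolerance = 1e-12)
  # constant epoch collapses to zeros
  z <- baseline_correct(make_epochs(make_epoch(100, 100)))
  expect_true(all(z[[1]]$left == 0) && all(z[[1]]$right == 0))
})
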