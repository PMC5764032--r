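test_that("constant difference gives the earliest-tie peak and LI equal to it", {
  eps <- baseline_correct(make_epochs(make_diff_epoch(3), make_diff_epoch(3)))
  ga <- grand_average(eps)
  out <- compute_li(ga)
  expect_equal(out$peak_time, 4)       # earliest sample on ties
  expect_equal(out$li, 3)              # mean of a constant window
  expect_equal(out$window, c(3, 5))
})

test_that("a negative excursion is found by the absolute-difference rule", {
  ep <- make_diff_epoch(0)
  sel <- abs(ep$rel_time - 8) < 1e-9
  ep$left[sel] <- ep$left[sel] - 5    # diff = -5 at exactly t = 8
  eps <- baseline_correct(make_epochs(ep))
  out <- compute_li(grand_average(eps))
  expect_equal(out$peak_time, 8)
  expect_lt(out$li, 0)
})

test_that("grand averaging is pointwise and antisymmetric", {
  eps <- make_epochs(make_diff_epoch(2), make_diff_epoch(4))
  ga <- grand_average(eps)
  expect_equal(unique(round(ga$diff[ga$rel_time >= 2], 12)), 3)
  one <- grand_average(make_epochs(make_diff_epoch(2)))
  expect_equal(one$left, make_diff_epoch(2)$left)
  swapped <- make_epochs(
    make_epoch(make_diff_epoch(2)$right, make_diff_epoch(2)$left),
    make_epoch(make_diff_epoch(4)$right, make_diff_epoch(4)$left))
  expect_equal(grand_average(swapped)$diff, -ga$diff)
  expect_error(grand_average(make_epochs(
    make_epoch(100, 100, status = "rejected", reason = "range"))),
    "zero accepted")
})

test_that("trial-wise SE and CI match the frozen hand computation", {
  # trial LIs {1, 2, 3}: SD = 1, SE = 1/sqrt(3) = 0.5774, CI = 2 +/- 1.96 SE
  eps <- baseline_correct(make_epochs(make_diff_epoch(1), make_diff_epoch(2),
                                      make_diff_epoch(3)))
  out <- li_se_ci(eps, window = c(3, 5), li = 2)
  expect_equal(out$trial_lis, c(1, 2, 3))
  expect_equal(out$se, 0.5774, tolerance = 1e-4)
  expect_equal(out$ci95, c(0.868, 3.132), tolerance = 1e-3)
  # all equal trial LIs collapse the CI to a point
  same <- li_se_ci(baseline_correct(make_epochs(make_diff_epoch(2),
                                                make_diff_epoch(2))),
                   window = c(3, 5), li = 2)
  expect_equal(same$se, 0)
  expect_equal(same$ci95, c(2, 2))
})

test_that("doubling the difference doubles LI, SE and CI half-width", {
  eps1 <- baseline_correct(make_epochs(make_diff_epoch(1), make_diff_epoch(2),
                                       make_diff_epoch(3)))
  eps2 <- baseline_correct(make_epochs(make_diff_epoch(2), make_diff_epoch(4),
                                       make_diff_epoch(6)))
  li1 <- compute_li(grand_average(eps1))
  li2 <- compute_li(grand_average(eps2))
  expect_equal(li2$li, 2 * li1$li)
  s1 <- li_se_ci(eps1, li1$window, li1$li)
  s2 <- li_se_ci(eps2, li2$window, li2$li)
  expect_equal(s2$se, 2 * s1$se)
  expect_equal(diff(s2$ci95), 2 * diff(s1$ci95))
})

test_that("CI categorisation treats a zero endpoint as crossing", {
  expect_equal(categorise_laterality(2, c(1, 3)), "left")
  expect_equal(categorise_laterality(1.5, c(-0.5, 3.5)), "bilateral")
  expect_equal(categorise_laterality(1, c(0, 2)), "bilateral")
  expect_equal(categorise_laterality(-1, c(-2, 0)), "bilateral")
  expect_equal(categorise_laterality(-2, c(-3, -1)), "right")
})

test_that("usability enforces the 12-trial minimum and the LI cap", {
  expect_false(usability(11, 3)$usable)
  expect_equal(usability(11, 3)$reason, "too few trials")
  expect_false(usability(20, 10.5)$usable)
  expect_equal(usability(20, 10.5)$reason, "extreme LI")
  expect_true(usability(12, 3)$usable)
  expect_true(usability(12, -10)$usable)   # boundary inclusive
  expect_true(usability(12, 10)$usable)
})

test_that("identical trials give identical split-half LIs", {
  eps <- baseline_correct(make_epochs(make_diff_epoch(3), make_diff_epoch(3),
                                      make_diff_epoch(3), make_diff_epoch(3)))
  sh <- split_half(eps)
  expect_equal(sh$li_odd, sh$li_even)
  expect_equal(sh$li_odd, 3)
  one <- split_half(baseline_correct(make_epochs(make_diff_epoch(3))))
  expect_true(is.na(one$li_even))
})

test_that("percent change recovers injected POI offsets per channel", {
  ep <- make_epoch(100, 100)
  poi <- ep$rel_time >= 4 & ep$rel_time <= 14
  ep$left[poi] <- 100 + 2
  ep$right[poi] <- 100 - 1
  eps <- baseline_correct(make_epochs(ep))
  pc <- percent_change(eps)
  expect_equal(pc$pct_left, 2, tolerance = 1e-9)
  expect_equal(pc$pct_right, -1, tolerance = 1e-9)
  zero <- percent_change(baseline_correct(make_epochs(make_epoch(100, 100))))
  expect_equal(zero$pct_left, 0)
  expect_equal(zero$pct_right, 0)
})

test_that("adding a duplicate accepted epoch keeps LI and shrinks SE", {
  eps <- baseline_correct(make_epochs(make_diff_epoch(1), make_diff_epoch(2),
                                      make_diff_epoch(3)))
  li <- compute_li(grand_average(eps))
  se <- li_se_ci(eps, li$window, li$li)$se
  dup <- baseline_correct(make_epochs(make_diff_epoch(1), make_diff_epoch(2),
                                      make_diff_epoch(3), make_diff_epoch(2)))
  li2 <- compute_li(grand_average(dup))
  se2 <- li_se_ci(dup, li2$window, li2$li)$se
  expect_equal(li2$li, li$li)
  expect_lt(se2, se)
})

test_that("the full pipeline is antisymmetric under a channel swap", {
  cfg <- recovery_config(n_pairs = 1, n_trials = 16, seed = 5,
                         lateral_effect_mean = 2.5, lateral_effect_sd = 0.5)
  sim <- generate_cohort(cfg)
  rec <- sim$recordings[[1]]
  a <- process_recording(rec)
  b <- process_recording(swap_channels(rec))
  expect_equal(b$li, -a$li, tolerance = 1e-9)
  expect_equal(b$trial_lis, -a$trial_lis, tolerance = 1e-9)
  expect_equal(b$peak_time, a$peak_time)
  expect_equal(sort(b$ci95), sort(-a$ci95), tolerance = 1e-9)
  map <- c(left = "right", right = "left", bilateral = "bilateral")
  expect_equal(b$category, unname(map[a$category]))
  expect_equal(b$pct_left, a$pct_right, tolerance = 1e-9)
})

test_that("the normalized-domain pipeline is invariant to raw channel scale", {
  cfg <- recovery_config(n_pairs = 1, n_trials = 14, seed = 9)
  sim <- generate_cohort(cfg)
  rec <- sim$recordings[[1]]
  scaled <- rec
  scaled$left <- scaled$left * 3.7
  scaled$right <- scaled$right * 3.7
  a <- process_recording(rec)
  b <- process_recording(scaled)
  expect_equal(b$li, a$li, tolerance = 1e-9)
  expect_equal(b$se, a$se, tolerance = 1e-9)
  expect_equal(b$pct_left, a$pct_left, tolerance = 1e-9)
  expect_equal(b$n_valid, a$n_valid)
})
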