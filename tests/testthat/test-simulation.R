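test_that("configuration errors name the offending field", {
  expect_error(simulation_config(prop_dld_target = 1.2), "prop_dld_target")
  expect_error(simulation_config(zygosity_mix = c(0.5, 0.4, 0.2)),
               "zygosity_mix")
  expect_error(simulation_config(sampling_rate = 5), "sampling_rate")
  expect_error(simulation_config(n_trials = 0), "n_trials")
  expect_error(simulation_config(n_pairs = 0), "n_pairs")
  expect_error(simulation_config(artefact_rate = -0.1), "artefact_rate")
})

test_that("cohort bookkeeping: one recording per child, pairs intact", {
  cfg <- simulation_config(n_pairs = 10, n_trials = 4, seed = 2)
  sim <- generate_cohort(cfg)
  expect_length(sim$recordings, 20)
  expect_equal(nrow(sim$cohort), 20)
  expect_equal(nrow(sim$truth), 20)
  expect_true(all(table(sim$cohort$pair_id) == 2))
  # pair members share pair id and zygosity; MZ pairs share sex
  for (p in unique(sim$truth$pair_id)) {
    tw <- sim$truth[sim$truth$pair_id == p, ]
    expect_equal(tw$zygosity[1], tw$zygosity[2])
    expect_equal(tw$age[1], tw$age[2])
    if (tw$zygosity[1] == "MZ") expect_equal(tw$sex[1], tw$sex[2])
    if (tw$zygosity[1] == "DZos") expect_true(tw$sex[1] != tw$sex[2])
  }
  # trial markers spaced 27 s apart (12 view + 10 talk + 5 gap)
  on <- sim$recordings[[1]]$markers$onset_s
  expect_true(all(diff(on) == 27))
  expect_equal(nrow(sim$trials), 20 * 4)
})

test_that("identical config and seed reproduce the cohort exactly", {
  cfg <- simulation_config(n_pairs = 3, n_trials = 5, seed = 99)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$truth, b$truth)
  expect_identical(a$recordings, b$recordings)
  expect_identical(a$artefact_log, b$artefact_log)
})

test_that("noise-free construction recovers the injected effect exactly", {
  cfg <- simulation_config(n_pairs = 2, n_trials = 16, seed = 7,
                           artefact_rate = 0, dropout_rate = 0,
                           invalid_trial_rate = 0, trial_li_sd = 0,
                           sample_noise_sd = 0, pulsatility_amplitude = 0,
                           lateral_effect_mean = 3, lateral_effect_sd = 0,
                           prop_right_dominant = 0, prop_bilateral = 0)
  sim <- generate_cohort(cfg)
  for (rec in sim$recordings) {
    r <- process_recording(rec)
    expect_equal(r$li, 3, tolerance = 0.05)
    expect_equal(r$category, "left")
  }
})

test_that("pipeline LI tracks injected effects across the dynamic range", {
  # low-noise cohort, effects spread over [-6, 6] via a wide distribution
  cfg <- recovery_config(n_pairs = 8, n_trials = 20, seed = 13,
                         lateral_effect_mean = 0, lateral_effect_sd = 3.5,
                         prop_right_dominant = 0, prop_bilateral = 0)
  sim <- generate_cohort(cfg)
  keep <- abs(sim$truth$true_li) <= 6
  err <- vapply(which(keep), function(i)
    process_recording(sim$recordings[[i]])$li - sim$truth$true_li[i],
    numeric(1))
  expect_true(all(abs(err) < 0.2))
})

test_that("realized dominance-class fractions match their targets", {
  cfg <- simulation_config(n_pairs = 250, n_trials = 1, seed = 21,
                           prop_right_dominant = 0.15, prop_bilateral = 0.18)
  sim <- generate_cohort(cfg)
  frac_right <- mean(sim$truth$true_class == "right")
  se <- sqrt(0.15 * 0.85 / 500)
  expect_lt(abs(frac_right - 0.15), 3 * se)
  frac_bi <- mean(sim$truth$true_class == "bilateral")
  expect_lt(abs(frac_bi - 0.18), 3 * sqrt(0.18 * 0.82 / 500))
})

test_that("pair ICC of true lateral effects matches the configured value", {
  cfg <- simulation_config(n_pairs = 400, n_trials = 1, seed = 5,
                           pair_icc_li = 0.4, prop_right_dominant = 0,
                           prop_bilateral = 0, group_li_shift = 0,
                           prop_dld_target = 0)
  sim <- generate_cohort(cfg)
  wide <- matrix(sim$truth$true_li, ncol = 2, byrow = TRUE)
  r <- cor(wide[, 1], wide[, 2])
  expect_lt(abs(r - 0.4), 3 / sqrt(400))
})

test_that("DLD prevalence follows the Monte-Carlo norm-model expectation", {
  # with zero latent shift the classifier rate equals the base rate of the
  # >=2-of-13 rule under the correlated norm model
  set.seed(1)
  base <- expected_dld_rate(0, rho = 0.5, n_sim = 40000)
  cfg <- simulation_config(n_pairs = 400, n_trials = 1, seed = 17,
                           language_score_params = list(
                             rho = 0.5, dld_latent_shift = 0,
                             iq_group_shift = 0),
                           prop_dld_target = 0)
  sim <- generate_cohort(cfg)
  realized <- mean(sim$cohort$group == "DLD")
  se <- sqrt(base * (1 - base) / 800)
  expect_lt(abs(realized - base), 4 * se + 0.02)
  # and the calibrated generator hits a nonzero target
  cfg2 <- simulation_config(n_pairs = 400, n_trials = 1, seed = 18,
                            prop_dld_target = 0.4)
  sim2 <- generate_cohort(cfg2)
  expect_lt(abs(mean(sim2$cohort$group == "DLD") - 0.4), 0.06)
})

test_that("children with all scores at norm means are clean TD cases", {
  norms <- battery_norms()
  lang <- norms[norms$language, ]
  res <- classify_dld(stats::setNames(lang$norm_mean, lang$measure))
  expect_equal(res$group, "TD")
  expect_equal(res$n_flags, 0)
})

test_that("handedness generation saturates, balances and fills positions", {
  truth <- data.frame(child_id = c("A", "B"), hand_latent = c(50, -50))
  hp <- simulation_config()$handedness_latent_params
  h <- generate_handedness(truth, hp, seed = 3)
  # latent +inf: all items right, all reaches right; -inf: all left
  expect_true(all(h$ehi_items[1, -1] %in% c("right", "both")))
  a_reaches <- h$qhp_reaches[h$qhp_reaches$child_id == "A", ]
  expect_true(all(a_reaches$hand == "right"))
  b_reaches <- h$qhp_reaches[h$qhp_reaches$child_id == "B", ]
  expect_true(all(b_reaches$hand == "left"))
  # exactly 3 reaches per position per child
  expect_true(all(table(a_reaches$position) == 3))
  # symmetric latent 0: expected QHP score 10.5 by link symmetry
  truth0 <- data.frame(child_id = sprintf("C%03d", 1:400), hand_latent = 0)
  h0 <- generate_handedness(truth0, hp, seed = 4)
  scores <- tapply(h0$qhp_reaches$hand == "right", h0$qhp_reaches$child_id,
                   sum)
  expect_lt(abs(mean(scores) - 10.5), 3 * sd(scores) / sqrt(400))
})

test_that("QHP position profile rises from left to right hemispace", {
  cfg <- simulation_config(n_pairs = 120, n_trials = 1, seed = 8)
  sim <- generate_cohort(cfg)
  prof <- colMeans(sim$cohort[paste0("qhp_pos", 1:7)])
  expect_true(all(diff(prof) > -0.02))  # monotone up to sampling noise
  expect_gt(prof[7], prof[1])
})

test_that("artefact injection is logged and drives downstream handling", {
  cfg <- recovery_config(n_pairs = 1, n_trials = 12, seed = 3)
  sim <- generate_cohort(cfg)
  rec <- sim$recordings[[1]]
  # rates of zero leave the recording untouched
  clean <- inject_artefacts(rec, 0, 0, seed = 1)
  expect_identical(clean$recording, rec)
  expect_equal(nrow(clean$log), 0)
  expect_error(inject_artefacts(rec, 1.4, 0), "rates")
  # a forced dropout in every trial: imputation counts match the log
  drop <- inject_artefacts(rec, 0, 1, seed = 2)
  expect_equal(nrow(drop$log), 12)
  expect_true(all(drop$log$kind == "dropout"))
  res <- process_recording(drop$recording)
  expect_equal(res$n_imputed, 12)
  expect_equal(res$n_valid, 12)  # all trials repaired, none lost
  # a forced spike in every trial: the range rule rejects them all
  spike <- inject_artefacts(rec, 1, 0, seed = 2)
  res2 <- process_recording(spike$recording)
  expect_equal(sum(res2$reject_reasons["range"]), 12)
  expect_false(res2$usable)
})
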