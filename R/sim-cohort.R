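# Trial timing (seconds): 12 s silent viewing of the animation, cue, 10 s
# talk phase, 5 s inter-trial gap. Markers sit at talk onset, so consecutive
# onsets are 27 s apart and the [-12, +15) epoch of one trial abuts the next.
TRIAL_VIEW_S <- 12
TRIAL_TALK_S <- 10
TRIAL_GAP_S <- 5
TRIAL_PERIOD_S <- TRIAL_VIEW_S + TRIAL_TALK_S + TRIAL_GAP_S

# Smooth activation time courses on the within-trial relative axis
# (0 = talk onset). The lateralised response ramps up over [2, 3) s and
# holds a flat plateau across [3, 15) s, so that any 2 s window inside the
# period of interest averages to exactly the injected effect. The early
# bilateral peak is gamma-shaped, maximal ~2 s after onset.
plateau_shape <- function(rel) {
  s <- numeric(length(rel))
  ramp <- rel >= 2 & rel < 3
  s[ramp] <- 0.5 * (1 - cos(pi * (rel[ramp] - 2)))
  s[rel >= 3 & rel < 15] <- 1
  s
}

bump_shape <- function(rel) {
  s <- numeric(length(rel))
  on <- rel > 0 & rel < 15
  s[on] <- (rel[on] / 2) * exp(1 - rel[on] / 2)
  s
}

# Synthesize one child's two-channel recording from the current RNG stream.
# true_li is the subject-level lateral effect in percent units; each trial's
# realized effect wobbles around it with SD trial_li_sd.
synth_recording <- function(child_id, true_li, cfg, valid, word_count) {
  fs <- cfg$sampling_rate
  nt <- cfg$n_trials
  n <- round(TRIAL_PERIOD_S * nt * fs)
  t <- (seq_len(n) - 1) / fs
  trial_ix <- pmin(floor(t / TRIAL_PERIOD_S) + 1, nt)
  rel <- t - (trial_ix - 1) * TRIAL_PERIOD_S - TRIAL_VIEW_S

  d_trial <- true_li + stats::rnorm(nt, 0, cfg$trial_li_sd)
  act_trial <- cfg$activation_peak_pct * stats::runif(nt, 0.8, 1.2)
  d <- d_trial[trial_ix] * plateau_shape(rel)
  act <- act_trial[trial_ix] * bump_shape(rel)

  hr <- max(stats::rnorm(1, cfg$heart_rate_mean, cfg$heart_rate_sd), 50)
  phase <- stats::runif(1, 0, 2 * pi)
  cyc <- 2 * pi * (hr / 60) * t + phase
  cardiac <- cfg$pulsatility_amplitude * (0.8 * sin(cyc) + 0.2 * sin(2 * cyc))

  bl <- cfg$base_velocity_left
  br <- cfg$base_velocity_right
  left <- bl * (1 + (act + d / 2) / 100 +
                  stats::rnorm(n, 0, cfg$sample_noise_sd) / 100) + cardiac
  right <- br * (1 + (act - d / 2) / 100 +
                   stats::rnorm(n, 0, cfg$sample_noise_sd) / 100) + cardiac

  markers <- data.frame(trial = seq_len(nt),
                        onset_s = TRIAL_VIEW_S + (seq_len(nt) - 1) * TRIAL_PERIOD_S,
                        valid = valid, word_count = word_count)
  ftcd_recording(child_id, fs, t, left, right, markers)
}

#' Inject spike artefacts and brief dropouts into a recording
#'
#' Each trial independently receives, with probability `artefact_rate`, a
#' short spike (a large transient excursion on one channel during the talk
#' phase, the kind rejected downstream by the normalized-range rule) and,
#' with probability `dropout_rate`, a single-sample near-zero dropout (the
#' kind repaired by dropout imputation). Every insertion is logged.
#'
#' @param rec an [ftcd_recording()].
#' @param artefact_rate,dropout_rate per-trial probabilities in `[0, 1]`.
#' @param seed optional integer seed; `NULL` continues the current RNG
#'   stream.
#' @return List with `recording` (modified) and `log` (data frame with
#'   columns `trial`, `channel`, `sample`, `kind`).
#' @export
inject_artefacts <- function(rec, artefact_rate = 0, dropout_rate = 0,
                             seed = NULL) {
  if (artefact_rate < 0 || artefact_rate > 1 ||
      dropout_rate < 0 || dropout_rate > 1)
    stop("configuration error: rates must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  fs <- rec$sampling_rate
  log <- data.frame(trial = integer(), channel = character(),
                    sample = integer(), kind = character())
  for (k in seq_len(nrow(rec$markers))) {
    onset <- rec$markers$onset_s[k]
    talk <- which(rec$time >= onset & rec$time < onset + TRIAL_TALK_S)
    if (!length(talk)) next
    if (stats::runif(1) < artefact_rate) {
      ch <- sample(c("left", "right"), 1)
      i <- sample(talk, 1)
      # probe-movement excursion lasting ~0.6 s: large enough to survive
      # heart-cycle averaging and trip the normalized-range rule even when
      # the run straddles a cycle boundary
      run <- i:min(i + round(0.6 * fs), length(rec$time))
      rec[[ch]][run] <- rec[[ch]][run] * 2.2
      log <- rbind(log, data.frame(trial = rec$markers$trial[k], channel = ch,
                                   sample = i, kind = "spike"))
    }
    if (stats::runif(1) < dropout_rate) {
      ch <- sample(c("left", "right"), 1)
      i <- sample(talk, 1)
      rec[[ch]][i] <- 0
      log <- rbind(log, data.frame(trial = rec$markers$trial[k], channel = ch,
                                   sample = i, kind = "dropout"))
    }
  }
  list(recording = rec, log = log)
}

#' Generate a complete synthetic twin cohort with known ground truth
#'
#' Produces one two-channel fTCD recording per child (cardiac pulsatility,
#' an early bilateral activation peak, a sustained left-minus-right plateau
#' during speech equal to the child's true lateral effect, measurement
#' noise, optional spikes/dropouts and behaviourally invalid trials),
#' together with handedness behaviour, normed language scores, the realized
#' DLD/TD classification, and the generating ground truth. Identical config
#' (including seed) yields identical output.
#'
#' @param config a [simulation_config()].
#' @return List with elements `recordings` (list of [ftcd_recording()]),
#'   `cohort` (one row per child: ids, zygosity, sex, age, group,
#'   handedness scores, language scores), `truth` (generating values per
#'   child), `trials` (per-trial validity and word count) and
#'   `artefact_log`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed)
  np <- cfg$n_pairs
  n <- 2L * np

  zyg <- sample(c("MZ", "DZss", "DZos"), np, replace = TRUE,
                prob = cfg$zygosity_mix)
  pair_sex1 <- sample(c("M", "F"), np, replace = TRUE)
  sex2 <- ifelse(zyg == "DZos", ifelse(pair_sex1 == "M", "F", "M"),
                 ifelse(zyg == "DZss", pair_sex1, pair_sex1))
  age <- round(stats::runif(np, 6, 11.9), 1)

  corr_pairs <- function(mu, sd, r) {
    a <- stats::rnorm(np); b <- stats::rnorm(np)
    shared <- stats::rnorm(np)
    t1 <- sqrt(r) * shared + sqrt(1 - r) * a
    t2 <- sqrt(r) * shared + sqrt(1 - r) * b
    cbind(mu + sd * t1, mu + sd * t2)
  }
  li_raw <- corr_pairs(cfg$lateral_effect_mean, cfg$lateral_effect_sd,
                       cfg$pair_icc_li)
  hp <- cfg$handedness_latent_params
  hand <- corr_pairs(hp$mean, hp$sd, hp$pair_cor)

  p_other <- c(cfg$prop_right_dominant, cfg$prop_bilateral)
  dom <- matrix(sample(c("right", "bilateral", "left"), n, replace = TRUE,
                       prob = c(p_other, 1 - sum(p_other))), ncol = 2)
  li_true <- li_raw
  li_true[dom == "right"] <- -abs(li_raw[dom == "right"])
  li_true[dom == "bilateral"] <- 0.15 * li_raw[dom == "bilateral"]

  lp <- cfg$language_score_params
  b0 <- expected_dld_rate(0, lp$rho, n_sim = 4000)
  b1 <- expected_dld_rate(lp$dld_latent_shift, lp$rho, n_sim = 4000)
  p_dest <- if (b1 > b0) min(max((cfg$prop_dld_target - b0) / (b1 - b0), 0), 1)
            else cfg$prop_dld_target
  destined <- stats::rbinom(n, 1, p_dest) == 1
  li_true <- t(li_true)
  li_true[destined] <- li_true[destined] + cfg$group_li_shift

  truth <- data.frame(
    child_id = sprintf("P%03d_%d", rep(seq_len(np), each = 2), rep(1:2, np)),
    pair_id = sprintf("P%03d", rep(seq_len(np), each = 2)),
    twin_label = rep(1:2, np),
    zygosity = rep(zyg, each = 2),
    sex = as.vector(rbind(pair_sex1, sex2)),
    age = rep(age, each = 2),
    true_li = as.vector(li_true),
    true_class = as.vector(t(dom)),
    destined_dld = destined,
    hand_latent = as.vector(t(hand)))

  scores <- generate_language_scores(truth, lp, seed = cfg$seed + 1L)
  cls <- lapply(seq_len(n), function(i)
    classify_dld(scores[i, , drop = FALSE], lp$norms))
  group <- vapply(cls, `[[`, character(1), "group")
  n_flags <- vapply(cls, `[[`, integer(1), "n_flags")

  handed <- generate_handedness(truth, hp, seed = cfg$seed + 2L)
  ehi <- lapply(seq_len(n), function(i)
    score_ehi(unlist(handed$ehi_items[i, -1])))
  qhp <- lapply(split(handed$qhp_reaches, handed$qhp_reaches$child_id),
                function(d) score_qhp(d))[truth$child_id]

  set.seed(cfg$seed + 3L)
  recordings <- vector("list", n)
  trials <- vector("list", n)
  alog <- vector("list", n)
  for (i in seq_len(n)) {
    valid <- stats::runif(cfg$n_trials) >= cfg$invalid_trial_rate
    words <- stats::rpois(cfg$n_trials, cfg$words_mean)
    rec <- synth_recording(truth$child_id[i], truth$true_li[i], cfg,
                           valid, words)
    inj <- inject_artefacts(rec, cfg$artefact_rate, cfg$dropout_rate)
    recordings[[i]] <- inj$recording
    if (nrow(inj$log)) {
      inj$log$child_id <- truth$child_id[i]
      alog[[i]] <- inj$log
    }
    trials[[i]] <- data.frame(child_id = truth$child_id[i],
                              trial = seq_len(cfg$n_trials),
                              valid = valid, word_count = words)
  }

  cohort <- data.frame(
    truth[c("child_id", "pair_id", "twin_label", "zygosity", "sex", "age")],
    group = group, n_flags = n_flags,
    ehi_score = vapply(ehi, `[[`, numeric(1), "score"),
    ehi_li = vapply(ehi, `[[`, numeric(1), "li"),
    ehi_right = vapply(ehi, `[[`, logical(1), "right"),
    qhp_score = vapply(qhp, `[[`, numeric(1), "score"),
    qhp_right = vapply(qhp, `[[`, logical(1), "right"))
  profs <- do.call(rbind, lapply(qhp, `[[`, "position_profile"))
  colnames(profs) <- paste0("qhp_pos", 1:7)
  cohort <- cbind(cohort, profs, scores)
  rownames(cohort) <- NULL

  list(recordings = recordings, cohort = cohort, truth = truth,
       trials = do.call(rbind, trials),
       artefact_log = if (length(Filter(Negate(is.null), alog)))
         do.call(rbind, Filter(Negate(is.null), alog))
       else data.frame())
}
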