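#' Simulation configuration for synthetic fTCD cohorts
#'
#' Bundles every knob of the cohort generator. Defaults emulate the study
#' population the pipeline is designed for: twin children performing an
#' animation-description task, a majority-left-lateralised population with a
#' minority right-dominant and bilateral, handedness strongly right-shifted,
#' and a group LI difference of zero (the null).
#'
#' @param n_pairs number of twin pairs.
#' @param prop_dld_target target DLD prevalence across children; the
#'   language-score generator is calibrated so the >=2-of-13 flag rule
#'   reproduces it in expectation.
#' @param zygosity_mix fractions of MZ, DZ same-sex, DZ opposite-sex pairs
#'   (must sum to 1).
#' @param sampling_rate recording sampling rate in Hz.
#' @param n_trials trials administered per child (maximum 30 in the task).
#' @param heart_rate_mean,heart_rate_sd child heart rate, beats/min.
#' @param base_velocity_left,base_velocity_right resting MCA velocities,
#'   cm/s.
#' @param pulsatility_amplitude cardiac waveform amplitude, cm/s.
#' @param activation_peak_pct height of the early bilateral activation peak,
#'   percent of baseline flow.
#' @param lateral_effect_mean,lateral_effect_sd population distribution of
#'   the subject-level true lateral effect, percent units.
#' @param prop_right_dominant,prop_bilateral fractions of children whose
#'   effect is folded negative (right-dominant) or shrunk toward zero
#'   (bilateral).
#' @param group_li_shift additive LI shift for DLD-destined children,
#'   percent units; 0 is the null.
#' @param pair_icc_li intraclass correlation of true lateral effects within
#'   twin pairs.
#' @param artefact_rate,dropout_rate,invalid_trial_rate per-trial
#'   probabilities of a spike artefact, a brief dropout, and a behavioural
#'   infringement.
#' @param trial_li_sd trial-to-trial SD of the lateral effect around the
#'   subject's true value, percent units.
#' @param sample_noise_sd white measurement noise, percent of baseline flow.
#' @param words_mean mean words spoken per trial (Poisson).
#' @param handedness_latent_params list: `mean`, `sd`, `pair_cor` of the
#'   handedness latent; `item_slope` and `both_rate` for EHI items;
#'   `qhp_latent_slope` and `qhp_pos_slope` for the reach model.
#' @param language_score_params list: `rho` (inter-measure correlation),
#'   `dld_latent_shift` (latent SD units subtracted for DLD-destined
#'   children), `iq_group_shift` (SD units of performance-IQ disadvantage),
#'   `norms` (see [battery_norms()]).
#' @param seed integer RNG seed; identical config + seed gives identical
#'   cohorts.
#' @return Validated list of class `sim_config`.
#' @export
simulation_config <- function(n_pairs = 25,
                              prop_dld_target = 0.4,
                              zygosity_mix = c(mz = 1/3, dzss = 1/3, dzos = 1/3),
                              sampling_rate = 25,
                              n_trials = 30,
                              heart_rate_mean = 95, heart_rate_sd = 8,
                              base_velocity_left = 60,
                              base_velocity_right = 55,
                              pulsatility_amplitude = 12,
                              activation_peak_pct = 4,
                              lateral_effect_mean = 1.8,
                              lateral_effect_sd = 3,
                              prop_right_dominant = 0.15,
                              prop_bilateral = 0.18,
                              group_li_shift = 0,
                              pair_icc_li = 0.3,
                              artefact_rate = 0.04,
                              dropout_rate = 0.04,
                              invalid_trial_rate = 0.08,
                              trial_li_sd = 3,
                              sample_noise_sd = 1,
                              words_mean = 20,
                              handedness_latent_params = list(
                                mean = 1.8, sd = 1.5, pair_cor = 0.4,
                                item_slope = 1.2, both_rate = 0.08,
                                qhp_latent_slope = 0.9, qhp_pos_slope = 0.55),
                              language_score_params = list(
                                rho = 0.5, dld_latent_shift = 0.75,
                                iq_group_shift = 0.6),
                              seed = 1L) {
  cfg <- as.list(environment())
  frac <- c("prop_dld_target", "prop_right_dominant", "prop_bilateral",
            "pair_icc_li", "artefact_rate", "dropout_rate",
            "invalid_trial_rate")
  for (f in frac) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || v < 0 || v > 1)
      stop("configuration error: ", f, " must be a fraction in [0, 1]")
  }
  if (length(zygosity_mix) != 3 || any(zygosity_mix < 0) ||
      abs(sum(zygosity_mix) - 1) > 1e-9)
    stop("configuration error: zygosity_mix must be 3 fractions summing to 1")
  if (!is.numeric(n_pairs) || n_pairs < 1 || n_pairs != round(n_pairs))
    stop("configuration error: n_pairs must be a positive integer")
  if (sampling_rate < 10)
    stop("configuration error: sampling_rate must be >= 10 Hz")
  if (n_trials < 1)
    stop("configuration error: n_trials must be >= 1")
  for (f in c("heart_rate_mean", "base_velocity_left", "base_velocity_right"))
    if (cfg[[f]] <= 0) stop("configuration error: ", f, " must be positive")
  if (is.null(cfg$language_score_params$norms))
    cfg$language_score_params$norms <- battery_norms()
  cfg$n_pairs <- as.integer(n_pairs)
  cfg$seed <- as.integer(seed)
  class(cfg) <- "sim_config"
  cfg
}
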