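---
title: "Measuring language laterality with fTCD: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring language laterality with fTCD: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ftcdlat)
```

# The measurement problem

Functional transcranial Doppler sonography measures blood-flow velocity in
the left and right middle cerebral arteries while a participant performs a
language task. In the animation-description paradigm a child silently
watches a 12 s cartoon clip, then describes it aloud for 10 s. Speech
production raises perfusion in language cortex; because the MCAs supply the
perisylvian language regions, left-hemisphere dominance appears as a
sustained left-over-right velocity difference once speech-related flow
changes have developed (about 4 s into the talk phase). The signal is small
— a few percent — and sits on top of cardiac pulsatility an order of
magnitude larger, probe-movement artefacts, and trial-to-trial behavioural
variation, which is what the processing chain exists to remove.

# The processing chain

`process_recording()` applies, in order:

1. **Heart-cycle integration.** Systolic peaks are detected on the summed
   channels (the cardiac waveform is common to both probes) with a minimum
   inter-peak interval of `60 / max_rate` s; every sample within a cycle is
   replaced by that cycle's per-channel mean. Putative cycles longer than
   one beat at `min_rate` (default 40 bpm) cannot be cardiac and pass
   through unchanged — this keeps the step well-defined on recordings with
   negligible pulsatility, where slow activation maxima would otherwise be
   mistaken for beats and the lateral signal averaged away.
2. **Dropout repair.** Brief probe dropouts appear as isolated aberrant
   samples. Within each provisional trial epoch, a sample is a candidate if
   it is non-positive or deviates from the trial median by more than
   `mad_k` (default 4) scaled MADs; candidate runs of at most `max_run`
   (default 1) samples are replaced by the mean of the trial's clean
   samples. Repair runs on the *raw* signal, before integration and
   normalisation: a single extreme value would otherwise corrupt its
   cycle's mean and bias the normalisation constant. Longer runs are left
   alone — they are artefacts, not dropouts, and trial rejection handles
   them.
3. **Normalisation.** Each channel is linearly rescaled so its mean over
   the epoched samples is exactly 100. All later quantities are therefore
   in percent units, and any multiplicative gain difference between probes
   cancels (the pipeline is invariant to rescaling either raw channel).
4. **Epoching.** One epoch per talk-onset marker, half-open window
   [−12, +15) s, sample-aligned. Behaviourally invalid trials (the child
   spoke during a silent period or failed to talk) are rejected with reason
   `behaviour`; epochs that would overrun the recording are dropped with a
   warning.
5. **Artefact rejection.** Any accepted epoch containing a sample outside
   [60, 140] normalized units on either channel is rejected with reason
   `range`. The bounds are configurable; 60/140 marks a ±40% excursion
   around the normalized mean, far beyond physiological flow modulation.
6. **Baseline correction.** Per channel and epoch, the mean over the 12 s
   viewing interval [−12, 0) is subtracted, so post-onset values read as
   percentage-point changes from that trial's own baseline.

## The laterality index

Accepted epochs are averaged pointwise into grand-mean curves; their
difference (left − right) carries the lateralised response. Within the
period of interest (POI, 4–14 s after talk onset, closed at sample
resolution) the sample with the greatest *absolute* difference anchors a
2 s window, and the LI is the signed mean of the difference curve over that
window. Using the absolute difference means right-dominant children get a
meaningful peak rather than whatever the largest positive blip happens to
be; ties break to the earliest sample so the result is deterministic.
Trial-by-trial LIs over the same fixed window give
SE = SD(trial LIs)/√n (n−1 denominator), and the 95% CI uses the normal
1.96 multiplier exactly — not a t quantile — because the categorisation
rule is defined in those terms. A CI lying strictly above zero codes
**left**, strictly below **right**, otherwise **bilateral**; an endpoint at
exactly zero counts as crossing, the conservative reading. Children with
fewer than 12 accepted trials or |LI| > 10 are flagged unusable.

Split-half LIs re-run the entire grand-average-and-peak procedure
separately on the odd- and even-numbered accepted trials — each half finds
its own peak and window, mirroring what running the procedure on half the
data would actually do — and cohort split-half reliability is the Pearson
correlation between the two across usable children. Per-MCA percent change
is the POI mean of the corrected signal per channel, averaged over accepted
trials.

# Behavioural instruments

The adapted Edinburgh Handedness Inventory scores ten demonstrated actions
(1 right / 0.5 both / 0 left), mapped linearly to an index
`(2·score − 10)·10` in −100…100; only the endpoints of this mapping are
conventionally fixed, and the linear interpolation is the natural choice.
Right-handedness requires an index strictly above 0. The Quantification of
Hand Preference task counts right-handed reaches to cards at seven
positions spanning the midline (3 reaches each, 21 total); right-handedness
requires strictly more than 10. Consistent left-hemisphere dominance means
left-lateralised fTCD *and* right-handed on both instruments. DLD
classification flags any of the 13 language/literacy measures falling
strictly more than 1 SD below its population norm and assigns DLD at two or
more flags. Norm scales follow the conventional family per instrument
(standard scores 100/15, scaled scores 10/3, t-scores 50/10) via
`battery_norms()`; the table is replaceable when an instrument uses another
scale.

# Group statistics for twin cohorts

Twins violate independence, so every group comparison models pair
membership. Continuous outcomes use a linear mixed model with a pair random
intercept (REML, Satterthwaite degrees of freedom, marginal means at
balanced factor levels). Binary outcomes use a multilevel logistic model;
ORs get profile-likelihood CIs with a Wald fallback that is flagged when
profiling fails. The three-way laterality category uses a baseline-category
multinomial model (bilateral-vs-left and right-vs-left equations) with
pair random intercepts per equation, sampled by a seeded
Metropolis-within-Gibbs chain: Normal(0, 10²) priors on fixed effects,
half-Normal(0, 5) on random-effect SDs, a jointly adapted random walk for
the fixed effects, and a *non-centred* parameterisation (u = σ·z) for the
random effects — with only two children per pair the likelihood barely
identifies σ, and a centred sampler goes sticky as σ approaches zero.
Default chain settings are 6000 iterations, 1500 burn-in, thinning 2;
convergence is monitored by split-half R-hat per fixed effect and reported
alongside posterior-median ORs, central 95% credible intervals, and
pMCMC = 2·min(P(β>0), P(β<0)).

Handedness scores are bounded and heavily right-skewed, with attainable
endpoints. Rescaled to [0, 1], they are modelled by zero-one-inflated beta
regression: point masses α₀ and α₁ at the endpoints and a
Beta(μφ, (1−μ)φ) interior with logit(μ) = β₀ + β₁·group. The likelihood
factorizes, so the inflation probabilities have their closed-form
multinomial MLE (the endpoint proportions) and only the beta component
needs numerical optimization (BFGS on (β₀, β₁, log φ), Wald t-tests with
n_interior − 2 df). Because no available inflated-beta implementation takes
a random effect, non-independence is handled by design instead: the model
is fitted separately in the twin-1 and twin-2 subsamples, and an effect
counts only if p < .05 in both. The same twin-subsample logic drives the
replicated Spearman screen (rank correlations because the LI is not
normal), Holm-adjusted within each 14-measure family and requiring
adjusted significance in both subsamples.

The QHP position analysis enters position as numeric 1–7 with group and
their interaction, plus random intercepts for pair and for child nested in
pair — each child contributes seven rows, so a child-level intercept is
needed even though the published description mentions only the pair effect.
Cohen's d uses the unweighted root-mean of the two group variances; this
convention reproduces the conventional values for the descriptive
comparisons the package reports. Pseudo-R² is the proportional reduction in
residual variance between nested mixed models sharing the random-effect
structure, floored at zero. Models drop incomplete cases per analysis with
logged counts.

# The synthetic cohort generator

`generate_cohort()` exists so that every stage above can be validated
against known truth without any external data. Per child it synthesizes a
two-channel recording as

baseline velocity × (1 + activation + lateral effect / 2 ± noise) + cardiac waveform,

with: a cardiac waveform (fundamental plus second harmonic) at a per-child
heart rate around 95 bpm; a gamma-shaped bilateral activation peak maximal
about 2 s after talk onset (`activation_peak_pct`, default 4%); and a
lateral plateau that ramps up over 2–3 s and is exactly flat from 3 s to
the epoch end, so that any 2 s window inside the POI averages to the
injected effect — making the generator a sharp oracle for the LI rather
than an approximate one. Each trial's effect wobbles around the child's
true value (`trial_li_sd`, default 3 percentage points) and white noise is
added per sample (`sample_noise_sd`, default 1%). These two dispersion
knobs are what give realistic trial-wise SEs (~0.6 at 26 accepted trials);
without them every SE would be zero and CI categorisation degenerate.
Trials follow the task timing exactly: 12 s viewing, 10 s talk, 5 s gap
(the inter-trial gap is not specified by the task description; 5 s makes
consecutive [−12, +15) epochs abut without overlap). The lateral plateau
ends with the epoch rather than decaying into the next trial's viewing
interval, a deliberate simplification that keeps each trial's baseline
uncontaminated.

Population structure: true lateral effects are drawn pair-correlated
(`pair_icc_li`, default 0.3) from N(1.8, 3²) — matching the typical
observed cohort mean and SD — then a configured fraction of children is
folded negative (right-dominant, default 0.15) or shrunk toward zero
(bilateral, default 0.18). The folding slightly perturbs the nominal ICC,
so ICC validation uses configurations without folding. Handedness rests on
a single pair-correlated latent driving both instruments: EHI items are
right with probability plogis(slope·latent) (plus a small fixed "both"
rate), and QHP reaches follow a monotone logit in latent and position, so a
latent of zero yields the symmetric expectation of 10.5 right reaches.
Language scores are equicorrelated normal (ρ = 0.5) on each measure's norm
scale; DLD-destined children receive a common latent shift (default 0.75
SD, giving a realistic 4–6 flags among affected children). Because the
≥2-of-13 rule also fires at a nonzero base rate in unshifted children, the
destined fraction is calibrated against a small Monte-Carlo estimate of
both rates so the realized prevalence matches `prop_dld_target` in
expectation. `group_li_shift` (default 0, the null) adds a group difference
in true laterality when non-null power checks are wanted. Synthesis happens
directly at the configured `sampling_rate` (default 25 Hz): that resolves
the ~1.5 Hz cardiac waveform with ~16 samples per beat while keeping
cohort-scale simulation cheap, and the integrator is additionally validated
at 100 Hz.

What the generator deliberately does **not** emulate: physiological
hemodynamics (autoregulation, respiratory modulation, heart-rate
variability), probe physics, per-item psychometrics of the language
battery, or pair correlation in language ability beyond the shared
classification shift. Passing tests therefore demonstrate correctness of
the *algorithms* under controlled conditions, not robustness to every
artefact of real recordings.

# Numerical choices and edge cases

- Peak-window and POI selections use a 1 ns time tolerance so binary
  floating-point representation of sample times can never shift a window
  boundary by one sample.
- Ties in the peak search break to the earliest sample; the peak window is
  clipped to the epoch extent when the peak lies within 1 s of it.
- An epoch whose samples are all dropout candidates is rejected
  (`flat/dropout`) rather than imputed into a constant.
- Already-rejected trials keep their first rejection reason; the range rule
  never overwrites a behavioural rejection.
- Mixed-model singular fits (zero variance estimates) are flagged, not
  errored: with two children per pair they are a legitimate outcome.
- Logistic separation (|β| > 10 or SE > 50) suppresses the OR with a flag.
- ZOIB fits with no interior observations skip the beta component and flag
  it.
- The MCMC sampler is bit-reproducible given (data, seed, settings).

# Validation problem sizes

The test suite validates parameter recovery at sizes chosen to balance
statistical sharpness against a desk-scale run: type-I error of the group
LMM over 1000 null replicates of 200 pairs (α = .05, acceptance band
0.035–0.065), CI coverage over 500 replicates with an injected 0.5-unit
shift (band 0.93–0.97), multilevel-logistic OR recovery over 200 replicates
of 300 pairs, ZOIB recovery at n = 500, split-half reliability on a
30-pair full-pipeline cohort, and LI ground-truth recovery within 0.2 on
low-noise cohorts. The whole suite runs in a few minutes on one CPU.

# Known limitations

- The artefact-rejection bounds, dropout rule and trial-gap length are
  package conventions, configurable but not empirically fitted.
- The inflated-beta model puts the group effect only on μ; group effects on
  φ or on the inflation probabilities are not modelled.
- The multinomial sampler is a single chain (split-half diagnostics); for
  publication-grade posteriors one would run multiple dispersed chains.
- Real fTCD deposits come in vendor formats; the TSV dialect here is a
  package convention for synthetic and adapted data, and readers for
  vendor formats must be written separately.
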