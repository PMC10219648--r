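#' Simulator configuration
#'
#' Assembles the full parameter set for the behaviour and photometry
#' simulators. Defaults are phenotype- and day-conditioned: sign-trackers
#' (`"ST"`) acquire lever pressing and a cue-dominant dopamine transient by
#' day 5, while goal-trackers/intermediates (`"GT_INT"`) acquire food-cup
#' poking and retain a reward-dominant signal. Day 1 parameters are
#' reward-dominant for both phenotypes, so the cue-reward difference score
#' flips sign across training (the US-to-CS transfer the pipeline is meant
#' to recover).
#'
#' Transient amplitudes are expressed as peak dF/F of the
#' difference-of-exponentials sensor kernel. The `spontaneous` amplitude
#' drives a Poisson background of untriggered dopamine transients
#' (`spont_rate` per minute), which is what gives per-trial signal metrics
#' realistic variability; setting every amplitude to zero yields a
#' pure-noise stream.
#'
#' @param phenotype `"ST"` or `"GT_INT"`.
#' @param day Training day 1-5; selects amplitude and behaviour-rate tables
#'   (linearly interpolated between the day-1 and day-5 anchors).
#' @param condition Session condition label. `PELLET_SATED` halves cue
#'   amplitudes and press/poke rates, `CHOW_SATED` scales both by 0.8,
#'   `FENTANYL` scales all transient amplitudes by 1.5 leaving behaviour and
#'   CS+/CS- discrimination untouched; `BASELINE`, `SHAM` and `VEHICLE` are
#'   neutral.
#' @param sampling_rate Stream sampling rate, Hz. The kernel rise must be
#'   resolvable: `sampling_rate >= 4 / tau_rise`.
#' @param tau_rise,tau_decay Sensor kernel time constants, s.
#' @param rpe_tau_rise,rpe_tau_decay,rpe_delay Kernel and onset delay (s)
#'   of the slow prediction-error bump/dip component, which peaks 2-3 s
#'   after delivery/omission.
#' @param amplitudes Optional named list overriding any of `cs_plus_onset`,
#'   `cs_minus_onset`, `reward`, `rpe_positive_bump`, `rpe_negative_dip`,
#'   `spontaneous` (peak dF/F).
#' @param amplitude_cv Multiplicative per-event amplitude jitter (CV of a
#'   truncated normal).
#' @param spont_rate Background transient rate, events/min.
#' @param f0,f0_iso Baseline fluorescence of the signal and isosbestic
#'   channels, arbitrary units.
#' @param bleach_params Double-exponential photobleaching curve
#'   `a1*exp(-t/tau1) + a2*exp(-t/tau2) + c`; coefficients must be
#'   non-negative so the curve is non-increasing.
#' @param artifact_rate Motion artifact rate, events/min; artifacts are
#'   Gaussian bumps (`artifact_width` s SD, amplitude up to
#'   `artifact_amp`, random sign) applied multiplicatively to both channels.
#' @param noise_sd Length-2 named vector `c(sig=, iso=)` of additive white
#'   noise SDs, same units as `f0`.
#' @param behavior_params Optional named list overriding press/poke rates
#'   (events/s during the cue), ITI poke rate, retrieval latency or the
#'   post-omission poke multiplier.
#' @param disconnect_prob Per-trial probability of a patch-cord disconnect
#'   (both channels drop to zero for 1-3 s inside the trial window).
#' @param seed Integer seed shared by the behaviour and photometry draws.
#' @return A `sim_config` list.
#' @export
sim_config <- function(phenotype = c("ST", "GT_INT"), day = 5,
                       condition = c("BASELINE", "PELLET_SATED", "CHOW_SATED",
                                     "SHAM", "FENTANYL", "VEHICLE"),
                       sampling_rate = 1000,
                       tau_rise = 0.1, tau_decay = 0.6,
                       rpe_tau_rise = 0.3, rpe_tau_decay = 1.5,
                       rpe_delay = 1.5,
                       amplitudes = list(), amplitude_cv = 0.2,
                       spont_rate = 6,
                       f0 = 100, f0_iso = 60,
                       bleach_params = list(a1 = 0.1, tau1 = 120,
                                            a2 = 0.2, tau2 = 1500, c = 0.7),
                       artifact_rate = 6, artifact_amp = 0.25,
                       artifact_width = 2,
                       noise_sd = c(sig = 1.5, iso = 0.9),
                       behavior_params = list(),
                       disconnect_prob = 0, seed = 1L) {
  phenotype <- match.arg(phenotype)
  condition <- match.arg(condition)
  assert_scalar_number(sampling_rate, "sampling_rate")
  if (sampling_rate <= 0) stop_config("sampling_rate must be positive")
  if (day < 1 || day > 5) stop_config("day must be in 1..5")
  if (any(unlist(bleach_params) < 0))
    stop_config("bleach_params must be non-negative")

  amp <- default_amplitudes(phenotype, day)
  amp[names(amplitudes)] <- amplitudes
  if (any(!is.finite(unlist(amp)))) stop_config("amplitudes must be finite")
  beh <- default_behavior_params(phenotype, day)
  beh[names(behavior_params)] <- behavior_params

  mods <- condition_modifiers(condition)
  amp$cs_plus_onset <- amp$cs_plus_onset * mods$cue_signal * mods$signal
  amp$cs_minus_onset <- amp$cs_minus_onset * mods$cue_signal * mods$signal
  for (k in c("reward", "rpe_positive_bump", "rpe_negative_dip",
              "spontaneous"))
    amp[[k]] <- amp[[k]] * mods$signal
  for (k in c("press_rate_csp", "press_rate_csm", "poke_rate_csp",
              "poke_rate_csm"))
    beh[[k]] <- beh[[k]] * mods$behavior

  structure(list(
    phenotype = phenotype, day = day, condition = condition,
    sampling_rate = sampling_rate,
    tau_rise = tau_rise, tau_decay = tau_decay,
    rpe_tau_rise = rpe_tau_rise, rpe_tau_decay = rpe_tau_decay,
    rpe_delay = rpe_delay,
    amplitudes = amp, amplitude_cv = amplitude_cv, spont_rate = spont_rate,
    f0 = f0, f0_iso = f0_iso, bleach_params = bleach_params,
    artifact_rate = artifact_rate, artifact_amp = artifact_amp,
    artifact_width = artifact_width, noise_sd = noise_sd,
    behavior_params = beh, disconnect_prob = disconnect_prob,
    seed = as.integer(seed)), class = "sim_config")
}

# Day-anchored transient amplitude tables (peak dF/F). Day 1 is
# reward-dominant for both phenotypes; by day 5 sign-trackers are
# cue-dominant while goal-trackers/intermediates stay reward-weighted.
default_amplitudes <- function(phenotype, day) {
  w <- (day - 1) / 4
  lerp <- function(d1, d5) d1 + w * (d5 - d1)
  if (phenotype == "ST") {
    list(cs_plus_onset = lerp(0.010, 0.060),
         cs_minus_onset = lerp(0.008, 0.010),
         reward = lerp(0.050, 0.020),
         rpe_positive_bump = 0.050,
         rpe_negative_dip = 0,
         spontaneous = 0.015)
  } else {
    list(cs_plus_onset = lerp(0.010, 0.030),
         cs_minus_onset = lerp(0.008, 0.010),
         reward = lerp(0.050, 0.030),
         rpe_positive_bump = 0.050,
         rpe_negative_dip = -0.040,
         spontaneous = 0.015)
  }
}

# Press/poke rates are events/s while the lever is inserted; counts within
# a cue are Poisson with uniform event times, so first-response latencies
# follow the induced minimum-order-statistic law.
default_behavior_params <- function(phenotype, day) {
  w <- (day - 1) / 4
  lerp <- function(d1, d5) d1 + w * (d5 - d1)
  if (phenotype == "ST") {
    list(press_rate_csp = lerp(0.10, 0.80),
         poke_rate_csp = lerp(0.15, 0.05),
         press_rate_csm = lerp(0.08, 0.08),
         poke_rate_csm = lerp(0.12, 0.03),
         iti_poke_rate = 0.05,
         retrieval_latency = 0.8,
         poke_dwell = 0.5,
         post_negative_poke_mult = 1)
  } else {
    list(press_rate_csp = lerp(0.10, 0.05),
         poke_rate_csp = lerp(0.15, 0.60),
         press_rate_csm = lerp(0.08, 0.03),
         poke_rate_csm = lerp(0.12, 0.08),
         iti_poke_rate = 0.05,
         retrieval_latency = 0.8,
         poke_dwell = 0.5,
         post_negative_poke_mult = 1)
  }
}

condition_modifiers <- function(condition) {
  switch(condition,
    BASELINE = ,
    SHAM = ,
    VEHICLE = list(signal = 1, cue_signal = 1, behavior = 1),
    PELLET_SATED = list(signal = 1, cue_signal = 0.5, behavior = 0.5),
    CHOW_SATED = list(signal = 1, cue_signal = 0.8, behavior = 0.8),
    FENTANYL = list(signal = 1.5, cue_signal = 1, behavior = 1))
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %s day %d (%s), %g Hz, seed %d\n",
    x$phenotype, x$day, x$condition, x$sampling_rate, x$seed))
  amp <- unlist(x$amplitudes)
  cat("  amplitudes (dF/F): ",
      paste(sprintf("%s=%.3g", names(amp), amp), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}
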