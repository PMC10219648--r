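# shared fixtures: small schedules and simulator configs sized for fast tests

zero_amplitudes <- function() {
  list(cs_plus_onset = 0, cs_minus_onset = 0, reward = 0,
       rpe_positive_bump = 0, rpe_negative_dip = 0, spontaneous = 0)
}

zero_behavior <- function() {
  list(press_rate_csp = 0, poke_rate_csp = 0, press_rate_csm = 0,
       poke_rate_csm = 0, iti_poke_rate = 0)
}

small_pla <- function(n = 5, seed = 1, ...) {
  pla_schedule(n_cs_plus = n, n_cs_minus = n, seed = seed, ...)
}

# clean configuration: no noise, no artifacts, no background transients
clean_config <- function(..., sampling_rate = 100) {
  args <- list(...)
  amps <- zero_amplitudes()
  if (!is.null(args$amplitudes)) {
    amps[names(args$amplitudes)] <- args$amplitudes
    args$amplitudes <- NULL
  }
  do.call(sim_config, c(list(
    sampling_rate = sampling_rate, amplitudes = amps, amplitude_cv = 0,
    artifact_rate = 0, noise_sd = c(sig = 0, iso = 0)), args))
}

# build an epoch_matrix directly from a z matrix (for epoch/QC unit tests)
epoch_from_matrix <- function(z, rate = 100, t0 = -5,
                              trial_type = "CS_PLUS") {
  structure(list(
    z = z,
    rel_time = seq(t0, by = 1 / rate, length.out = ncol(z)),
    trial = seq_len(nrow(z)),
    trial_type = rep(trial_type, length.out = nrow(z)),
    align_event = "cue_onset", baseline_window = c(t0, 0),
    excluded = tibble::tibble(trial = integer(), reason = character())),
    class = "epoch_matrix")
}

# two-sided permutation test for a difference in group means
perm_test_diff <- function(x, y, n_perm = 499, seed = 1) {
  obs <- mean(x) - mean(y)
  pooled <- c(x, y)
  nx <- length(x)
  stats <- pavphot:::with_seed(seed, replicate(n_perm, {
    idx <- sample.int(length(pooled), nx)
    mean(pooled[idx]) - mean(pooled[-idx])
  }))
  (1 + sum(abs(stats) >= abs(obs))) / (n_perm + 1)
}
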