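#!/usr/bin/env Rscript
# Signal-inclusion QC on the day-5 sessions of the simulated cohort: the
# 2z peak-amplitude criterion on the trial-averaged CS+ trace (0 to +20 s
# from cue onset) and the bootstrap criterion (95% CI of the trial-mean
# trace from 1000 trial resamples; needs >= 40 ms of consecutive
# significance). Onset latency of the first significant point is reported
# alongside. One rat is simulated with all transient amplitudes at zero as
# a negative control and should be excluded.

suppressPackageStartupMessages({
  library(pavphot)
  library(dplyr)
})

seed <- 20260921L
dir.create("results", showWarnings = FALSE)
n_per_group <- 4L

qc_rows <- list()
cs_plus_epoch <- function(r, phenotype, day, amplitudes) {
  sched <- pla_schedule(seed = seed + 37L * r + day)
  cfg <- sim_config(phenotype = phenotype, day = day, sampling_rate = 100,
                    seed = seed + 1000L * r + day, amplitudes = amplitudes)
  sess <- simulate_session(sched, cfg)
  corr <- correct_photometry(sess$raw, sched)
  epoch_and_zscore(corr$trace, sched, "cue_onset", types = "CS_PLUS",
                   exclude_trials = corr$excluded_trials)
}
run_rat <- function(r, phenotype, amplitudes = list()) {
  # peak criterion may be met on day 1 or day 5; bootstrap runs on day 5
  ep1 <- cs_plus_epoch(r, phenotype, 1, amplitudes)
  ep5 <- cs_plus_epoch(r, phenotype, 5, amplitudes)
  p1 <- peak_inclusion(ep1)
  p5 <- peak_inclusion(ep5)
  peak <- structure(as.logical(p1) || as.logical(p5),
                    peak_z = max(attr(p1, "peak_z"), attr(p5, "peak_z")))
  boot <- bootstrap_trace_ci(ep5, n_resamples = 1000,
                             seed = seed + 1000L * r)
  rep <- inclusion_decision(peak, boot)
  tibble::tibble(rat = r, phenotype = phenotype,
                 peak_pass = rep$peak_pass, peak_z = rep$peak_z,
                 onset_latency_s = rep$onset_latency_s,
                 max_consecutive_sig_s = rep$max_consecutive_sig_s,
                 included = rep$included)
}
for (r in seq_len(2 * n_per_group))
  qc_rows[[r]] <- run_rat(r, if (r <= n_per_group) "ST" else "GT_INT")
# negative control: sensor expressing but no dopamine binding
qc_rows[[length(qc_rows) + 1L]] <- run_rat(
  99L, "ST", amplitudes = list(cs_plus_onset = 0, cs_minus_onset = 0,
                               reward = 0, rpe_positive_bump = 0,
                               rpe_negative_dip = 0, spontaneous = 0))
qc <- bind_rows(qc_rows)
write.csv(qc, "results/qc_inclusion.csv", row.names = FALSE)

for (i in seq_len(nrow(qc)))
  message(sprintf(
    "rat %2d (%6s): peak %5.2f z [%s], onset %s, run %5.3f s -> %s",
    qc$rat[i], qc$phenotype[i], qc$peak_z[i],
    if (qc$peak_pass[i]) "pass" else "fail",
    if (is.na(qc$onset_latency_s[i])) "  none " else
      sprintf("%5.3f s", qc$onset_latency_s[i]),
    qc$max_consecutive_sig_s[i],
    if (qc$included[i]) "INCLUDED" else "excluded"))
message(sprintf("included %d of %d rats (negative control excluded: %s)",
                sum(qc$included), nrow(qc), !qc$included[qc$rat == 99]))
message("wrote results/qc_inclusion.csv")
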