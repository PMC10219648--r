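#!/usr/bin/env Rscript
# Reward-prediction-error probe: 13 simulated rats (7 GT/INT, 6 ST) each
# get one 48-trial session mixing expected deliveries, unsignalled
# deliveries (positive RPE) and omissions (negative RPE). Signals aligned
# to delivery/omission are summarised in three 2-s bins (0-6 s), and
# anticipatory food-cup checking is read from the 10 s before each trial,
# keyed by the preceding trial's type.

suppressPackageStartupMessages({
  library(pavphot)
  library(dplyr)
})

seed <- 20260921L
dir.create("results", showWarnings = FALSE)
rats <- tibble::tibble(rat = 1:13,
                       phenotype = rep(c("GT_INT", "ST"), c(7, 6)))

bins_all <- check_all <- list()
for (i in seq_len(nrow(rats))) {
  sched <- rpe_schedule(seed = seed + 11L * i)
  cfg <- sim_config(phenotype = rats$phenotype[i], day = 5,
                    sampling_rate = 50, seed = seed + 2000L * i,
                    behavior_params = list(iti_poke_rate = 0.2,
                                           post_negative_poke_mult = 2))
  sess <- simulate_session(sched, cfg)
  rpe <- analyze_rpe_session(sess$raw, sched)
  bins_all[[i]] <- mutate(rpe$bins, rat = rats$rat[i],
                          phenotype = rats$phenotype[i], .before = 1)
  check_all[[i]] <- mutate(pretrial_check_rate(sess$events, sched),
                           rat = rats$rat[i],
                           phenotype = rats$phenotype[i], .before = 1)
}
bins <- bind_rows(bins_all)
checks <- bind_rows(check_all)
write.csv(bins, "results/rpe_bins.csv", row.names = FALSE)
write.csv(checks, "results/pretrial_checking.csv", row.names = FALSE)

summ <- bins |>
  summarise(mean_z = mean(mean_z), .by = c(phenotype, trial_type, bin)) |>
  arrange(phenotype, bin, trial_type)
for (ph in unique(summ$phenotype)) {
  b2 <- filter(summ, phenotype == ph, bin == 2)
  message(sprintf(
    "%6s bin 2 (2-4 s): expected %5.2f, positive %5.2f, negative %5.2f z",
    ph, b2$mean_z[b2$trial_type == "EXPECTED"],
    b2$mean_z[b2$trial_type == "POSITIVE"],
    b2$mean_z[b2$trial_type == "NEGATIVE"]))
}
chk <- checks |> summarise(rate = mean(rate), .by = prev_type)
message(sprintf(
  "pre-trial checking (pokes/10 s) after expected %.2f, positive %.2f, negative %.2f",
  chk$rate[chk$prev_type == "EXPECTED"],
  chk$rate[chk$prev_type == "POSITIVE"],
  chk$rate[chk$prev_type == "NEGATIVE"]))
message("wrote results/rpe_bins.csv and results/pretrial_checking.csv")
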