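#!/usr/bin/env Rscript
# Session design: build one instance of every session type used in the
# study — magazine acclimation (25 reward-only trials over 3 sessions),
# Pavlovian lever autoshaping (25 CS+ / 25 CS- on VI 45 s), and the
# reward-prediction-error probe (48 trials, 24 expected / 12 unsignalled /
# 12 omission) — and record their analytic properties.

library(pavphot)

seed <- 20260921L
dir.create("results/schedules", showWarnings = FALSE, recursive = TRUE)

mag <- magazine_schedules(seed = seed)
for (i in seq_along(mag))
  write_schedule(mag[[i]], sprintf("results/schedules/magazine_%d.csv", i))
message(sprintf("magazine: %s trials over %d sessions (total %d)",
                paste(vapply(mag, nrow, integer(1)), collapse = "/"),
                length(mag), sum(vapply(mag, nrow, integer(1)))))

pla <- pla_schedule(seed = seed)
write_schedule(pla, "results/schedules/pla_day5.csv")
dur <- expected_session_duration(pla)
message(sprintf(
  "PLA: %d CS+ / %d CS- trials; expected span %.0f s (~%d min)",
  sum(pla$trial_type == "CS_PLUS"), sum(pla$trial_type == "CS_MINUS"),
  dur, round(dur / 60)))

rpe <- rpe_schedule(seed = seed)
write_schedule(rpe, "results/schedules/rpe_probe.csv")
counts <- table(rpe$trial_type)
message(sprintf("RPE probe: %d expected / %d positive / %d negative",
                counts[["EXPECTED"]], counts[["POSITIVE"]],
                counts[["NEGATIVE"]]))

# round-trip sanity: what we wrote is what we will analyse
stopifnot(isTRUE(all.equal(
  as.data.frame(read_schedule("results/schedules/pla_day5.csv")),
  as.data.frame(pla), tolerance = 1e-12)))
message("schedules written to results/schedules/ and verified")
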