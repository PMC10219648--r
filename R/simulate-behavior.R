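#' Simulate a behavioural event log
#'
#' Generates a MedPC-style timestamped event log for one session of the
#' given schedule, conditioned on the phenotype and day encoded in
#' `config`. Lever presses occur only while the corresponding lever is
#' inserted; food-cup entries occur during cues and inter-trial intervals;
#' every pellet delivery is followed by a retrieval poke. Press/poke counts
#' within a cue are Poisson with uniform event times, so sign-tracker
#' configurations produce frequent, short-latency CS+ presses and
#' goal-tracker configurations frequent CS+ pokes.
#'
#' Event codes: `CSP_ON`/`CSP_OFF` and `CSM_ON`/`CSM_OFF` (lever
#' insertion/retraction; RPE `EXPECTED` and `NEGATIVE` trials use the CS+
#' lever), `PRESS_P`/`PRESS_M` (lever presses), `FC_ENTRY`/`FC_EXIT`
#' (food-cup beam breaks) and `PELLET` (delivery). Inter-trial food-cup
#' checks carry `trial = NA`.
#'
#' @param schedule A [trial_schedule].
#' @param config A [sim_config()]; its seed makes the log reproducible.
#' @return An event-log tibble with columns `timestamp` (s), `code` and
#'   `trial` (index into the schedule, `NA` for ITI events).
#' @export
simulate_behavior <- function(schedule, config) {
  stopifnot(inherits(schedule, "trial_schedule"),
            inherits(config, "sim_config"))
  bp <- config$behavior_params
  s <- schedule
  n <- nrow(s)

  with_seed(config$seed, {
    rows <- list()
    add <- function(ts, code, trial) {
      if (length(ts) > 0)
        rows[[length(rows) + 1L]] <<- tibble::tibble(
          timestamp = ts, code = code, trial = trial)
    }

    # per-trial window bookkeeping for ITI poke placement
    prev_end <- 0
    for (i in seq_len(n)) {
      ty <- s$trial_type[i]
      cued <- !is.na(s$cue_onset[i])
      uses_csm <- identical(ty, "CS_MINUS")
      trial_start <- if (cued) s$cue_onset[i] else s$reward_1[i]
      trial_end <- if (cued) s$cue_offset[i] else
        prev_end + s$iti_draw[i]

      # ITI food-cup checking between previous trial and this one
      iti_lo <- prev_end
      iti_hi <- if (cued) s$cue_onset[i] else trial_end
      rate <- bp$iti_poke_rate
      if (i > 1 && s$trial_type[i - 1] == "NEGATIVE")
        rate <- rate * bp$post_negative_poke_mult
      len <- max(0, iti_hi - iti_lo)
      n_checks <- rpois(1, rate * len)
      if (n_checks > 0) {
        entries <- sort(runif(n_checks, iti_lo, iti_hi))
        exits <- entries + rexp(n_checks, 1 / bp$poke_dwell)
        if (n_checks > 1)
          exits[-n_checks] <- pmin(exits[-n_checks],
                                   entries[-1] - 1e-3)
        add(entries, "FC_ENTRY", NA_integer_)
        add(exits, "FC_EXIT", NA_integer_)
      }

      if (cued) {
        on_code <- if (uses_csm) "CSM_ON" else "CSP_ON"
        off_code <- if (uses_csm) "CSM_OFF" else "CSP_OFF"
        press_code <- if (uses_csm) "PRESS_M" else "PRESS_P"
        press_rate <- if (uses_csm) bp$press_rate_csm else bp$press_rate_csp
        poke_rate <- if (uses_csm) bp$poke_rate_csm else bp$poke_rate_csp
        dur <- s$cue_offset[i] - s$cue_onset[i]
        add(s$cue_onset[i], on_code, i)
        add(s$cue_offset[i], off_code, i)
        np <- rpois(1, press_rate * dur)
        if (np > 0)
          add(sort(runif(np, s$cue_onset[i], s$cue_offset[i] - 1e-6)),
              press_code, i)
        nk <- rpois(1, poke_rate * dur)
        if (nk > 0) {
          entries <- sort(runif(nk, s$cue_onset[i], s$cue_offset[i] - 1e-6))
          exits <- entries + rexp(nk, 1 / bp$poke_dwell)
          if (nk > 1) exits[-nk] <- pmin(exits[-nk], entries[-1] - 1e-3)
          add(entries, "FC_ENTRY", i)
          add(exits, "FC_EXIT", i)
        }
      }

      if (!is.na(s$reward_1[i])) {
        add(c(s$reward_1[i], s$reward_2[i]), "PELLET", i)
        # retrieval poke after the second pellet
        entry <- s$reward_2[i] + rexp(1, 1 / bp$retrieval_latency)
        add(entry, "FC_ENTRY", i)
        add(entry + rexp(1, 1 / bp$poke_dwell), "FC_EXIT", i)
      }

      prev_end <- max(trial_end,
                      if (!is.na(s$reward_2[i])) s$reward_2[i] else -Inf)
    }

    log <- dplyr::arrange(dplyr::bind_rows(rows), .data$timestamp)
    validate_event_log(log)
    log
  })
}

#' Validate an event log
#'
#' Checks that timestamps are non-decreasing and that every lever
#' insertion has a matching retraction.
#'
#' @param events Event-log tibble (`timestamp`, `code`, `trial`).
#' @return The log, invisibly.
#' @export
validate_event_log <- function(events) {
  if (is.unsorted(events$timestamp))
    stop_config("event timestamps must be non-decreasing")
  for (pair in list(c("CSP_ON", "CSP_OFF"), c("CSM_ON", "CSM_OFF"))) {
    if (sum(events$code == pair[1]) != sum(events$code == pair[2]))
      stop_config("unmatched %s/%s events", pair[1], pair[2])
  }
  invisible(events)
}
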