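#' Trial schedules
#'
#' A trial schedule is a tibble with one row per trial and columns
#' `trial` (1-based index), `trial_type` (`"CS_PLUS"`, `"CS_MINUS"`,
#' `"EXPECTED"`, `"POSITIVE"`, `"NEGATIVE"` or `"MAGAZINE"`), `iti_draw`
#' (the variable-interval draw preceding the trial, s), `cue_onset`,
#' `cue_offset` (s from session start; `NA` for cue-less trials) and
#' `reward_1`, `reward_2` (pellet drop times, s; `NA` when unreinforced).
#' The session kind, generating configuration and seed are carried as
#' attributes and survive CSV round-trips via [write_schedule()].
#'
#' @name trial_schedule
NULL

new_trial_schedule <- function(trials, session_kind, config, seed) {
  out <- tibble::as_tibble(trials)
  attr(out, "session_kind") <- session_kind
  attr(out, "config") <- config
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("trial_schedule", class(out))
  out
}

#' @export
print.trial_schedule <- function(x, ...) {
  cat(sprintf("<trial_schedule> %s session, %d trials, seed %d\n",
              attr(x, "session_kind"), nrow(x), attr(x, "seed")))
  NextMethod()
}

# Seeded shuffle of trial-type labels with a cap on same-type run length.
# Sequential draw weighted by remaining counts; on a dead end (only the
# capped type remains) the whole sequence is redrawn, which keeps the result
# a deterministic function of the RNG state.
constrained_order <- function(counts, max_run = 3L) {
  types <- names(counts)
  if (is.null(types)) stop_config("counts must be a named vector")
  n <- sum(counts)
  # cap unsatisfiable (e.g. a single trial type): plain seeded shuffle
  if (max(counts) > (n - max(counts) + 1) * max_run)
    return(sample(rep(types, times = counts)))
  repeat {
    remaining <- counts
    out <- character(n)
    run_type <- ""
    run_len <- 0L
    ok <- TRUE
    for (i in seq_len(n)) {
      avail <- types[remaining > 0L]
      if (run_len >= max_run) avail <- setdiff(avail, run_type)
      if (length(avail) == 0L) { ok <- FALSE; break }
      pick <- if (length(avail) == 1L) avail else
        sample(avail, 1L, prob = remaining[avail])
      out[i] <- pick
      remaining[pick] <- remaining[pick] - 1L
      if (pick == run_type) run_len <- run_len + 1L
      else { run_type <- pick; run_len <- 1L }
    }
    if (ok) return(out)
  }
}

draw_iti <- function(n, vi_bounds) {
  runif(n, vi_bounds[1], vi_bounds[2])
}

check_vi <- function(vi_mean, vi_bounds) {
  if (length(vi_bounds) != 2L || vi_bounds[1] > vi_bounds[2])
    stop_config("vi_bounds must be an increasing pair, got (%s)",
                paste(vi_bounds, collapse = ", "))
  if (vi_mean < vi_bounds[1] || vi_mean > vi_bounds[2])
    stop_config("vi_mean %.1f lies outside vi_bounds [%g, %g]",
                vi_mean, vi_bounds[1], vi_bounds[2])
}

#' Generate a Pavlovian lever autoshaping (PLA) schedule
#'
#' Builds one session of reinforced (CS+) and non-reinforced (CS-) lever
#' presentation trials in pseudorandom order (at most `max_run` consecutive
#' trials of the same type) on a variable-interval schedule. Each CS+ trial
#' is a `cue_dur` lever insertion followed by two pellet deliveries 0.5 s
#' apart; CS- trials present the other lever with no reward.
#'
#' @param n_cs_plus,n_cs_minus Trial counts per type (defaults 25 + 25).
#' @param cue_dur Lever (cue) duration in seconds, default 10.
#' @param vi_mean Mean of the variable interval, seconds (default 45).
#' @param vi_bounds Length-2 bounds of the uniform VI draw (default 35-55).
#' @param max_run Maximum same-type run length in the pseudorandom order.
#' @param seed Integer seed; identical seeds give identical schedules.
#' @return A [trial_schedule] tibble.
#' @examples
#' sched <- pla_schedule(seed = 1)
#' table(sched$trial_type)
#' @export
pla_schedule <- function(n_cs_plus = 25, n_cs_minus = 25, cue_dur = 10,
                         vi_mean = 45, vi_bounds = c(35, 55),
                         max_run = 3L, seed = 1L) {
  if (n_cs_plus <= 0 || n_cs_minus <= 0)
    stop_config("trial counts must be positive")
  check_vi(vi_mean, vi_bounds)
  config <- list(n_cs_plus = n_cs_plus, n_cs_minus = n_cs_minus,
                 cue_dur = cue_dur, vi_mean = vi_mean, vi_bounds = vi_bounds,
                 max_run = max_run)
  with_seed(seed, {
    types <- constrained_order(
      c(CS_PLUS = n_cs_plus, CS_MINUS = n_cs_minus), max_run)
    n <- length(types)
    iti <- draw_iti(n, vi_bounds)
    onset <- offset <- r1 <- r2 <- numeric(n)
    t <- 0
    for (i in seq_len(n)) {
      onset[i] <- t + iti[i]
      offset[i] <- onset[i] + cue_dur
      if (types[i] == "CS_PLUS") {
        r1[i] <- offset[i]
        r2[i] <- offset[i] + 0.5
      } else {
        r1[i] <- r2[i] <- NA_real_
      }
      t <- offset[i]
    }
    new_trial_schedule(
      tibble::tibble(trial = seq_len(n), trial_type = types, iti_draw = iti,
                     cue_onset = onset, cue_offset = offset,
                     reward_1 = r1, reward_2 = r2),
      "PLA", config, seed)
  })
}

#' Generate a reward-prediction-error (RPE) probe schedule
#'
#' One session presenting only the CS+ lever, with three interleaved trial
#' types: `EXPECTED` (cue followed by reward), `POSITIVE` (unsignalled reward
#' dropped during the inter-trial interval) and `NEGATIVE` (cue with reward
#' omitted). Default mixture is 48 trials split 24/12/12.
#'
#' @param n_total Total trial count (default 48).
#' @param frac_expected,frac_positive,frac_negative Mixture proportions;
#'   must sum to 1 and imply integer counts.
#' @param reward_gap Minimum separation (s) between an unsignalled reward and
#'   any cue interval, so reward-aligned epochs never overlap cue epochs.
#' @inheritParams pla_schedule
#' @return A [trial_schedule] tibble.
#' @export
rpe_schedule <- function(n_total = 48, frac_expected = 0.5,
                         frac_positive = 0.25, frac_negative = 0.25,
                         cue_dur = 10, vi_mean = 45, vi_bounds = c(35, 55),
                         reward_gap = 5, max_run = 3L, seed = 1L) {
  fr <- c(EXPECTED = frac_expected, POSITIVE = frac_positive,
          NEGATIVE = frac_negative)
  if (abs(sum(fr) - 1) > 1e-9)
    stop_config("trial-type fractions must sum to 1 (got %.4f)", sum(fr))
  counts <- fr * n_total
  if (any(abs(counts - round(counts)) > 1e-9))
    stop_config("fractions imply non-integer counts: %s",
                paste(sprintf("%.2f", counts), collapse = "/"))
  counts <- round(counts)  # keeps names
  counts <- counts[counts > 0]
  check_vi(vi_mean, vi_bounds)
  if (vi_bounds[1] <= 2 * reward_gap + 0.5)
    stop_config("vi lower bound too short for reward_gap %.1f", reward_gap)
  config <- list(n_total = n_total, counts = as.list(counts),
                 cue_dur = cue_dur, vi_mean = vi_mean, vi_bounds = vi_bounds,
                 reward_gap = reward_gap, max_run = max_run)
  with_seed(seed, {
    types <- constrained_order(counts, max_run)
    n <- length(types)
    iti <- draw_iti(n, vi_bounds)
    onset <- offset <- r1 <- r2 <- rep(NA_real_, n)
    t <- 0
    for (i in seq_len(n)) {
      if (types[i] == "POSITIVE") {
        # unsignalled reward inside this trial's ITI, clear of cue epochs
        r1[i] <- runif(1, t + reward_gap, t + iti[i] - reward_gap - 0.5)
        r2[i] <- r1[i] + 0.5
        t <- t + iti[i]
      } else {
        onset[i] <- t + iti[i]
        offset[i] <- onset[i] + cue_dur
        if (types[i] == "EXPECTED") {
          r1[i] <- offset[i]
          r2[i] <- offset[i] + 0.5
        }
        t <- offset[i]
      }
    }
    new_trial_schedule(
      tibble::tibble(trial = seq_len(n), trial_type = types, iti_draw = iti,
                     cue_onset = onset, cue_offset = offset,
                     reward_1 = r1, reward_2 = r2),
      "RPE", config, seed)
  })
}

#' Generate magazine-training schedules
#'
#' Reward-only acclimation sessions: each trial delivers two pellets 0.5 s
#' apart at the end of a variable interval, with no cue. The default splits
#' 25 trials over three sessions of 7, 8 and 10 trials on a VI 60 s
#' (50-70 s) schedule.
#'
#' @param trials_per_session Integer vector, one entry per session.
#' @inheritParams pla_schedule
#' @return A list of [trial_schedule] tibbles, one per session.
#' @export
magazine_schedules <- function(trials_per_session = c(7, 8, 10),
                               vi_mean = 60, vi_bounds = c(50, 70),
                               seed = 1L) {
  if (length(trials_per_session) == 0L)
    stop_config("trials_per_session must be non-empty")
  if (any(trials_per_session <= 0))
    stop_config("trial counts must be positive")
  check_vi(vi_mean, vi_bounds)
  with_seed(seed, {
    lapply(seq_along(trials_per_session), function(s) {
      n <- trials_per_session[s]
      iti <- draw_iti(n, vi_bounds)
      r1 <- cumsum(iti)
      new_trial_schedule(
        tibble::tibble(trial = seq_len(n), trial_type = "MAGAZINE",
                       iti_draw = iti, cue_onset = NA_real_,
                       cue_offset = NA_real_, reward_1 = r1,
                       reward_2 = r1 + 0.5),
        "MAGAZINE",
        list(n_trials = n, session = s, vi_mean = vi_mean,
             vi_bounds = vi_bounds),
        seed)
    })
  })
}

#' Expected session duration from schedule parameters
#'
#' Analytic expectation of the span of a schedule:
#' `n_trials * (cue_dur + vi_mean)`, with `cue_dur = 0` for cue-less
#' sessions. Accepts either a [trial_schedule] (its stored config is used)
#' or an explicit parameter list.
#'
#' @param x A [trial_schedule], or a list with `n_trials`, `cue_dur` and
#'   `vi_mean`.
#' @return Expected duration in seconds.
#' @examples
#' expected_session_duration(list(n_trials = 50, cue_dur = 10, vi_mean = 45))
#' @export
expected_session_duration <- function(x) {
  if (inherits(x, "trial_schedule")) {
    cfg <- attr(x, "config")
    n_cued <- sum(!is.na(x$cue_onset))
    n_uncued <- sum(is.na(x$cue_onset))
    cue_dur <- if (n_cued > 0) cfg$cue_dur else 0
    return(n_cued * (cue_dur + cfg$vi_mean) + n_uncued * cfg$vi_mean)
  }
  n <- x$n_trials
  if (is.null(n)) stop_config("need `n_trials` in schedule config")
  cue <- if (is.null(x$cue_dur)) 0 else x$cue_dur
  vi <- x$vi_mean
  if (is.null(vi)) stop_config("need `vi_mean` in schedule config")
  n * (cue + vi)
}

#' Validate schedule invariants
#'
#' Checks strict temporal ordering, per-type counts against the stored
#' config, ITI draws within bounds, cue duration, and pellet spacing.
#' Called on every schedule read back from disk.
#'
#' @param schedule A [trial_schedule].
#' @return The schedule, invisibly; errors describe the first violation.
#' @export
validate_schedule <- function(schedule) {
  cfg <- attr(schedule, "config")
  s <- schedule
  ev <- c(s$cue_onset, s$reward_1)
  ev <- ev[!is.na(ev)]
  starts <- ifelse(is.na(s$cue_onset), s$reward_1, s$cue_onset)
  if (any(diff(starts[!is.na(starts)]) <= 0))
    stop_config("trial times are not strictly increasing")
  if (!is.null(cfg$vi_bounds) &&
      any(s$iti_draw < cfg$vi_bounds[1] - 1e-9 |
          s$iti_draw > cfg$vi_bounds[2] + 1e-9))
    stop_config("ITI draw outside configured bounds")
  cued <- !is.na(s$cue_onset)
  if (!is.null(cfg$cue_dur) && any(cued) &&
      any(abs((s$cue_offset - s$cue_onset)[cued] - cfg$cue_dur) > 1e-9))
    stop_config("cue duration differs from configured value")
  rew <- !is.na(s$reward_1)
  if (any(rew & is.na(s$reward_2)) ||
      any(abs((s$reward_2 - s$reward_1)[rew] - 0.5) > 1e-9))
    stop_config("reward deliveries must be two pellets 0.5 s apart")
  # cue intervals must not overlap
  if (sum(cued) > 1) {
    on <- s$cue_onset[cued]; off <- s$cue_offset[cued]
    if (any(on[-1] < off[-length(off)] - 1e-9))
      stop_config("cue intervals overlap")
  }
  invisible(schedule)
}
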