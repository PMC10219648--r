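#' Score per-trial behaviour
#'
#' Counts lever presses and food-cup entries, and first-response latencies,
#' strictly within each cue's `[onset, offset)` window. Trials with no
#' response get latency equal to the cue duration (the maximum observable
#' value). Cue-less trials (`POSITIVE`, `MAGAZINE`) get `NA` measures.
#' Events that fall outside every cue window and are not ITI-classifiable
#' food-cup checks trigger a warning and are ignored.
#'
#' @param events Event-log tibble from [simulate_behavior()] or
#'   [read_event_log()].
#' @param schedule The session's [trial_schedule].
#' @return Tibble with one row per trial: `trial`, `trial_type`, `presses`,
#'   `pokes`, `press_latency`, `poke_latency`.
#' @export
score_trials <- function(events, schedule) {
  s <- schedule
  cue_dur <- attr(s, "config")$cue_dur
  if (is.null(cue_dur)) cue_dur <- 10
  press_codes <- c("PRESS_P", "PRESS_M")
  presses <- events[events$code %in% press_codes, ]
  # presses outside every cue interval are orphans: levers are retracted
  cued <- which(!is.na(s$cue_onset))
  if (nrow(presses) > 0 && length(cued) > 0) {
    in_cue <- vapply(presses$timestamp, function(ts)
      any(ts >= s$cue_onset[cued] & ts < s$cue_offset[cued]), logical(1))
    if (any(!in_cue))
      warning(sprintf("%d press event(s) outside any cue window; excluded",
                      sum(!in_cue)))
    presses <- presses[in_cue, ]
  }
  pokes <- events[events$code == "FC_ENTRY", ]

  out <- lapply(seq_len(nrow(s)), function(i) {
    if (is.na(s$cue_onset[i]))
      return(tibble::tibble(trial = s$trial[i],
                            trial_type = s$trial_type[i],
                            presses = NA_integer_, pokes = NA_integer_,
                            press_latency = NA_real_,
                            poke_latency = NA_real_))
    on <- s$cue_onset[i]; off <- s$cue_offset[i]
    code <- if (s$trial_type[i] == "CS_MINUS") "PRESS_M" else "PRESS_P"
    pr <- presses$timestamp[presses$code == code &
                              presses$timestamp >= on &
                              presses$timestamp < off]
    pk <- pokes$timestamp[pokes$timestamp >= on & pokes$timestamp < off]
    tibble::tibble(
      trial = s$trial[i], trial_type = s$trial_type[i],
      presses = length(pr), pokes = length(pk),
      press_latency = if (length(pr)) min(pr) - on else cue_dur,
      poke_latency = if (length(pk)) min(pk) - on else cue_dur)
  })
  dplyr::bind_rows(out)
}

ratio_or_zero <- function(num, den) if (den == 0) 0 else num / den

#' Pavlovian conditioned approach (PCA) score
#'
#' Composite index of lever- versus food-cup-directed behaviour on CS+
#' trials, in `[-1, 1]` (+1 = pure sign-tracking, -1 = pure goal-tracking).
#' The score is the mean of three components:
#' response bias `(presses - pokes) / (presses + pokes)` (session totals),
#' probability difference `P(press) - P(poke)` (fraction of CS+ trials with
#' at least one response of each kind), and latency score
#' `(poke_latency - press_latency) / cue_dur` using session-mean
#' first-response latencies. Components with undefined denominators
#' contribute 0.
#'
#' @param trial_scores Per-trial tibble from [score_trials()].
#' @param cue_dur Cue duration in seconds (default 10).
#' @param cs_plus_types Trial types counted as CS+ (default `"CS_PLUS"`).
#' @return List with `pca_score` and the three components.
#' @export
pca_score <- function(trial_scores, cue_dur = 10,
                      cs_plus_types = "CS_PLUS") {
  tr <- trial_scores[trial_scores$trial_type %in% cs_plus_types, ]
  if (nrow(tr) == 0)
    stop_config("no CS+ trials; PCA score undefined")
  response_bias <- ratio_or_zero(sum(tr$presses) - sum(tr$pokes),
                                 sum(tr$presses) + sum(tr$pokes))
  probability_difference <- mean(tr$presses > 0) - mean(tr$pokes > 0)
  latency_score <- (mean(tr$poke_latency) - mean(tr$press_latency)) / cue_dur
  list(pca_score = mean(c(response_bias, probability_difference,
                          latency_score)),
       response_bias = response_bias,
       probability_difference = probability_difference,
       latency_score = latency_score)
}

#' Classify tracking phenotype
#'
#' Sign-tracker (`"ST"`) if the mean of the day-4 and day-5 PCA scores is
#' at least 0.5, otherwise goal-tracker/intermediate (`"GT_INT"`).
#'
#' @param day4_score,day5_score PCA scores in `[-1, 1]`.
#' @return `"ST"` or `"GT_INT"`.
#' @examples
#' classify_tracking(0.6, 0.4)   # "ST"
#' classify_tracking(0.5, 0.49)  # "GT_INT"
#' @export
classify_tracking <- function(day4_score, day5_score) {
  stopifnot(abs(day4_score) <= 1, abs(day5_score) <= 1)
  if (mean(c(day4_score, day5_score)) >= 0.5) "ST" else "GT_INT"
}

#' CS+/CS- response discrimination
#'
#' Difference between mean per-trial CS+ and CS- response counts, for
#' presses and pokes separately.
#'
#' @param trial_scores Per-trial tibble from [score_trials()].
#' @return List with `delta_presses` and `delta_pokes`.
#' @export
delta_responses <- function(trial_scores) {
  plus <- trial_scores[trial_scores$trial_type == "CS_PLUS", ]
  minus <- trial_scores[trial_scores$trial_type == "CS_MINUS", ]
  if (nrow(plus) == 0 || nrow(minus) == 0)
    stop_config("need both CS+ and CS- trials for delta responses")
  list(delta_presses = mean(plus$presses) - mean(minus$presses),
       delta_pokes = mean(plus$pokes) - mean(minus$pokes))
}

#' Pre-trial food-cup checking rate
#'
#' For every trial after the first, counts food-cup entries in the
#' `window` seconds preceding that trial's cue onset (or reward time for
#' unsignalled-reward trials), grouped by the *preceding* trial's type.
#' Used on RPE probe sessions to ask whether reward omission changes
#' anticipatory checking.
#'
#' @param events Event-log tibble.
#' @param schedule The session's [trial_schedule].
#' @param window Look-back window, seconds (default 10).
#' @return Tibble with `prev_type`, `rate` (entries per window) and `n`
#'   (trials contributing).
#' @export
pretrial_check_rate <- function(events, schedule, window = 10) {
  s <- schedule
  if (nrow(s) < 2) stop_config("need at least 2 trials")
  entries <- events$timestamp[events$code == "FC_ENTRY"]
  anchors <- ifelse(is.na(s$cue_onset), s$reward_1, s$cue_onset)
  rows <- lapply(2:nrow(s), function(i) {
    cnt <- sum(entries >= anchors[i] - window & entries < anchors[i])
    tibble::tibble(prev_type = s$trial_type[i - 1], count = cnt)
  })
  tab <- dplyr::bind_rows(rows)
  dplyr::summarise(dplyr::group_by(tab, .data$prev_type),
                   rate = mean(.data$count), n = dplyr::n(),
                   .groups = "drop")
}

#' Per-session behaviour summary
#'
#' One-row tidy summary combining [score_trials()], [pca_score()] and
#' [delta_responses()], suitable for binding across rats/sessions and
#' feeding to external ANOVA software.
#'
#' @param events Event-log tibble.
#' @param schedule The session's [trial_schedule].
#' @param cue_dur Cue duration, seconds.
#' @return One-row tibble of session-level behavioural measures.
#' @export
behavior_summary <- function(events, schedule, cue_dur = 10) {
  tr <- score_trials(events, schedule)
  pca <- pca_score(tr, cue_dur = cue_dur)
  has_both <- all(c("CS_PLUS", "CS_MINUS") %in% tr$trial_type)
  deltas <- if (has_both) delta_responses(tr) else
    list(delta_presses = NA_real_, delta_pokes = NA_real_)
  plus <- tr[tr$trial_type == "CS_PLUS", ]
  tibble::tibble(
    n_trials = nrow(tr),
    cs_plus_presses = mean(plus$presses),
    cs_plus_pokes = mean(plus$pokes),
    p_press = mean(plus$presses > 0),
    p_poke = mean(plus$pokes > 0),
    response_bias = pca$response_bias,
    probability_difference = pca$probability_difference,
    latency_score = pca$latency_score,
    pca_score = pca$pca_score,
    delta_presses = deltas$delta_presses,
    delta_pokes = deltas$delta_pokes)
}
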