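#' Event-aligned, baseline z-scored epochs
#'
#' Cuts the corrected dF/F trace into trial epochs aligned to cue onset or
#' reward delivery and z-scores each trial against its own pre-event
#' baseline: `z = (dff - baseline_mean) / baseline_sd` with statistics
#' taken over `baseline_window` (default the 5 s before the event). For
#' reward alignment, `NEGATIVE` (omission) trials align to the scheduled
#' omitted delivery (lever retraction) and `POSITIVE` (unsignalled) trials
#' to the delivery itself, their baseline being the 5 s preceding it.
#'
#' @param trace A `corrected_trace` from [correct_photometry()].
#' @param schedule The session's [trial_schedule].
#' @param align_event `"cue_onset"` or `"reward"`.
#' @param window Epoch span relative to the event, seconds
#'   (default `c(-5, 20)`).
#' @param baseline_window Baseline span, seconds (default `c(-5, 0)`,
#'   half-open on the right).
#' @param types Optional trial-type filter.
#' @param exclude_trials Trial indices to drop (e.g. disconnect overlaps
#'   from [correct_photometry()]).
#' @return An `epoch_matrix`: list with `z` (trials x samples), `rel_time`,
#'   `trial`, `trial_type`, `align_event`, `baseline_window` and an
#'   `excluded` tibble recording dropped trials and reasons.
#' @export
epoch_and_zscore <- function(trace, schedule,
                             align_event = c("cue_onset", "reward"),
                             window = c(-5, 20),
                             baseline_window = c(-5, 0),
                             types = NULL, exclude_trials = integer()) {
  stopifnot(inherits(trace, "corrected_trace"))
  align_event <- match.arg(align_event)
  if (baseline_window[1] < window[1] || baseline_window[2] > window[2])
    stop_config("baseline_window must lie inside the epoch window")
  s <- schedule
  if (!is.null(types)) s <- s[s$trial_type %in% types, ]

  anchors <- if (align_event == "cue_onset") s$cue_onset else
    ifelse(is.na(s$reward_1), s$cue_offset, s$reward_1)
  fs <- trace$rate
  offsets <- round(window[1] * fs):round(window[2] * fs)
  rel_time <- offsets / fs
  bl_cols <- rel_time >= baseline_window[1] - 1e-9 &
    rel_time < baseline_window[2] - 1e-9

  keep_rows <- list()
  excluded <- tibble::tibble(trial = integer(), reason = character())
  note_excl <- function(tr, why)
    dplyr::bind_rows(excluded, tibble::tibble(trial = tr, reason = why))

  for (i in seq_len(nrow(s))) {
    tr_id <- s$trial[i]
    if (tr_id %in% exclude_trials) {
      excluded <- note_excl(tr_id, "disconnect"); next
    }
    if (is.na(anchors[i])) {
      excluded <- note_excl(tr_id, "no alignment event"); next
    }
    i0 <- round((anchors[i] - trace$time[1]) * fs) + 1L
    idx <- i0 + offsets
    if (idx[1] < 1L || idx[length(idx)] > length(trace$dff)) {
      excluded <- note_excl(tr_id, "window outside record"); next
    }
    seg <- trace$dff[idx]
    bl <- seg[bl_cols]
    mu <- mean(bl, na.rm = TRUE)
    sdv <- sd(bl, na.rm = TRUE)
    if (!is.finite(sdv) || sdv == 0) {
      # an exactly-constant segment carries zero deviation and maps to z = 0;
      # a flat baseline under a varying segment is unnormalisable
      if (is.finite(mu) && all(abs(seg - mu) < 1e-15, na.rm = TRUE)) {
        keep_rows[[length(keep_rows) + 1L]] <-
          list(trial = tr_id, type = s$trial_type[i], z = seg * 0)
        next
      }
      excluded <- note_excl(tr_id, "degenerate baseline"); next
    }
    keep_rows[[length(keep_rows) + 1L]] <-
      list(trial = tr_id, type = s$trial_type[i], z = (seg - mu) / sdv)
  }
  if (length(keep_rows) == 0)
    stop_config("no usable trials after exclusion")
  z <- do.call(rbind, lapply(keep_rows, `[[`, "z"))
  structure(list(
    z = z, rel_time = rel_time,
    trial = vapply(keep_rows, `[[`, integer(1), "trial"),
    trial_type = vapply(keep_rows, `[[`, character(1), "type"),
    align_event = align_event, baseline_window = baseline_window,
    excluded = excluded), class = "epoch_matrix")
}

#' @export
print.epoch_matrix <- function(x, ...) {
  cat(sprintf(
    "<epoch_matrix> %d trials x %d samples, aligned to %s [%g, %g] s\n",
    nrow(x$z), ncol(x$z), x$align_event, min(x$rel_time), max(x$rel_time)))
  invisible(x)
}

#' Area under the z-scored trace
#'
#' Trapezoidal integral of each trial's z-scored trace over a window of
#' relative time, in z-score-seconds.
#'
#' @param epoch An `epoch_matrix`.
#' @param window Length-2 integration window in epoch-relative seconds.
#' @return Tibble with `trial`, `trial_type` and `auc`.
#' @export
epoch_auc <- function(epoch, window) {
  stopifnot(inherits(epoch, "epoch_matrix"))
  cols <- epoch$rel_time >= window[1] - 1e-9 &
    epoch$rel_time <= window[2] + 1e-9
  if (sum(cols) < 2) stop_config("AUC window contains fewer than 2 samples")
  tt <- epoch$rel_time[cols]
  tibble::tibble(
    trial = epoch$trial, trial_type = epoch$trial_type,
    auc = apply(epoch$z[, cols, drop = FALSE], 1,
                function(zz) pracma::trapz(tt, zz)))
}

#' Session difference metrics
#'
#' The three cue/reward contrasts reported per session:
#' * `delta_lever_extension_auc` — mean CS+ minus mean CS- AUC in the 2 s
#'   after cue onset;
#' * `delta_cue_period_auc` — same contrast over the full 10 s cue;
#' * `delta_cue_reward_auc` — mean CS+ cue-onset AUC minus mean reward
#'   (US) delivery AUC, each over 2 s. Positive values mean the cue
#'   response dominates the reward response (US-to-CS transfer).
#'
#' @param csplus,csminus Cue-onset-aligned `epoch_matrix` objects for CS+
#'   and CS- trials of one session.
#' @param reward Reward-delivery-aligned `epoch_matrix` for the same
#'   session's reinforced trials.
#' @param cue_dur Cue duration, seconds (default 10).
#' @return One-row tibble with the three delta metrics.
#' @export
difference_metrics <- function(csplus, csminus, reward, cue_dur = 10) {
  for (nm in c("csplus", "csminus", "reward")) {
    e <- get(nm)
    if (!inherits(e, "epoch_matrix") || nrow(e$z) == 0)
      stop_config("epoch matrix `%s` is empty", nm)
  }
  tibble::tibble(
    delta_lever_extension_auc =
      mean(epoch_auc(csplus, c(0, 2))$auc) -
      mean(epoch_auc(csminus, c(0, 2))$auc),
    delta_cue_period_auc =
      mean(epoch_auc(csplus, c(0, cue_dur))$auc) -
      mean(epoch_auc(csminus, c(0, cue_dur))$auc),
    delta_cue_reward_auc =
      mean(epoch_auc(csplus, c(0, 2))$auc) -
      mean(epoch_auc(reward, c(0, 2))$auc))
}

#' Binned post-event z-score means
#'
#' Mean z within consecutive bins after the alignment event (default three
#' 2-s bins covering 0-6 s post reward delivery/omission), per trial.
#' Bins are half-open `[lo, hi)`.
#'
#' @param epoch An `epoch_matrix` (reward/omission aligned for the RPE
#'   analysis).
#' @param bin_width Bin width, seconds (default 2).
#' @param n_bins Number of bins (default 3).
#' @param start Start of the first bin in relative seconds (default 0).
#' @return Tibble with `trial`, `trial_type`, `bin`, `t_lo`, `t_hi`,
#'   `mean_z`.
#' @export
binned_means <- function(epoch, bin_width = 2, n_bins = 3, start = 0) {
  stopifnot(inherits(epoch, "epoch_matrix"))
  if (max(epoch$rel_time) < start + bin_width * n_bins - 1e-9)
    stop_config("epoch does not cover the requested bins")
  rows <- lapply(seq_len(n_bins), function(b) {
    lo <- start + (b - 1) * bin_width
    hi <- lo + bin_width
    cols <- epoch$rel_time >= lo - 1e-9 & epoch$rel_time < hi - 1e-9
    tibble::tibble(
      trial = epoch$trial, trial_type = epoch$trial_type,
      bin = b, t_lo = lo, t_hi = hi,
      mean_z = rowMeans(epoch$z[, cols, drop = FALSE], na.rm = TRUE))
  })
  dplyr::bind_rows(rows)
}

#' Correlation between behavioural scores and signal metrics
#'
#' Ordinary least-squares fit of a per-rat signal metric (e.g. the
#' lever-extension delta AUC) on per-rat PCA scores, as used to relate
#' cue-evoked dopamine signals to the degree of sign-tracking.
#'
#' @param scores Numeric vector of per-rat PCA scores.
#' @param metrics Numeric vector of per-rat signal metrics, same length.
#' @return List with `r_squared`, `slope`, `intercept`, `p_value`
#'   (two-sided slope test) and `n`.
#' @export
score_signal_correlation <- function(scores, metrics) {
  ok <- is.finite(scores) & is.finite(metrics)
  scores <- scores[ok]; metrics <- metrics[ok]
  if (length(scores) < 3)
    stop_config("need at least 3 rats for the score-signal correlation")
  fit <- lm(metrics ~ scores)
  sm <- summary(fit)
  list(r_squared = sm$r.squared,
       slope = coef(fit)[["scores"]],
       intercept = coef(fit)[["(Intercept)"]],
       p_value = sm$coefficients["scores", "Pr(>|t|)"],
       n = length(scores))
}
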