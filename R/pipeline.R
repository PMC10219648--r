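#' End-to-end signal metrics for one PLA session
#'
#' Runs the full signal pipeline on a raw stream: isosbestic correction,
#' disconnect-based trial exclusion, cue- and reward-aligned epoching, and
#' the session difference metrics.
#'
#' @param raw A [raw_photometry()].
#' @param schedule The session's [trial_schedule] (PLA-style, with CS+ and
#'   CS- trials).
#' @param window Isosbestic smoothing window, seconds.
#' @param epoch_window Epoch span, seconds.
#' @param cue_dur Cue duration, seconds.
#' @return List: `trace`, `cs_plus`, `cs_minus`, `reward` (epoch
#'   matrices), `metrics` (from [difference_metrics()]) and
#'   `excluded_trials`.
#' @export
analyze_pla_session <- function(raw, schedule, window = 1,
                                epoch_window = c(-5, 20), cue_dur = 10) {
  corr <- correct_photometry(raw, schedule, window = window,
                             trial_window = epoch_window)
  excl <- corr$excluded_trials
  csp <- epoch_and_zscore(corr$trace, schedule, "cue_onset",
                          window = epoch_window, types = "CS_PLUS",
                          exclude_trials = excl)
  csm <- epoch_and_zscore(corr$trace, schedule, "cue_onset",
                          window = epoch_window, types = "CS_MINUS",
                          exclude_trials = excl)
  rew <- epoch_and_zscore(corr$trace, schedule, "reward",
                          window = epoch_window, types = "CS_PLUS",
                          exclude_trials = excl)
  list(trace = corr$trace, cs_plus = csp, cs_minus = csm, reward = rew,
       metrics = difference_metrics(csp, csm, rew, cue_dur = cue_dur),
       excluded_trials = excl)
}

#' Binned RPE summary for one probe session
#'
#' Corrects the stream, aligns every trial to reward delivery or omission,
#' and returns per-trial binned z-means plus the per-type bin averages used
#' to read out prediction-error signalling.
#'
#' @inheritParams analyze_pla_session
#' @param n_bins,bin_width Binning of the post-event period (defaults:
#'   three 2-s bins, 0-6 s).
#' @return List: `bins` (per-trial tibble), `by_type` (trial-type x bin
#'   means) and `epoch`.
#' @export
analyze_rpe_session <- function(raw, schedule, window = 1,
                                epoch_window = c(-5, 20),
                                bin_width = 2, n_bins = 3) {
  corr <- correct_photometry(raw, schedule, window = window,
                             trial_window = epoch_window)
  ep <- epoch_and_zscore(corr$trace, schedule, "reward",
                         window = epoch_window,
                         exclude_trials = corr$excluded_trials)
  bins <- binned_means(ep, bin_width = bin_width, n_bins = n_bins)
  by_type <- dplyr::summarise(
    dplyr::group_by(bins, .data$trial_type, .data$bin),
    mean_z = mean(.data$mean_z), .groups = "drop")
  list(bins = bins, by_type = by_type, epoch = ep)
}
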