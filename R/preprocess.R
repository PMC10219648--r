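#' Smooth the isosbestic channel
#'
#' Zero-phase moving average of the isosbestic control channel, with
#' reflected endpoints so the smoother preserves constants and slow drift
#' right up to the record edges. Smoothing the motion/bleaching reference
#' before regression keeps channel noise out of the fitted reference
#' without distorting the sub-1 Hz structure the correction targets.
#'
#' @param raw A [raw_photometry()].
#' @param window Window length in seconds (default 1); must span at least
#'   2 samples and no more than the record.
#' @return Numeric vector, the smoothed isosbestic channel.
#' @export
smooth_isosbestic <- function(raw, window = 1) {
  stopifnot(inherits(raw, "raw_photometry"))
  n_win <- max(2L, round(window * raw$rate))
  n <- length(raw$iso)
  if (n_win > n)
    stop_config("smoothing window (%d samples) exceeds record length %d",
                n_win, n)
  half <- n_win %/% 2
  padded <- c(rev(raw$iso[seq_len(half)]), raw$iso,
              rev(raw$iso[(n - half + 1):n]))
  sm <- stats::filter(padded, rep(1 / n_win, n_win), sides = 2)
  as.numeric(sm[(half + 1):(half + n)])
}

#' Regress the smoothed isosbestic onto the signal channel
#'
#' Ordinary least squares of the dopamine-sensitive channel on the smoothed
#' isosbestic reference. Because photobleaching and motion scale both
#' channels multiplicatively, the fitted values
#' `slope * iso + intercept` reconstruct what the signal channel would look
#' like with no dopamine transients.
#'
#' @param sig Signal-channel vector.
#' @param smoothed_iso Smoothed isosbestic vector (same length).
#' @param exclude Optional logical mask of samples (e.g. disconnects) to
#'   drop from the fit; fitted values are still produced everywhere.
#' @return List with `slope`, `intercept` and `fitted`.
#' @export
fit_reference <- function(sig, smoothed_iso, exclude = NULL) {
  if (length(sig) != length(smoothed_iso))
    stop_config("sig and smoothed_iso must have equal length")
  keep <- if (is.null(exclude)) rep(TRUE, length(sig)) else !exclude
  x <- smoothed_iso[keep]
  y <- sig[keep]
  if (length(x) < 3 || var(x) <= 0)
    stop_config("isosbestic channel has zero variance; cannot fit reference")
  slope <- stats::cov(x, y) / var(x)
  intercept <- mean(y) - slope * mean(x)
  list(slope = slope, intercept = intercept,
       fitted = slope * smoothed_iso + intercept)
}

#' Compute dF/F from the fitted reference
#'
#' `dff = (sig - fitted) / fitted`, the fractional fluorescence change
#' relative to the motion/bleaching reference. Samples flagged in the
#' disconnect mask become `NA`.
#'
#' @param raw A [raw_photometry()].
#' @param fit Output of [fit_reference()].
#' @param smoothing_window Window (s) used for the reference, recorded in
#'   the result.
#' @return A `corrected_trace` list: `time`, `dff`, `rate`, `fit_slope`,
#'   `fit_intercept`, `smoothing_window`, `disconnect_mask`.
#' @export
compute_dff <- function(raw, fit, smoothing_window = NA_real_) {
  stopifnot(inherits(raw, "raw_photometry"))
  keep <- !raw$disconnect_mask
  bad <- sum(fit$fitted[keep] <= 0)
  if (bad > 0.01 * sum(keep))
    stop_config(
      "fitted reference non-positive on %.1f%% of samples; data unusable",
      100 * bad / sum(keep))
  dff <- (raw$sig - fit$fitted) / fit$fitted
  dff[!keep] <- NA_real_
  structure(list(time = raw$time, dff = dff, rate = raw$rate,
                 fit_slope = fit$slope, fit_intercept = fit$intercept,
                 smoothing_window = smoothing_window,
                 disconnect_mask = raw$disconnect_mask),
            class = "corrected_trace")
}

#' @export
print.corrected_trace <- function(x, ...) {
  cat(sprintf(
    "<corrected_trace> %d samples @ %g Hz; fit slope %.4f, intercept %.3f\n",
    length(x$time), x$rate, x$fit_slope, x$fit_intercept))
  invisible(x)
}

#' Detect patch-cord disconnects
#'
#' Flags samples where both channels fall below a floor (a fraction of each
#' channel's session median) for at least a minimum duration — the
#' signature of the patch cord coming off — and, when a schedule is given,
#' lists the trials whose analysis window overlaps a masked run.
#'
#' @param raw A [raw_photometry()].
#' @param schedule Optional [trial_schedule] for trial exclusion.
#' @param floor_frac Floor as a fraction of the per-channel median
#'   (default 0.05).
#' @param min_dur Minimum run duration in seconds (default 0.1).
#' @param trial_window Analysis window (s) around each trial's alignment
#'   event used for the overlap test, default `c(-5, 20)`.
#' @return List with `raw` (mask updated), `runs` (tibble of masked
#'   intervals) and `excluded_trials` (integer vector, empty without a
#'   schedule).
#' @export
detect_disconnects <- function(raw, schedule = NULL, floor_frac = 0.05,
                               min_dur = 0.1, trial_window = c(-5, 20)) {
  stopifnot(inherits(raw, "raw_photometry"))
  floor_sig <- floor_frac * median(raw$sig)
  floor_iso <- floor_frac * median(raw$iso)
  below <- raw$sig < floor_sig & raw$iso < floor_iso
  min_len <- max(1L, round(min_dur * raw$rate))
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep_run <- r$values & r$lengths >= min_len
  mask <- rep(FALSE, length(below))
  runs <- tibble::tibble(start = numeric(), end = numeric())
  for (j in which(keep_run)) {
    mask[starts[j]:ends[j]] <- TRUE
    runs <- dplyr::bind_rows(runs, tibble::tibble(
      start = raw$time[starts[j]], end = raw$time[ends[j]]))
  }
  raw$disconnect_mask <- raw$disconnect_mask | mask

  excluded <- integer()
  if (!is.null(schedule) && nrow(runs) > 0) {
    anchors <- ifelse(is.na(schedule$cue_onset), schedule$reward_1,
                      schedule$cue_onset)
    for (i in seq_along(anchors)) {
      lo <- anchors[i] + trial_window[1]
      hi <- anchors[i] + trial_window[2]
      if (any(runs$start <= hi & runs$end >= lo))
        excluded <- c(excluded, schedule$trial[i])
    }
    if (length(excluded))
      message(sprintf("disconnects: excluding trial(s) %s",
                      paste(excluded, collapse = ", ")))
  }
  list(raw = raw, runs = runs, excluded_trials = excluded)
}

#' Full isosbestic correction pipeline
#'
#' Runs disconnect detection, isosbestic smoothing, reference regression
#' and dF/F computation in the standard order.
#'
#' @inheritParams detect_disconnects
#' @param window Isosbestic smoothing window, seconds.
#' @return List with `trace` (a `corrected_trace`), `excluded_trials`, and
#'   `qc` (fit coefficients and disconnect runs).
#' @export
correct_photometry <- function(raw, schedule = NULL, window = 1,
                               floor_frac = 0.05, min_dur = 0.1,
                               trial_window = c(-5, 20)) {
  dd <- detect_disconnects(raw, schedule, floor_frac, min_dur, trial_window)
  raw <- dd$raw
  sm <- smooth_isosbestic(raw, window)
  fit <- fit_reference(raw$sig, sm, exclude = raw$disconnect_mask)
  trace <- compute_dff(raw, fit, smoothing_window = window)
  list(trace = trace, excluded_trials = dd$excluded_trials,
       qc = list(fit_slope = fit$slope, fit_intercept = fit$intercept,
                 disconnect_runs = dd$runs))
}
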