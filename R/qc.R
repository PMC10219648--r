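#' Peak-amplitude inclusion test
#'
#' A rat's session passes if its trial-averaged, baseline-z-scored trace
#' reaches at least `threshold_z` (default 2, the one-sided p = 0.05 point
#' of the baseline distribution) anywhere in the trial window (default
#' 0 to +20 s from cue onset).
#'
#' @param epoch An `epoch_matrix` of the rat's trials.
#' @param window Search window in relative seconds, default `c(0, 20)`.
#' @param threshold_z Peak criterion in baseline SD units, default 2.
#' @return Logical; attribute `"peak_z"` carries the observed peak.
#' @export
peak_inclusion <- function(epoch, window = c(0, 20), threshold_z = 2) {
  stopifnot(inherits(epoch, "epoch_matrix"))
  cols <- epoch$rel_time >= window[1] - 1e-9 &
    epoch$rel_time <= window[2] + 1e-9
  avg <- colMeans(epoch$z[, cols, drop = FALSE], na.rm = TRUE)
  peak <- max(avg)
  structure(peak >= threshold_z, peak_z = peak)
}

#' Bootstrap confidence band of the trial-averaged trace
#'
#' Resamples trials with replacement `n_resamples` times; each resample's
#' trial-mean trace contributes to a pointwise percentile confidence band
#' at level `level`. A timepoint is "significantly above baseline" when the
#' lower band exceeds zero (traces are baseline-z-scored, so baseline mean
#' is zero by construction). Reports the onset latency (first post-onset
#' time with `ci_low > 0`) and the longest consecutive significant run.
#'
#' @param epoch An `epoch_matrix`; needs at least 5 trials.
#' @param n_resamples Number of bootstrap resamples, default 1000.
#' @param level Confidence level, default 0.95.
#' @param seed Integer seed; identical `(epoch, seed)` give identical
#'   results.
#' @return A `bootstrap_result`: `mean_trace`, `ci_low`, `ci_high`,
#'   `rel_time`, `onset_latency` (s, `NA` if never significant),
#'   `max_consecutive_sig` (s), `n_resamples`, `level`, `seed`.
#' @export
bootstrap_trace_ci <- function(epoch, n_resamples = 1000, level = 0.95,
                               seed = 1L) {
  stopifnot(inherits(epoch, "epoch_matrix"))
  z <- epoch$z
  complete <- !apply(z, 1, anyNA)
  if (any(!complete)) {
    warning(sprintf("dropping %d trial(s) with missing samples",
                    sum(!complete)))
    z <- z[complete, , drop = FALSE]
  }
  n <- nrow(z)
  if (n < 5)
    stop_config("bootstrap CI needs >= 5 trials, got %d", n)
  alpha <- (1 - level) / 2
  with_seed(seed, {
    idx <- matrix(sample.int(n, n * n_resamples, replace = TRUE),
                  nrow = n_resamples)
    # weight matrix: resamples x trials, counts / n
    w <- matrix(0, n_resamples, n)
    for (r in seq_len(n_resamples))
      w[r, ] <- tabulate(idx[r, ], nbins = n)
    boot_means <- (w %*% z) / n
    ci <- apply(boot_means, 2, quantile, probs = c(alpha, 1 - alpha),
                names = FALSE, type = 7)
    rel <- epoch$rel_time
    dt <- 1 / round(1 / mean(diff(rel)))
    post <- rel >= 0
    sig_post <- ci[1, ] > 0 & post
    onset <- if (any(sig_post)) rel[which(sig_post)[1]] else NA_real_
    max_run <- longest_true_run(ci[1, post] > 0) * dt
    structure(list(
      mean_trace = colMeans(z), ci_low = ci[1, ], ci_high = ci[2, ],
      rel_time = rel, onset_latency = onset,
      max_consecutive_sig = max_run, n_resamples = n_resamples,
      level = level, n_trials = n, seed = as.integer(seed)),
      class = "bootstrap_result")
  })
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf(
    paste0("<bootstrap_result> %d trials, %d resamples, %.0f%% CI; ",
           "onset %s, longest significant run %.3f s\n"),
    x$n_trials, x$n_resamples, 100 * x$level,
    if (is.na(x$onset_latency)) "none" else
      sprintf("%.3f s", x$onset_latency),
    x$max_consecutive_sig))
  invisible(x)
}

#' Combined inclusion decision
#'
#' A rat's signal is included when it meets **both** criteria: the 2z peak
#' test and a consecutive significant run of at least `min_consecutive`
#' (default 40 ms) in the bootstrap band. The onset latency is reported but
#' is not itself a gate.
#'
#' @param peak Logical from [peak_inclusion()].
#' @param boot A `bootstrap_result` from [bootstrap_trace_ci()] for the
#'   same rat/session.
#' @param min_consecutive Minimum consecutive significant time, seconds
#'   (default 0.04).
#' @return List (`qc_report`): `included`, `peak_pass`, `peak_z`,
#'   `onset_latency_s`, `max_consecutive_sig_s`, `n_resamples`, `seed`.
#' @export
inclusion_decision <- function(peak, boot, min_consecutive = 0.04) {
  stopifnot(inherits(boot, "bootstrap_result"))
  structure(list(
    included = isTRUE(as.logical(peak)) &&
      boot$max_consecutive_sig >= min_consecutive,
    peak_pass = isTRUE(as.logical(peak)),
    peak_z = attr(peak, "peak_z"),
    onset_latency_s = boot$onset_latency,
    max_consecutive_sig_s = boot$max_consecutive_sig,
    n_resamples = boot$n_resamples,
    seed = boot$seed), class = "qc_report")
}

#' Write a QC report as JSON
#'
#' @param report A `qc_report` from [inclusion_decision()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}
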