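#' Raw photometry container
#'
#' A `raw_photometry` object holds the demodulated two-channel stream:
#' `time` (s), `sig` (dopamine-sensitive channel, a.u.), `iso` (isosbestic
#' channel, a.u.), `rate` (Hz) and a per-sample logical `disconnect_mask`
#' (all `FALSE` until [detect_disconnects()] is run).
#'
#' @param time,sig,iso Equal-length numeric vectors.
#' @param rate Sampling rate in Hz; must match the time spacing.
#' @param disconnect_mask Optional logical vector.
#' @return A `raw_photometry` list.
#' @export
raw_photometry <- function(time, sig, iso, rate,
                           disconnect_mask = rep(FALSE, length(time))) {
  n <- length(time)
  if (length(sig) != n || length(iso) != n || length(disconnect_mask) != n)
    stop_config("time, sig, iso and disconnect_mask must have equal length")
  if (n > 1) {
    dt <- diff(time)
    if (any(abs(dt - 1 / rate) > (1 / rate) * 1e-6))
      stop_config("time spacing inconsistent with rate %g Hz", rate)
  }
  structure(list(time = time, sig = sig, iso = iso, rate = rate,
                 disconnect_mask = disconnect_mask),
            class = "raw_photometry")
}

#' @export
print.raw_photometry <- function(x, ...) {
  cat(sprintf("<raw_photometry> %d samples @ %g Hz (%.1f s), %d masked\n",
              length(x$time), x$rate, length(x$time) / x$rate,
              sum(x$disconnect_mask)))
  invisible(x)
}

# difference-of-exponentials kernel, peak-normalised to 1
transient_kernel <- function(t, tau_rise, tau_decay) {
  tpk <- tau_rise * tau_decay / (tau_decay - tau_rise) *
    log(tau_decay / tau_rise)
  peak <- exp(-tpk / tau_decay) - exp(-tpk / tau_rise)
  ifelse(t < 0, 0, (exp(-t / tau_decay) - exp(-t / tau_rise)) / peak)
}

add_transients <- function(train, time, events, tau_rise, tau_decay, rate) {
  span <- tau_decay * 10
  for (j in seq_len(nrow(events))) {
    t0 <- events$time[j]
    i0 <- max(1L, floor((t0 - time[1]) * rate) + 1L)
    i1 <- min(length(time), ceiling((t0 + span - time[1]) * rate) + 1L)
    if (i1 < i0) next
    idx <- i0:i1
    train[idx] <- train[idx] +
      events$amplitude[j] * transient_kernel(time[idx] - t0,
                                             tau_rise, tau_decay)
  }
  train
}

#' Simulate a dual-channel photometry stream
#'
#' Emits demodulated signal and isosbestic streams for one session:
#' `sig = bleach(t) * (1 + artifact(t)) * f0 * (1 + T(t)) + noise`,
#' `iso = bleach(t) * (1 + artifact(t)) * f0_iso + noise`, where `T(t)` is
#' the dopamine transient train (cue-onset and reward transients plus the
#' spontaneous background). Photobleaching and motion artifacts are shared
#' multiplicatively between channels, which is the structure the isosbestic
#' regression in [correct_photometry()] exploits; transients appear only in
#' the signal channel.
#'
#' RPE trial types use the bump/dip amplitudes: `POSITIVE` deliveries get a
#' fast transient of amplitude `rpe_positive_bump` plus a slow copy delayed
#' by `rpe_delay`, and `NEGATIVE` omissions get a slow dip of amplitude
#' `rpe_negative_dip` at the scheduled (omitted) delivery time. Both slow
#' components peak 2-3 s after the event.
#'
#' @param schedule A [trial_schedule].
#' @param events Event log from [simulate_behavior()] (recorded alongside
#'   the stream; transient timing is taken from the schedule).
#' @param config A [sim_config()].
#' @param pad Seconds of stream padded before the first and after the last
#'   scheduled event.
#' @return A list with elements `raw` (a [raw_photometry()]) and `truth`
#'   (ground truth: transient table, artifact and bleach time courses,
#'   disconnect intervals and per-trial behavioural rates).
#' @export
simulate_photometry <- function(schedule, events, config, pad = 25) {
  stopifnot(inherits(schedule, "trial_schedule"),
            inherits(config, "sim_config"))
  fs <- config$sampling_rate
  if (fs < 4 / config$tau_rise)
    stop_config(paste0("sampling_rate %g Hz too low to resolve the kernel ",
                       "rise (need >= %g Hz)"), fs, 4 / config$tau_rise)
  s <- schedule
  span <- max(c(s$cue_offset, s$reward_2, s$reward_1), na.rm = TRUE) + pad
  n <- floor(span * fs) + 1L
  time <- (seq_len(n) - 1L) / fs

  with_seed(config$seed + 1L, {
    jitter_amp <- function(a, k) a * pmax(0, 1 + config$amplitude_cv *
                                            rnorm(k))
    amp <- config$amplitudes
    ev <- list()
    push <- function(t0, a, kind, trial, slow = FALSE) {
      if (length(t0) > 0 && any(a != 0))
        ev[[length(ev) + 1L]] <<- tibble::tibble(
          time = t0, amplitude = a, kind = kind, trial = trial, slow = slow)
    }
    for (i in seq_len(nrow(s))) {
      ty <- s$trial_type[i]
      if (!is.na(s$cue_onset[i])) {
        a <- switch(ty, CS_MINUS = amp$cs_minus_onset, amp$cs_plus_onset)
        push(s$cue_onset[i], jitter_amp(a, 1), "cue", i)
      }
      if (!is.na(s$reward_1[i])) {
        if (ty == "POSITIVE") {
          push(s$reward_1[i], jitter_amp(amp$rpe_positive_bump, 1),
               "reward", i)
          push(s$reward_1[i] + config$rpe_delay,
               jitter_amp(amp$rpe_positive_bump, 1), "rpe_bump", i,
               slow = TRUE)
        } else {
          push(s$reward_1[i], jitter_amp(amp$reward, 1), "reward", i)
        }
      }
      if (ty == "NEGATIVE" && amp$rpe_negative_dip != 0) {
        a <- amp$rpe_negative_dip *
          pmax(0, 1 + config$amplitude_cv * rnorm(1))
        push(s$cue_offset[i] + config$rpe_delay, a, "rpe_dip", i,
             slow = TRUE)
      }
    }
    if (amp$spontaneous != 0 && config$spont_rate > 0) {
      k <- rpois(1, config$spont_rate / 60 * span)
      if (k > 0)
        push(sort(runif(k, 0, span)), jitter_amp(amp$spontaneous, k),
             "spontaneous", NA_integer_)
    }
    transients <- if (length(ev)) dplyr::bind_rows(ev) else
      tibble::tibble(time = numeric(), amplitude = numeric(),
                     kind = character(), trial = integer(),
                     slow = logical())

    train <- numeric(n)
    fast <- transients[!transients$slow, , drop = FALSE]
    slow <- transients[transients$slow, , drop = FALSE]
    if (nrow(fast))
      train <- add_transients(train, time, fast,
                              config$tau_rise, config$tau_decay, fs)
    if (nrow(slow))
      train <- add_transients(train, time, slow,
                              config$rpe_tau_rise, config$rpe_tau_decay, fs)

    bp <- config$bleach_params
    bleach <- bp$a1 * exp(-time / bp$tau1) + bp$a2 * exp(-time / bp$tau2) +
      bp$c

    artifact <- numeric(n)
    art_tab <- tibble::tibble(time = numeric(), amplitude = numeric())
    if (config$artifact_rate > 0 && config$artifact_amp > 0) {
      k <- rpois(1, config$artifact_rate / 60 * span)
      if (k > 0) {
        centers <- sort(runif(k, 0, span))
        amps <- config$artifact_amp * runif(k, 0.5, 1.5) *
          sample(c(-1, 1), k, replace = TRUE)
        w <- config$artifact_width
        for (j in seq_len(k)) {
          i0 <- max(1L, floor((centers[j] - 4 * w) * fs) + 1L)
          i1 <- min(n, ceiling((centers[j] + 4 * w) * fs) + 1L)
          idx <- i0:i1
          artifact[idx] <- artifact[idx] +
            amps[j] * exp(-((time[idx] - centers[j])^2) / (2 * w^2))
        }
        art_tab <- tibble::tibble(time = centers, amplitude = amps)
      }
    }

    shared <- bleach * (1 + artifact)
    sig <- shared * config$f0 * (1 + train)
    iso <- shared * config$f0_iso
    if (config$noise_sd[["sig"]] > 0)
      sig <- sig + rnorm(n, sd = config$noise_sd[["sig"]])
    if (config$noise_sd[["iso"]] > 0)
      iso <- iso + rnorm(n, sd = config$noise_sd[["iso"]])

    disconnects <- tibble::tibble(trial = integer(), start = numeric(),
                                  end = numeric())
    if (config$disconnect_prob > 0) {
      for (i in seq_len(nrow(s))) {
        if (runif(1) < config$disconnect_prob) {
          anchor <- if (!is.na(s$cue_onset[i])) s$cue_onset[i] else
            s$reward_1[i]
          dur <- runif(1, 1, 3)
          start <- runif(1, anchor - 5, anchor + 15 - dur)
          idx <- which(time >= start & time < start + dur)
          sig[idx] <- 0
          iso[idx] <- 0
          disconnects <- dplyr::bind_rows(
            disconnects,
            tibble::tibble(trial = i, start = start, end = start + dur))
        }
      }
    }

    truth <- structure(list(
      transients = transients, artifact = artifact, bleach = bleach,
      transient_train = train, disconnects = disconnects,
      behavior_params = config$behavior_params), class = "ground_truth")

    list(raw = raw_photometry(time, sig, iso, fs), truth = truth)
  })
}

#' Simulate a full session (behaviour + photometry)
#'
#' Convenience wrapper running [simulate_behavior()] then
#' [simulate_photometry()] on one schedule.
#'
#' @inheritParams simulate_photometry
#' @return List with `events`, `raw` and `truth`.
#' @export
simulate_session <- function(schedule, config, pad = 25) {
  events <- simulate_behavior(schedule, config)
  phot <- simulate_photometry(schedule, events, config, pad = pad)
  list(events = events, raw = phot$raw, truth = phot$truth)
}
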