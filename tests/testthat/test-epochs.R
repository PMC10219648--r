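# corrected trace with a prescribed dff on a uniform grid
trace_from_dff <- function(dff, rate = 100) {
  structure(list(time = (seq_along(dff) - 1) / rate, dff = dff, rate = rate,
                 fit_slope = 1, fit_intercept = 0, smoothing_window = 1,
                 disconnect_mask = rep(FALSE, length(dff))),
            class = "corrected_trace")
}

test_that("constant traces map to zero z everywhere; shifts change nothing", {
  s <- small_pla(n = 3, seed = 9)
  n <- (max(s$cue_offset) + 30) * 100
  ep0 <- epoch_and_zscore(trace_from_dff(rep(0, n)), s, "cue_onset")
  expect_true(all(ep0$z == 0))
  expect_equal(nrow(ep0$z), 6)
  pavphot:::with_seed(4, {
    dff <- rnorm(n, sd = 0.01)
    epa <- epoch_and_zscore(trace_from_dff(dff), s, "cue_onset")
    epb <- epoch_and_zscore(trace_from_dff(dff + 3.5), s, "cue_onset")
    expect_equal(epa$z, epb$z, tolerance = 1e-10)
  })
})

test_that("a 3-sigma step reads out as z of about 3", {
  s <- small_pla(n = 2, seed = 10)
  n <- (max(s$cue_offset) + 30) * 100
  post_means <- vapply(1:50, function(sd) pavphot:::with_seed(sd, {
    sigma <- 0.01
    dff <- rnorm(n, sd = sigma)
    step <- rep(0, n)
    tvec <- (seq_len(n) - 1) / 100
    for (on in s$cue_onset)
      step[tvec >= on & tvec < on + 6] <- 3 * sigma
    ep <- epoch_and_zscore(trace_from_dff(dff + step), s, "cue_onset")
    mean(ep$z[, ep$rel_time >= 0.5 & ep$rel_time <= 5])
  }), numeric(1))
  expect_lt(abs(mean(post_means) - 3), 0.3)
})

test_that("AUC matches closed-form integrals and is linear/additive", {
  z <- matrix(1, 2, 2501)
  ep <- epoch_from_matrix(z, rate = 100)
  expect_equal(epoch_auc(ep, c(0, 2))$auc, c(2, 2))
  expect_equal(epoch_auc(ep, c(0, 2))$trial_type, c("CS_PLUS", "CS_PLUS"))
  expect_equal(epoch_auc(epoch_from_matrix(0 * z), c(0, 2))$auc, c(0, 0))
  # linear ramp 0 -> 2 over [0, 2] at 1 kHz: triangle area 2
  rate <- 1000
  rel_len <- 5 * rate + 2 * rate + 1
  ramp <- matrix(0, 1, rel_len)
  rel <- seq(-5, 2, by = 1 / rate)
  ramp[1, ] <- pmax(0, rel)
  epr <- epoch_from_matrix(ramp, rate = rate)
  expect_equal(epoch_auc(epr, c(0, 2))$auc, 2, tolerance = 0.002 / 2)
  # linearity and additivity over abutting windows
  pavphot:::with_seed(5, {
    zr <- matrix(rnorm(3 * 2501), 3, 2501)
    ep2 <- epoch_from_matrix(zr, rate = 100)
    ep2a <- epoch_from_matrix(2.5 * zr, rate = 100)
    expect_equal(epoch_auc(ep2a, c(0, 4))$auc,
                 2.5 * epoch_auc(ep2, c(0, 4))$auc, tolerance = 1e-12)
    expect_equal(epoch_auc(ep2, c(0, 2))$auc + epoch_auc(ep2, c(2, 4))$auc,
                 epoch_auc(ep2, c(0, 4))$auc, tolerance = 1e-12)
  })
  expect_error(epoch_auc(ep, c(0, 0.001)), "fewer than 2")
})

test_that("identical CS+ and CS- responses give zero difference metrics", {
  z <- matrix(rnorm(5 * 2501, sd = 1), 5, 2501)
  csp <- epoch_from_matrix(z, trial_type = "CS_PLUS")
  csm <- epoch_from_matrix(z, trial_type = "CS_MINUS")
  rew <- epoch_from_matrix(z, trial_type = "CS_PLUS")
  m <- difference_metrics(csp, csm, rew)
  expect_equal(m$delta_lever_extension_auc, 0)
  expect_equal(m$delta_cue_period_auc, 0)
  expect_equal(m$delta_cue_reward_auc, 0)
})

test_that("cue-reward transfer flips the difference score across training", {
  res <- vapply(1:10, function(sd) {
    s <- small_pla(n = 6, seed = sd)
    vapply(c(1, 5), function(day) {
      cfg <- sim_config(phenotype = "ST", day = day, sampling_rate = 50,
                        seed = sd)
      sess <- simulate_session(s, cfg)
      analyze_pla_session(sess$raw, s)$metrics$delta_cue_reward_auc
    }, numeric(1))
  }, numeric(2))
  expect_gte(sum(res[1, ] < 0), 9)  # day 1: reward-dominant
  expect_gte(sum(res[2, ] > 0), 9)  # day 5 ST: cue-dominant
})

test_that("binned means honour half-open 2-s bins and trial-type grouping", {
  z <- matrix(2.5, 3, 2501)
  ep <- epoch_from_matrix(z, rate = 100,
                          trial_type = c("EXPECTED", "POSITIVE", "NEGATIVE"))
  b <- binned_means(ep)
  expect_equal(nrow(b), 9)
  expect_true(all(b$mean_z == 2.5))
  expect_equal(unique(b$t_lo), c(0, 2, 4))
  expect_equal(unique(b$t_hi), c(2, 4, 6))
  # [lo, hi): a spike exactly at t = 2 belongs to bin 2 only
  z2 <- matrix(0, 1, 2501)
  z2[1, epoch_from_matrix(z2, rate = 100)$rel_time == 2] <- 100
  b2 <- binned_means(epoch_from_matrix(z2, rate = 100))
  expect_equal(b2$mean_z[b2$bin == 1], 0)
  expect_gt(b2$mean_z[b2$bin == 2], 0)
  short <- epoch_from_matrix(matrix(0, 1, 301), rate = 100)
  expect_error(binned_means(short), "does not cover")
})

test_that("score-signal correlation matches OLS expectations", {
  scores <- seq(-0.8, 0.9, length.out = 12)
  exact <- suppressWarnings(score_signal_correlation(scores, 2 * scores + 1))
  expect_equal(exact$r_squared, 1)
  expect_equal(exact$slope, 2)
  expect_lt(exact$p_value, 1e-10)
  expect_error(score_signal_correlation(1:2, 1:2), "at least 3")
  # permutation null: E[R^2] = 1/(n-1)
  pavphot:::with_seed(6, {
    n <- 8
    metrics <- rnorm(n)
    r2 <- replicate(1000, {
      score_signal_correlation(rnorm(n), sample(metrics))$r_squared
    })
    expect_lt(abs(mean(r2) - 1 / (n - 1)), 0.03)
  })
})

test_that("cohorts with signal tied to phenotype show a detectable correlation", {
  hits <- vapply(1:20, function(coh) {
    s <- pla_schedule(n_cs_plus = 5, n_cs_minus = 5,
                      seed = 600 + coh)
    rats <- vapply(1:16, function(r) {
      # amplitude scales linearly with the rat's behavioural drive
      drive <- (r - 1) / 15
      sk <- coh * 100L + r
      cfg <- sim_config(phenotype = "ST", day = 5, sampling_rate = 50,
                        seed = sk,
                        amplitudes = list(
                          cs_plus_onset = 0.01 + 0.05 * drive))
      m <- analyze_pla_session(simulate_session(s, cfg)$raw, s)$metrics
      c(score = -0.5 + 1.4 * drive, metric = m$delta_lever_extension_auc)
    }, numeric(2))
    score_signal_correlation(rats["score", ],
                             rats["metric", ])$r_squared > 0.3
  }, logical(1))
  expect_gte(sum(hits), 18)
})

test_that("trial bookkeeping: epoch rows plus exclusions cover the schedule", {
  s <- small_pla(n = 5, seed = 11)
  cfg <- sim_config(phenotype = "ST", sampling_rate = 100,
                    disconnect_prob = 0.4, seed = 14)
  sess <- simulate_session(s, cfg)
  res <- analyze_pla_session(sess$raw, s)
  n_plus <- sum(s$trial_type == "CS_PLUS")
  excl_plus <- sum(s$trial_type[res$excluded_trials] == "CS_PLUS")
  expect_equal(nrow(res$cs_plus$z) + excl_plus, n_plus)
})
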