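make_log <- function(...) {
  rows <- list(...)
  log <- dplyr::bind_rows(lapply(rows, function(r)
    tibble::tibble(timestamp = r[[1]], code = r[[2]],
                   trial = as.integer(r[[3]]))))
  dplyr::arrange(log, timestamp)
}

# two-trial schedule (CS+ at 40-50 s, CS- at 100-110 s) built by hand
toy_schedule <- function() {
  pavphot:::new_trial_schedule(
    tibble::tibble(trial = 1:2, trial_type = c("CS_PLUS", "CS_MINUS"),
                   iti_draw = c(40, 50),
                   cue_onset = c(40, 100), cue_offset = c(50, 110),
                   reward_1 = c(50, NA), reward_2 = c(50.5, NA)),
    "PLA", list(cue_dur = 10, vi_bounds = c(35, 55)), 1L)
}

test_that("per-trial scoring reads counts and first-response latencies", {
  s <- toy_schedule()
  log <- make_log(list(41.2, "PRESS_P", 1), list(43.0, "PRESS_P", 1),
                  list(49.9, "PRESS_P", 1), list(44.0, "FC_ENTRY", 1),
                  list(44.4, "FC_EXIT", 1))
  tr <- score_trials(log, s)
  expect_equal(tr$presses, c(3L, 0L))
  expect_equal(tr$press_latency, c(1.2, 10))
  expect_equal(tr$pokes, c(1L, 0L))
  expect_equal(tr$poke_latency, c(4, 10))
})

test_that("an empty trial gets zero counts and ceiling latencies", {
  tr <- score_trials(make_log(list(40, "CSP_ON", 1)), toy_schedule())
  expect_equal(tr$presses, c(0L, 0L))
  expect_equal(tr$pokes, c(0L, 0L))
  expect_equal(tr$press_latency, c(10, 10))
  expect_equal(tr$poke_latency, c(10, 10))
})

test_that("presses while levers are retracted are excluded with a warning", {
  s <- toy_schedule()
  log <- make_log(list(41, "PRESS_P", 1), list(70, "PRESS_P", NA))
  expect_warning(tr <- score_trials(log, s), "outside any cue window")
  expect_equal(tr$presses[1], 1L)
  expect_equal(sum(tr$presses), 1L)
})

trial_tbl <- function(presses, pokes, press_lat, poke_lat) {
  tibble::tibble(trial = seq_along(presses), trial_type = "CS_PLUS",
                 presses = presses, pokes = pokes,
                 press_latency = press_lat, poke_latency = poke_lat)
}

test_that("PCA score attains the formula extremes and centre", {
  all_press <- trial_tbl(c(5, 3, 4), c(0, 0, 0), c(0, 0, 0), c(10, 10, 10))
  expect_equal(pca_score(all_press)$pca_score, 1)
  all_poke <- trial_tbl(c(0, 0, 0), c(5, 3, 4), c(10, 10, 10), c(0, 0, 0))
  expect_equal(pca_score(all_poke)$pca_score, -1)
  balanced <- trial_tbl(c(2, 3), c(2, 3), c(1.5, 2), c(2, 1.5))
  expect_equal(pca_score(balanced)$pca_score, 0)
  # undefined 0/0 components contribute zero, not NaN
  silent <- trial_tbl(c(0, 0), c(0, 0), c(10, 10), c(10, 10))
  expect_equal(pca_score(silent)$pca_score, 0)
  expect_error(pca_score(trial_tbl(1, 0, 0, 10)[0, ]), "no CS\\+")
})

test_that("PCA score is antisymmetric under swapping press and poke roles", {
  pavphot:::with_seed(8, {
    for (k in 1:10) {
      n <- sample(3:8, 1)
      tb <- trial_tbl(rpois(n, 3), rpois(n, 3),
                      runif(n, 0, 10), runif(n, 0, 10))
      swapped <- tb
      swapped$presses <- tb$pokes
      swapped$pokes <- tb$presses
      swapped$press_latency <- tb$poke_latency
      swapped$poke_latency <- tb$press_latency
      expect_equal(pca_score(swapped)$pca_score,
                   -pca_score(tb)$pca_score, tolerance = 1e-12)
    }
  })
})

test_that("tracking classification switches exactly at mean score 0.5", {
  expect_equal(classify_tracking(0.6, 0.4), "ST")
  expect_equal(classify_tracking(0.5, 0.49), "GT_INT")
  expect_equal(classify_tracking(-1, -1), "GT_INT")
  expect_equal(classify_tracking(0.5, 0.5), "ST")
  # monotone in both arguments
  grid <- seq(-1, 1, by = 0.25)
  lab <- outer(grid, grid, Vectorize(classify_tracking))
  is_st <- lab == "ST"
  expect_true(all(diff(rowSums(is_st)) >= 0))
  expect_true(all(diff(colSums(is_st)) >= 0))
})

test_that("delta responses are the CS+/CS- mean count differences", {
  tb <- dplyr::bind_rows(
    trial_tbl(c(8, 8), c(1, 1), c(1, 1), c(5, 5)),
    within(trial_tbl(c(1, 1), c(1, 1), c(5, 5), c(5, 5)),
           trial_type <- "CS_MINUS"))
  d <- delta_responses(tb)
  expect_equal(d$delta_presses, 7)
  expect_equal(d$delta_pokes, 0)
  expect_error(delta_responses(trial_tbl(1, 1, 1, 1)), "CS\\+ and CS-")
})

test_that("pre-trial checking rate counts entries in the look-back window", {
  s <- rpe_schedule(seed = 6)
  anchors <- ifelse(is.na(s$cue_onset), s$reward_1, s$cue_onset)
  # no pokes anywhere -> all rates zero
  empty <- tibble::tibble(timestamp = anchors, code = "CSP_ON",
                          trial = s$trial)
  r0 <- pretrial_check_rate(empty, s)
  expect_true(all(r0$rate == 0))
  # exactly two entries in each pre-trial window -> rate 2 in every group
  ts <- as.vector(vapply(2:nrow(s),
                         function(i) anchors[i] - c(1, 2), numeric(2)))
  log2 <- tibble::tibble(timestamp = sort(ts), code = "FC_ENTRY",
                         trial = NA_integer_)
  r2 <- pretrial_check_rate(log2, s)
  expect_true(all(r2$rate == 2))
  expect_setequal(r2$prev_type, c("EXPECTED", "POSITIVE", "NEGATIVE"))
  expect_equal(sum(r2$n), nrow(s) - 1L)
})

test_that("elevated post-omission checking is recovered from simulated logs", {
  hits <- vapply(1:20, function(sd) {
    s <- rpe_schedule(seed = sd)
    cfg <- sim_config(phenotype = "GT_INT", sampling_rate = 100, seed = sd,
                      behavior_params = list(iti_poke_rate = 0.2,
                                             post_negative_poke_mult = 2))
    ev <- simulate_behavior(s, cfg)
    r <- pretrial_check_rate(ev, s)
    r$rate[r$prev_type == "NEGATIVE"] == max(r$rate)
  }, logical(1))
  expect_gte(sum(hits), 18)
})

test_that("session press counts are conserved across trial scoring", {
  s <- small_pla(n = 6, seed = 3)
  cfg <- sim_config(phenotype = "ST", day = 5, sampling_rate = 100,
                    seed = 13)
  ev <- simulate_behavior(s, cfg)
  tr <- score_trials(ev, s)
  expect_equal(sum(tr$presses),
               sum(ev$code %in% c("PRESS_P", "PRESS_M")))
})

test_that("behaviour summaries give one tidy row per session", {
  s <- small_pla(n = 5, seed = 2)
  cfg <- sim_config(phenotype = "ST", day = 5, sampling_rate = 100,
                    seed = 21)
  bs <- behavior_summary(simulate_behavior(s, cfg), s)
  expect_equal(nrow(bs), 1L)
  expect_true(all(c("pca_score", "delta_presses", "delta_pokes",
                    "response_bias") %in% names(bs)))
  expect_true(abs(bs$pca_score) <= 1)
  expect_true(bs$p_press >= 0 && bs$p_press <= 1)
})
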