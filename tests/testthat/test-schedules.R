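test_that("PLA schedules have exact counts, valid timing and reward structure", {
  for (seed in c(1L, 7L, 101L)) {
    s <- pla_schedule(seed = seed)
    expect_s3_class(s, "trial_schedule")
    expect_equal(sum(s$trial_type == "CS_PLUS"), 25)
    expect_equal(sum(s$trial_type == "CS_MINUS"), 25)
    expect_true(all(s$iti_draw >= 35 & s$iti_draw <= 55))
    expect_equal(s$cue_offset - s$cue_onset, rep(10, 50))
    plus <- s[s$trial_type == "CS_PLUS", ]
    expect_equal(plus$reward_1, plus$cue_offset)
    expect_equal(plus$reward_2 - plus$reward_1, rep(0.5, 25))
    expect_true(all(is.na(s$reward_1[s$trial_type == "CS_MINUS"])))
    expect_true(all(diff(s$cue_onset) > 0))
    # run-length cap on the pseudorandom order
    expect_lte(max(rle(s$trial_type)$lengths), 3)
    expect_silent(validate_schedule(s))
  }
})

test_that("schedules are deterministic under a fixed seed", {
  expect_identical(pla_schedule(seed = 7L), pla_schedule(seed = 7L))
  expect_identical(rpe_schedule(seed = 7L), rpe_schedule(seed = 7L))
  expect_false(identical(pla_schedule(seed = 7L), pla_schedule(seed = 8L)))
})

test_that("variable-interval draws are uniform over the stated bounds", {
  draws <- unlist(lapply(1:200, function(sd)
    pla_schedule(seed = sd)$iti_draw))
  expect_gte(length(draws), 10000)
  expect_lt(abs(mean(draws) - 45), 0.5)
  expect_true(all(draws >= 35 & draws <= 55))
})

test_that("RPE schedules carry the 24/12/12 mixture with correct trial anatomy", {
  s <- rpe_schedule(seed = 3L)
  counts <- table(s$trial_type)
  expect_equal(as.integer(counts[c("EXPECTED", "POSITIVE", "NEGATIVE")]),
               c(24L, 12L, 12L))
  pos <- s[s$trial_type == "POSITIVE", ]
  expect_true(all(is.na(pos$cue_onset)))
  expect_false(anyNA(pos$reward_1))
  neg <- s[s$trial_type == "NEGATIVE", ]
  expect_false(anyNA(neg$cue_onset))
  expect_true(all(is.na(neg$reward_1)))
  exp_tr <- s[s$trial_type == "EXPECTED", ]
  expect_equal(exp_tr$reward_1, exp_tr$cue_offset)
})

test_that("degenerate RPE mixture reduces to a CS+-only session", {
  s <- rpe_schedule(frac_expected = 1, frac_positive = 0, frac_negative = 0,
                    seed = 2L)
  expect_true(all(s$trial_type == "EXPECTED"))
  expect_equal(nrow(s), 48)
  # structurally a CS+-only autoshaping session: every trial cued + rewarded
  expect_equal(s$cue_offset - s$cue_onset, rep(10, 48))
  expect_equal(s$reward_1, s$cue_offset)
})

test_that("unsignalled rewards keep a safety gap from every cue interval", {
  for (sd in 1:150) {
    s <- rpe_schedule(seed = sd)
    pos <- which(s$trial_type == "POSITIVE")
    cues <- s[!is.na(s$cue_onset), ]
    for (i in pos) {
      for (rt in c(s$reward_1[i], s$reward_2[i])) {
        gaps <- pmax(cues$cue_onset - rt, rt - cues$cue_offset)
        expect_gte(min(gaps), 5 - 0.5 - 1e-9)
      }
      # first pellet itself is >= 5 s from any cue boundary
      gap1 <- pmax(cues$cue_onset - s$reward_1[i],
                   s$reward_1[i] - cues$cue_offset)
      expect_gte(min(gap1), 5 - 1e-9)
    }
  }
})

test_that("schedule configuration errors are caught", {
  expect_error(pla_schedule(n_cs_plus = 0), "positive")
  expect_error(pla_schedule(vi_bounds = c(55, 35)), "increasing")
  expect_error(pla_schedule(vi_mean = 60, vi_bounds = c(35, 55)), "outside")
  expect_error(rpe_schedule(n_total = 50, frac_expected = 0.5,
                            frac_positive = 0.25, frac_negative = 0.25),
               "non-integer")
  expect_error(rpe_schedule(frac_expected = 0.6, frac_positive = 0.25,
                            frac_negative = 0.25), "sum to 1")
  expect_error(magazine_schedules(integer(0)), "non-empty")
})

test_that("magazine training splits 25 reward-only trials over 7/8/10", {
  ms <- magazine_schedules(seed = 4L)
  expect_length(ms, 3)
  expect_equal(vapply(ms, nrow, integer(1)), c(7L, 8L, 10L))
  expect_equal(sum(vapply(ms, nrow, integer(1))), 25L)
  for (m in ms) {
    expect_true(all(m$trial_type == "MAGAZINE"))
    expect_true(all(is.na(m$cue_onset)))
    expect_equal(m$reward_2 - m$reward_1, rep(0.5, nrow(m)))
    expect_true(all(m$iti_draw >= 50 & m$iti_draw <= 70))
  }
  single <- magazine_schedules(1, seed = 9L)[[1]]
  expect_equal(nrow(single), 1L)
  expect_equal(single$reward_1, single$iti_draw)
})

test_that("expected session duration matches the analytic form", {
  expect_equal(
    expected_session_duration(list(n_trials = 50, cue_dur = 10,
                                   vi_mean = 45)), 2750)
  expect_equal(round(2750 / 60), 46)
  expect_equal(
    expected_session_duration(list(n_trials = 0, cue_dur = 10,
                                   vi_mean = 45)), 0)
  s <- pla_schedule(seed = 1L)
  expect_equal(expected_session_duration(s), 2750)
})

test_that("mean simulated schedule span agrees with the analytic duration", {
  spans <- vapply(1:300, function(sd) {
    s <- pla_schedule(seed = sd)
    max(s$cue_offset)
  }, numeric(1))
  expect_lt(abs(mean(spans) - 2750) / 2750, 0.01)
})

test_that("schedules round-trip through CSV losslessly", {
  path <- withr::local_tempfile(fileext = ".csv")
  for (s in list(pla_schedule(seed = 5L), rpe_schedule(seed = 5L))) {
    write_schedule(s, path)
    r <- read_schedule(path)
    expect_equal(attr(r, "session_kind"), attr(s, "session_kind"))
    expect_equal(attr(r, "seed"), attr(s, "seed"))
    expect_equal(as.data.frame(r), as.data.frame(s), tolerance = 1e-12)
  }
})
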