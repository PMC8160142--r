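test_that("the session schedule follows the mini-block protocol", {
  sch <- schedule_session(seed = 11)
  expect_equal(nrow(sch), 36)
  expect_equal(unique(sch$block), c("A1", "B1", "C1", "B2", "C2", "A2"))
  cond <- unique(sch[c("block", "condition")])
  expect_equal(cond$condition,
               c("normal", "full_gaze", "head_only",
                 "full_gaze", "head_only", "normal"))
  sizes <- seq(0.9, 1.4, by = 0.1)
  for (b in unique(sch$block)) {
    expect_equal(sort(sch$logmar[sch$block == b]), sizes)
  }
  expect_equal(anyDuplicated(sch$sentence_id), 0)
  # conserved across subjects: the schedule is a pure function of its seed
  expect_identical(sch, schedule_session(seed = 11))
  expect_false(identical(sch$logmar, schedule_session(seed = 12)$logmar))
  expect_error(schedule_session(seed = 1, n_sentences = 30), "36")
})

test_that("normal trials read every word at the deterministic pace", {
  geom <- default_geom()
  field <- default_field(seed = 1)
  fx <- fixture_sentences()
  obs <- observer_params()
  spec <- tibble::tibble(trial = 1, block = "A1", condition = "normal",
                         logmar = 1.0, sentence_id = 1)
  rec <- simulate_trial(spec, obs, field, geom, fx, seed = 7,
                        ref = cached_reference(1, 1.0))
  expect_equal(rec$n_correct, rec$n_words)
  words <- rec$words_reported[[1]]
  expect_equal(nrow(words), rec$n_words)
  expect_true(all(words$outcome == "correct"))
  # duration: n_words fixations + saccades, plus the saccade to the dot
  expect_equal(rec$reading_duration_ms,
               rec$n_words * (obs$fixation_ms + obs$saccade_ms) +
                 obs$saccade_ms)
})

test_that("trial phases are ordered with exact dwell and ITI bookkeeping", {
  geom <- default_geom()
  field <- default_field(seed = 1)
  fx <- fixture_sentences()
  obs <- observer_params()
  for (cond in c("normal", "full_gaze", "head_only")) {
    spec <- tibble::tibble(trial = 1, block = "X1", condition = cond,
                           logmar = 1.2, sentence_id = 2)
    rec <- simulate_trial(spec, obs, field, geom, fx, seed = 19,
                          ref = cached_reference(2, 1.2))
    expect_true(rec$start_ms < rec$prestim_on_ms)
    expect_true(rec$prestim_on_ms < rec$reading_on_ms)
    expect_true(rec$reading_on_ms < rec$reading_off_ms)
    expect_equal(rec$reading_on_ms - rec$prestim_on_ms, obs$prestim_ms)
    expect_equal(rec$end_ms - rec$reading_off_ms, 350)
    expect_equal(rec$trial_end_ms - rec$end_ms, 2000)
    expect_gt(rec$reading_duration_ms, 0)
    expect_equal(nrow(rec$words_reported[[1]]), rec$n_words)
  }
})

test_that("full-gaze legibility is driven by the logistic in coverage", {
  geom <- default_geom()
  field <- default_field(seed = 1)
  fx <- fixture_sentences()
  spec <- tibble::tibble(trial = 1, block = "B1", condition = "full_gaze",
                         logmar = 1.4, sentence_id = 1)
  # midpoint far below the coverage at 1.4 logMAR: everything legible
  easy <- observer_params(legibility_midpoint_ppx = 1,
                          legibility_slope = 3)
  rec <- simulate_trial(spec, easy, field, geom, fx, seed = 3,
                        ref = cached_reference(1, 1.4))
  expect_equal(rec$n_correct, rec$n_words)
  # midpoint far above any attainable coverage: nothing legible
  hard <- observer_params(legibility_midpoint_ppx = 1000,
                          legibility_slope = 3)
  rec2 <- simulate_trial(spec, hard, field, geom, fx, seed = 3,
                         ref = cached_reference(1, 1.4))
  expect_equal(rec2$n_correct, 0)
  # failed words cost extra time
  expect_gt(rec2$reading_duration_ms, rec$reading_duration_ms)
})

test_that("full-gaze accuracy falls sigmoidally as print size shrinks", {
  geom <- default_geom()
  field <- default_field(seed = 1)
  fx <- fixture_sentences()
  obs <- observer_params()
  acc <- vapply(c(0.9, 1.4), function(lm) {
    recs <- lapply(1:6, function(s) {
      spec <- tibble::tibble(trial = 1, block = "B1",
                             condition = "full_gaze", logmar = lm,
                             sentence_id = s)
      simulate_trial(spec, obs, field, geom, fx, seed = 100 + s,
                     ref = cached_reference(s, lm))
    })
    mean(vapply(recs, function(r) r$n_correct / r$n_words, 0))
  }, 0)
  expect_lt(acc[1], 0.5) # hard at the smallest size
  expect_gt(acc[2], 0.8) # near ceiling at the largest
})

test_that("head-only trials loop out and back and scan with the head", {
  geom <- default_geom()
  field <- default_field(seed = 1)
  fx <- fixture_sentences()
  obs <- observer_params(incongruence_sd_deg = 5)
  spec <- tibble::tibble(trial = 1, block = "C1", condition = "head_only",
                         logmar = 1.3, sentence_id = 3)
  rec <- simulate_trial(spec, obs, field, geom, fx, seed = 5,
                        ref = cached_reference(3, 1.3), store_traces = TRUE)
  gz <- rec$gaze_trace[[1]]
  hd <- rec$head_trace[[1]]
  # gaze repeatedly returns to the screen center between excursions
  center_visits <- sum(gz$azimuth_deg == 0 & gz$elevation_deg == 0)
  expect_gte(center_visits, rec$n_words)
  expect_gt(max(abs(gz$azimuth_deg)), 2) # excursions leave the center
  # the head trace visits all three text lines left to right
  ref <- cached_reference(3, 1.3)
  tg <- phosread:::word_targets_deg(ref, geom)
  expect_equal(nrow(hd), rec$n_words + 1) # start + one aim per word
  expect_equal(hd$azimuth_deg[-1], unname(tg$azimuth_deg), tolerance = 1e-9)
  expect_gt(rec$reading_duration_ms,
            1000 * sum(abs(diff(tg$azimuth_deg))) / obs$headscan_speed_dps)
})

test_that("head-only accuracy is dominated by full gaze in paired trials", {
  geom <- default_geom()
  field <- default_field(seed = 1)
  fx <- fixture_sentences()
  obs <- observer_params()
  ref <- cached_reference(4, 1.3)
  n_pairs <- 60
  acc <- vapply(seq_len(n_pairs), function(k) {
    fg <- simulate_trial(
      tibble::tibble(trial = 1, block = "B1", condition = "full_gaze",
                     logmar = 1.3, sentence_id = 4),
      obs, field, geom, fx, seed = 2000 + k, ref = ref)
    ho <- simulate_trial(
      tibble::tibble(trial = 1, block = "C1", condition = "head_only",
                     logmar = 1.3, sentence_id = 4),
      obs, field, geom, fx, seed = 2000 + k, ref = ref)
    c(fg$n_correct, ho$n_correct)
  }, c(0, 0))
  expect_gt(mean(acc[1, ]), mean(acc[2, ])) # expectation ordering
  expect_lt(mean(acc[2, ]) / mean(acc[1, ]), 0.5) # and by a wide margin
})

test_that("abandonment kicks in at the give-up limit", {
  geom <- default_geom()
  field <- default_field(seed = 1)
  fx <- fixture_sentences()
  quick <- observer_params(give_up_ms = 2000, incongruence_sd_deg = 8)
  spec <- tibble::tibble(trial = 1, block = "C1", condition = "head_only",
                         logmar = 1.0, sentence_id = 5)
  rec <- simulate_trial(spec, quick, field, geom, fx, seed = 9,
                        ref = cached_reference(5, 1.0))
  expect_true(rec$gave_up)
  words <- rec$words_reported[[1]]
  expect_true(any(words$outcome == "skipped"))
})

test_that("cohorts are deterministic per seed and structurally complete", {
  geom <- default_geom()
  field <- default_field(seed = 1)
  fx <- fixture_sentences()
  log1 <- simulate_cohort(n_subjects = 2, seed = 5, field = field,
                          geom = geom, sentences = fx)
  log2 <- simulate_cohort(n_subjects = 2, seed = 5, field = field,
                          geom = geom, sentences = fx)
  expect_equal(as.data.frame(log1[setdiff(names(log1), c("words_reported", "gaze_trace", "head_trace"))]),
               as.data.frame(log2[setdiff(names(log2), c("words_reported", "gaze_trace", "head_trace"))]))
  expect_equal(nrow(log1), 72)
  expect_equal(length(unique(log1$subject)), 2)
  # both subjects saw the same schedule
  s1 <- log1[log1$subject == "S01", c("block", "condition", "logmar", "sentence_id")]
  s2 <- log1[log1$subject == "S02", c("block", "condition", "logmar", "sentence_id")]
  expect_equal(as.data.frame(s1), as.data.frame(s2))
  # and a different seed changes outcomes
  log3 <- simulate_cohort(n_subjects = 2, seed = 6, field = field,
                          geom = geom, sentences = fx)
  expect_false(identical(log1$n_correct, log3$n_correct))
})

test_that("session CSV round-trips the flat trial table", {
  geom <- default_geom()
  field <- default_field(seed = 1)
  fx <- fixture_sentences()
  log <- simulate_cohort(n_subjects = 1, seed = 5, field = field,
                         geom = geom, sentences = fx)
  path <- tempfile(fileext = ".csv")
  write_session_csv(log, path)
  back <- utils::read.csv(path)
  expect_equal(nrow(back), 36)
  expect_equal(back$n_correct, log$n_correct)
  expect_equal(back$reading_duration_ms, log$reading_duration_ms,
               tolerance = 1e-9)
  unlink(path)
})

test_that("observer parameter validation rejects nonsense", {
  expect_error(observer_params(fixation_ms = -5), "positive")
  expect_error(observer_params(legibility_slope = 0), "positive")
})
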