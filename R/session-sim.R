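#' Synthetic observer parameters
#'
#' The synthetic observer is a modeling stand-in for human subjects: it
#' fixates words in reading order, recognizes each word with a probability
#' given by a logistic in phosphene coverage, and pays time costs for
#' fixations, saccades and head scanning. Under head-only steering its
#' eye-in-head position fluctuates, and the resulting gaze-camera
#' incongruence multiplies recognition probability by
#' `exp(-||incongruence|| / 1 deg)`.
#'
#' Defaults are calibrated once against the packaged phosphene field so that
#' normal-vision reading runs in the low hundreds of words per minute and
#' full-gaze accuracy is sigmoidal over 0.9-1.4 logMAR print sizes.
#'
#' @param legibility_midpoint_ppx Coverage (activated phosphenes per
#'   x-height of word width) at which word recognition is 50%.
#' @param legibility_slope Logistic slope on the coverage scale.
#' @param fixation_ms Per-word fixation duration, ms.
#' @param saccade_ms Per-saccade cost, ms.
#' @param headscan_speed_dps Head scanning speed under head-only steering,
#'   deg/s.
#' @param incongruence_sd_deg Eye-in-head jitter (per-axis Gaussian sd,
#'   degrees) during head-only reading.
#' @param give_up_ms Per-trial abandonment limit, ms.
#' @param prestim_ms Pre-stimulus fixation hold, ms.
#' @param phosphene_effort Multiplier on `fixation_ms` for words viewed in
#'   phosphene vision (reading through phosphenes is slower even when
#'   accurate).
#' @param retry_attempts Extra fixations spent on a word that was not
#'   recognized (full gaze).
#' @param head_attempts Recognition attempts per word under head-only
#'   steering, each with fresh eye-in-head jitter.
#' @return An `observer_params` object.
#' @export
observer_params <- function(legibility_midpoint_ppx = 27,
                            legibility_slope = 0.3,
                            fixation_ms = 280,
                            saccade_ms = 50,
                            headscan_speed_dps = 1.5,
                            incongruence_sd_deg = 3,
                            give_up_ms = 180000,
                            prestim_ms = 500,
                            phosphene_effort = 3,
                            retry_attempts = 2,
                            head_attempts = 3) {
  obs <- list(legibility_midpoint_ppx = legibility_midpoint_ppx,
              legibility_slope = legibility_slope,
              fixation_ms = fixation_ms,
              saccade_ms = saccade_ms,
              headscan_speed_dps = headscan_speed_dps,
              incongruence_sd_deg = incongruence_sd_deg,
              give_up_ms = give_up_ms,
              prestim_ms = prestim_ms,
              phosphene_effort = phosphene_effort,
              retry_attempts = retry_attempts,
              head_attempts = head_attempts)
  if (any(!is.finite(unlist(obs))) || any(unlist(obs) < 0) ||
      legibility_slope <= 0) {
    stop("observer parameters must be positive (legibility_slope > 0)",
         call. = FALSE)
  }
  structure(obs, class = "observer_params")
}

#' @export
print.observer_params <- function(x, ...) {
  cat(sprintf(
    "<observer_params> midpoint %.3g ppx, slope %.3g, fixation %g ms, incongruence sd %g deg\n",
    x$legibility_midpoint_ppx, x$legibility_slope, x$fixation_ms,
    x$incongruence_sd_deg))
  invisible(x)
}

# word recognition probability given coverage
legibility <- function(obs, coverage) {
  1 / (1 + exp(-obs$legibility_slope *
                 (coverage - obs$legibility_midpoint_ppx)))
}

#' Schedule a full session of trials
#'
#' Mini-block order is fixed as A1, B1, C1, B2, C2, A2 (Normal, Full Gaze,
#' Head Only, each twice, in increasing order of difficulty first, control
#' closing the session). Within each mini-block the six print sizes appear
#' once in a pseudo-random order that varies from mini-block to mini-block
#' but is conserved across subjects (same scheduling seed, same orders).
#' Each of the 36 trials gets a distinct sentence.
#'
#' @param seed Scheduling seed (shared by all subjects of a cohort).
#' @param n_sentences Number of fixture sentences available (must be at
#'   least 36).
#' @return A tibble with columns `trial`, `block`, `condition`, `logmar`,
#'   `sentence_id`.
#' @export
#' @examples
#' schedule_session(seed = 11) |> head()
schedule_session <- function(seed = 11, n_sentences = 36) {
  if (n_sentences < 36) {
    stop(sprintf("36 distinct sentences are required, got %d", n_sentences),
         call. = FALSE)
  }
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  blocks <- tibble::tibble(
    block = c("A1", "B1", "C1", "B2", "C2", "A2"),
    condition = c("normal", "full_gaze", "head_only",
                  "full_gaze", "head_only", "normal")
  )
  sizes <- seq(0.9, 1.4, by = 0.1)
  out <- purrr::map_dfr(seq_len(6), function(b) {
    tibble::tibble(block = blocks$block[b], condition = blocks$condition[b],
                   logmar = sample(sizes))
  })
  out$trial <- seq_len(36)
  out$sentence_id <- sample.int(n_sentences)[1:36]
  out[c("trial", "block", "condition", "logmar", "sentence_id")]
}

# per-trial timing constants (ms)
DOT_DWELL_MS <- 350
ITI_MS <- 2000

# reading-order fixation targets: word centers in degree space
word_targets_deg <- function(ref, geom) {
  wc <- ref$words
  ctr <- px_to_deg((wc$x0 + wc$x1) / 2, (wc$y0 + wc$y1) / 2, geom)
  tibble::tibble(line = wc$line, word = wc$word,
                 azimuth_deg = ctr$azimuth_deg,
                 elevation_deg = ctr$elevation_deg)
}

# position of the Next Sentence dot (near the top center of the screen)
next_dot_deg <- function(geom) {
  px_to_deg(geom$width_px / 2, geom$height_px * 0.06, geom)
}

#' Simulate one reading trial
#'
#' Runs the four trial phases (Start, Pre-Stimulus, Reading, End) with the
#' synthetic observer. Under `normal` viewing every word is read correctly
#' with a left-to-right, line-by-line scanpath. Under `full_gaze` each
#' fixated word is recognized with probability `L(coverage)`; missed words
#' are skipped after extra fixations. Under `head_only` the head rasters
#' across the text while eye-in-head jitter produces gaze-camera
#' incongruence that both multiplies recognition probability by
#' `exp(-||incongruence||)` (sigma 1 degree) and drives looping
#' center-out-and-back gaze traces; the trial is abandoned when
#' `give_up_ms` elapses.
#'
#' @param spec One row of a [schedule_session()] table.
#' @param obs An [observer_params()].
#' @param field A [generate_field()] result.
#' @param geom A [viewing_geometry()].
#' @param sentences A [make_fixtures()] table containing
#'   `spec$sentence_id`.
#' @param seed Integer RNG seed for this trial.
#' @param ref Optionally, a pre-rendered [render_reference()] for the
#'   trial's sentence and size (cached by cohort runs).
#' @param store_traces Keep gaze/head traces in the record?
#' @return A one-row tibble (`trial_record`): condition, size, counts,
#'   phase timestamps, and list-columns `words_reported`, `gaze_trace`,
#'   `head_trace`.
#' @export
simulate_trial <- function(spec, obs, field, geom, sentences, seed = 1,
                           ref = NULL, store_traces = TRUE) {
  stopifnot(inherits(obs, "observer_params"))
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)

  condition <- spec$condition
  if (is.null(ref)) {
    srow <- sentences[sentences$sentence_id == spec$sentence_id, ]
    if (nrow(srow) != 1) stop("sentence_id not found in fixtures", call. = FALSE)
    ref <- render_reference(srow, spec$logmar, geom)
  }
  targets <- word_targets_deg(ref, geom)
  n_words <- nrow(targets)
  dot <- next_dot_deg(geom)

  # phase clock
  t_start <- 0
  t_prestim <- obs$saccade_ms             # dot foveated
  t_read_on <- t_prestim + obs$prestim_ms # text appears

  gaze_pts <- list()
  head_pts <- list()
  push_gaze <- function(t, az, el) {
    gaze_pts[[length(gaze_pts) + 1L]] <<- c(t, az, el)
  }
  push_head <- function(t, az, el) {
    head_pts[[length(head_pts) + 1L]] <<- c(t, az, el)
  }

  outcome <- rep("skipped", n_words)
  t <- t_read_on
  gave_up <- FALSE
  push_gaze(t, 0, 0)
  push_head(t, 0, 0)

  if (condition == "normal") {
    for (i in seq_len(n_words)) {
      t <- t + obs$saccade_ms + obs$fixation_ms
      outcome[i] <- "correct"
      push_gaze(t, targets$azimuth_deg[i], targets$elevation_deg[i])
    }
  } else if (condition == "full_gaze") {
    for (i in seq_len(n_words)) {
      # gaze (= camera) lands on the word center
      cam <- direction(targets$azimuth_deg[i], targets$elevation_deg[i])
      ci <- word_coverage(field, ref, cam, geom, word_idx = i)$coverage[i]
      t <- t + obs$saccade_ms + obs$phosphene_effort * obs$fixation_ms
      if (stats::runif(1) < legibility(obs, ci)) {
        outcome[i] <- "correct"
      } else {
        t <- t + obs$retry_attempts * obs$fixation_ms
      }
      push_gaze(t, targets$azimuth_deg[i], targets$elevation_deg[i])
      if (t - t_read_on > obs$give_up_ms) { gave_up <- TRUE; break }
    }
  } else if (condition == "head_only") {
    head_prev <- c(0, 0)
    for (i in seq_len(n_words)) {
      tgt <- c(targets$azimuth_deg[i], targets$elevation_deg[i])
      travel <- sqrt(sum((tgt - head_prev)^2)) / obs$headscan_speed_dps * 1000
      t <- t + travel
      push_head(t, tgt[1], tgt[2])
      head_prev <- tgt
      cam <- direction(tgt[1], tgt[2])
      ci <- word_coverage(field, ref, cam, geom, word_idx = i)$coverage[i]
      p_base <- legibility(obs, ci)
      for (a in seq_len(obs$head_attempts)) {
        eye <- stats::rnorm(2, 0, obs$incongruence_sd_deg)
        inc <- sqrt(sum(eye^2))
        # looping center-out-and-back gaze movement around the head aim
        t_out <- t + obs$saccade_ms
        push_gaze(t_out, tgt[1] + eye[1], tgt[2] + eye[2])
        t <- t_out + obs$fixation_ms
        push_gaze(t, tgt[1], tgt[2]) # saccade back toward the tracked text
        if (stats::runif(1) < p_base * exp(-inc)) {
          outcome[i] <- "correct"
          break
        }
      }
      push_gaze(t + obs$saccade_ms, 0, 0) # recenter
      t <- t + obs$saccade_ms
      if (t - t_read_on > obs$give_up_ms) { gave_up <- TRUE; break }
    }
  } else {
    stop("unknown condition: ", condition, call. = FALSE)
  }

  # saccade to the Next Sentence dot ends the reading interval
  t <- t + obs$saccade_ms
  push_gaze(t, dot$azimuth_deg, dot$elevation_deg)
  t_read_off <- t
  t_end <- t_read_off + DOT_DWELL_MS
  t_final <- t_end + ITI_MS

  mk_trace <- function(pts) {
    m <- do.call(rbind, pts)
    tibble::tibble(t_ms = m[, 1], azimuth_deg = m[, 2], elevation_deg = m[, 3])
  }
  tibble::tibble(
    block = spec$block, condition = condition, logmar = spec$logmar,
    sentence_id = spec$sentence_id,
    n_words = n_words, n_correct = sum(outcome == "correct"),
    reading_duration_ms = t_read_off - t_read_on,
    start_ms = t_start, prestim_on_ms = t_prestim,
    reading_on_ms = t_read_on, reading_off_ms = t_read_off,
    end_ms = t_end, trial_end_ms = t_final,
    gave_up = gave_up,
    words_reported = list(tibble::tibble(word = targets$word,
                                         outcome = outcome)),
    gaze_trace = if (store_traces) list(mk_trace(gaze_pts)) else list(NULL),
    head_trace = if (store_traces) list(mk_trace(head_pts)) else list(NULL)
  )
}

#' Simulate one subject's full session
#'
#' @param subject_id Subject label.
#' @param obs An [observer_params()].
#' @param field A [generate_field()] result.
#' @param geom A [viewing_geometry()].
#' @param sentences A [make_fixtures()] table with at least 36 sentences.
#' @param schedule A [schedule_session()] table (shared across subjects).
#' @param seed Integer RNG seed for the subject's trials.
#' @param ref_cache Optional environment caching rendered references by
#'   `sentence_id:logmar`.
#' @param store_traces Keep gaze/head traces?
#' @return A tibble of 36 trial records with a `subject` column.
#' @export
simulate_session <- function(subject_id, obs, field, geom, sentences,
                             schedule = schedule_session(),
                             seed = 1, ref_cache = NULL,
                             store_traces = FALSE) {
  recs <- purrr::map_dfr(seq_len(nrow(schedule)), function(i) {
    spec <- schedule[i, ]
    # normal trials also use the rendered reference (word targets/timing)
    key <- sprintf("%d:%.1f", spec$sentence_id, spec$logmar)
    if (!is.null(ref_cache) && !is.null(ref_cache[[key]])) {
      ref <- ref_cache[[key]]
    } else {
      srow <- sentences[sentences$sentence_id == spec$sentence_id, ]
      ref <- render_reference(srow, spec$logmar, geom)
      if (!is.null(ref_cache)) ref_cache[[key]] <- ref
    }
    simulate_trial(spec, obs, field, geom, sentences,
                   seed = seed * 1000L + i, ref = ref,
                   store_traces = store_traces)
  })
  dplyr::bind_cols(tibble::tibble(subject = rep(subject_id, nrow(recs))), recs)
}

# log-normal jitter of observer parameters for a simulated population
jitter_observer <- function(obs, sdlog = 0.05) {
  fields <- c("legibility_midpoint_ppx", "legibility_slope", "fixation_ms",
              "saccade_ms", "headscan_speed_dps", "incongruence_sd_deg")
  for (f in fields) obs[[f]] <- obs[[f]] * stats::rlnorm(1, 0, sdlog)
  obs
}

#' Simulate a cohort of subjects
#'
#' Samples per-subject observer parameters (log-normal jitter around the
#' nominal values), runs a full 36-trial session for each subject against a
#' shared schedule, sentence set and phosphene field, and binds the session
#' logs. Deterministic for a fixed seed.
#'
#' @param n_subjects Number of subjects (the study population size is 23).
#' @param obs Nominal [observer_params()].
#' @param seed Master seed; subject parameter draws and trial seeds derive
#'   from it.
#' @param field A [generate_field()] result; default generates the packaged
#'   2000-phosphene field.
#' @param geom A [viewing_geometry()].
#' @param sentences Fixture sentences (default 36 from [make_fixtures()]
#'   with the scheduling seed).
#' @param schedule_seed Seed of the shared trial schedule.
#' @param subject_sdlog Log-normal sd of between-subject parameter jitter.
#' @param store_traces Keep gaze/head traces (memory-heavy for cohorts)?
#' @return A `session_log` tibble of `36 * n_subjects` trial records.
#' @export
simulate_cohort <- function(n_subjects = 23, obs = observer_params(),
                            seed = 1, field = NULL,
                            geom = viewing_geometry(),
                            sentences = NULL, schedule_seed = 11,
                            subject_sdlog = 0.05, store_traces = FALSE) {
  stopifnot(n_subjects >= 1)
  if (is.null(field)) {
    field <- generate_field(calibrate_profile(), 2000, seed = schedule_seed)
  }
  if (is.null(sentences)) sentences <- make_fixtures(36, seed = schedule_seed)
  schedule <- schedule_session(seed = schedule_seed,
                               n_sentences = nrow(sentences))
  ref_cache <- new.env(parent = emptyenv())

  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  subject_seeds <- sample.int(2^20, n_subjects)

  logs <- purrr::map_dfr(seq_len(n_subjects), function(s) {
    set.seed(subject_seeds[s])
    obs_s <- jitter_observer(obs, subject_sdlog)
    simulate_session(sprintf("S%02d", s), obs_s, field, geom, sentences,
                     schedule = schedule, seed = subject_seeds[s],
                     ref_cache = ref_cache, store_traces = store_traces)
  })
  class(logs) <- c("session_log", class(logs))
  attr(logs, "schedule_seed") <- schedule_seed
  logs
}

#' Acuity implied by the observer's legibility midpoint
#'
#' Computes the mean fixated-word coverage of the fixture sentences at each
#' print size on a given field, then inverts the (monotone) coverage-size
#' relation at the observer's legibility midpoint. This is the print size at
#' which the average word is a coin flip for the observer -- the equivalent
#' acuity the psychometric fit should recover from simulated sessions.
#'
#' @param obs An [observer_params()].
#' @param field A [generate_field()] result.
#' @param geom A [viewing_geometry()].
#' @param sentences Fixture sentences to probe (a handful suffices).
#' @param sizes Print sizes to probe.
#' @return Implied equivalent acuity in logMAR.
#' @export
observer_implied_acuity <- function(obs, field, geom,
                                    sentences = make_fixtures(4, seed = 11),
                                    sizes = seq(0.9, 1.4, by = 0.1)) {
  mean_cov <- vapply(sizes, function(lm) {
    covs <- purrr::map_dbl(seq_len(nrow(sentences)), function(k) {
      ref <- render_reference(sentences[k, ], lm, geom)
      tg <- word_targets_deg(ref, geom)
      mean(purrr::map_dbl(seq_len(nrow(tg)), function(i) {
        cam <- direction(tg$azimuth_deg[i], tg$elevation_deg[i])
        word_coverage(field, ref, cam, geom, word_idx = i)$coverage[i]
      }))
    })
    mean(covs)
  }, 0)
  if (any(diff(mean_cov) <= 0)) {
    warning("coverage is not strictly increasing with print size")
  }
  stats::approx(mean_cov, sizes, xout = obs$legibility_midpoint_ppx,
                rule = 2)$y
}

#' Write a session log as CSV (one row per trial)
#'
#' Serializes the flat per-trial columns; traces and per-word outcomes live
#' in a JSON sidecar when `sidecar = TRUE`.
#'
#' @param log A [simulate_cohort()] result.
#' @param path CSV path.
#' @param sidecar Also write `<path>.json` with per-word outcomes and any
#'   stored traces?
#' @return `path`, invisibly.
#' @export
write_session_csv <- function(log, path, sidecar = FALSE) {
  flat <- dplyr::select(as.data.frame(log), -dplyr::any_of(
    c("words_reported", "gaze_trace", "head_trace")))
  utils::write.csv(flat, path, row.names = FALSE)
  if (sidecar) {
    side <- purrr::map(seq_len(nrow(log)), function(i) {
      list(subject = log$subject[i], trial = i,
           words = log$words_reported[[i]],
           gaze_trace = log$gaze_trace[[i]],
           head_trace = log$head_trace[[i]])
    })
    jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, null = "null")
  }
  invisible(path)
}
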