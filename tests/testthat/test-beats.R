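make_rec <- function(pressure, fs = 200, id = "T") {
  n <- length(pressure)
  pressure_recording(id, pressure, fs = fs,
                     marks = protocol_marks(0, n / fs / 3, n / fs, "presyncope"))
}

test_that("beat onsets are recovered from a noise-free synthetic recording", {
  cfg <- synth_config(n_subjects = 1, presyncope_fraction = 1,
                      noise_sd_mmHg = 0, seed = 21)
  sub <- generate_subject(cfg, 1, presyncope = TRUE, seed = 321)
  beats <- detect_beats(sub$recording)
  ons <- vapply(beats, `[[`, numeric(1), "onset_s")
  err <- vapply(ons, function(o) min(abs(o - sub$truth$beat_onset_s)), numeric(1))
  expect_gte(mean(err <= 2 / 200 + 1e-9), 0.99)
})

test_that("per-phase heart rate is recovered within 1 bpm at moderate noise", {
  cfg <- synth_config(n_subjects = 1, presyncope_fraction = 1,
                      noise_sd_mmHg = 1.5, seed = 21)
  sub <- generate_subject(cfg, 1, presyncope = TRUE, seed = 321)
  beats <- remove_calibration_beats(detect_beats(sub$recording),
                                    sub$recording$artifact_intervals)
  ons <- vapply(beats, `[[`, numeric(1), "onset_s")
  dur <- vapply(beats, `[[`, numeric(1), "duration_s")
  B <- cfg$baseline_duration_s
  tt <- sub$truth
  # phase-mean HR as beats per elapsed beat time (the clinical average; the
  # per-beat 60/duration mean is biased upward by foot jitter under noise)
  phase_hr <- function(sel) 60 * sum(sel) / sum(dur[sel])
  expect_lt(abs(phase_hr(ons < B) - mean(tt$hr_bpm[tt$beat_onset_s < B])), 1)
  expect_lt(abs(phase_hr(ons >= B) - mean(tt$hr_bpm[tt$beat_onset_s >= B])), 1)
})

test_that("degenerate signals yield no beats and a warning", {
  expect_warning(b <- detect_beats(make_rec(rep(100, 1000))), "flat")
  expect_length(b, 0)
})

test_that("a pure periodic train yields the count implied by its rate", {
  # 1.25 Hz oscillation for 60 s: 74 or 75 complete foot-to-foot cycles
  tt <- seq(0, 60, by = 1 / 200)
  rec <- make_rec(100 + 20 * sin(2 * pi * 1.25 * tt))
  beats <- detect_beats(rec)
  expect_true(length(beats) %in% c(74L, 75L))
  expect_equal(unname(median(vapply(beats, `[[`, numeric(1), "duration_s"))),
               0.8, tolerance = 0.01)
})

test_that("beat count is invariant to a constant pressure offset", {
  cfg <- synth_config(n_subjects = 1, presyncope_fraction = 0,
                      baseline_duration_s = 60, max_lbnp_duration_s = 120,
                      physiocal_period_s = 1e6, seed = 6)
  sub <- generate_subject(cfg, 1, presyncope = FALSE, seed = 906)
  rec <- sub$recording
  rec_off <- pressure_recording(rec$subject_id, rec$pressure + 35, fs = rec$fs,
                                marks = rec$marks)
  expect_equal(length(detect_beats(rec_off)), length(detect_beats(rec)))
})

test_that("calibration-overlap removal is half-open at both boundaries", {
  beat <- list(subject_id = "T", onset_s = 10.0, duration_s = 0.8,
               raw = c(80, 100, 120, 90), sap_mmHg = 120, dap_mmHg = 80,
               map_mmHg = 97.5, hr_bpm = 75)
  expect_length(remove_calibration_beats(list(beat), list(c(10.5, 12))), 0)
  expect_length(remove_calibration_beats(list(beat), list(c(10.8, 12))), 1)
  expect_length(remove_calibration_beats(list(beat), list(c(9.0, 10.0))), 1)
  expect_length(remove_calibration_beats(list(beat), list(c(9.0, 10.0 + 1e-6))), 0)
  expect_identical(remove_calibration_beats(list(beat), list()), list(beat))
})

test_that("resampling returns exactly 33 samples and reproduces linear ramps", {
  raw160 <- beat_template(120, 80, 0.8, 0, synth_config(), fs = 200)
  out <- resample_beat(list(raw = raw160))
  expect_length(out, 33)
  # linear data are reproduced exactly by monotone cubic Hermite interpolation
  for (n in c(7, 33, 100)) {
    ramp <- seq(80, 120, length.out = n)
    out <- resample_beat(list(raw = ramp))
    expect_lt(max(abs(out - seq(80, 120, length.out = 33))), 1e-9)
  }
  expect_error(resample_beat(list(raw = c(1, 2, 3))), "4 raw samples")
})

test_that("resampling preserves endpoints and never overshoots the raw range", {
  # monotone raw data: the Fritsch-Carlson interpolant is range-preserving
  set.seed(8)
  for (i in 1:10) {
    raw <- 80 + cumsum(abs(rnorm(sample(10:200, 1))))
    out <- resample_beat(list(raw = raw))
    expect_equal(out[1], raw[1])
    expect_equal(out[33], raw[length(raw)])
    expect_gte(min(out), min(raw) - 1e-9)
    expect_lte(max(out), max(raw) + 1e-9)
  }
  # beat-shaped raw data (piecewise monotone, moderate noise): endpoints are
  # exact and any extremum overshoot stays far below measurement resolution
  cfg <- synth_config()
  for (sev in c(0, 0.5, 1)) {
    raw <- beat_template(125, 72, 0.9, sev, cfg, fs = 200) + rnorm(180, 0, 1)
    out <- resample_beat(list(raw = raw))
    expect_equal(out[1], raw[1])
    expect_equal(out[33], raw[length(raw)])
    expect_gte(min(out), min(raw) - 0.05)
    expect_lte(max(out), max(raw) + 0.05)
  }
  # 33 input samples on the same grid: identity
  raw33 <- as.numeric(beat_template(115, 75, 0.8, 0.4, synth_config(), fs = 41))[1:33]
  expect_equal(resample_beat(list(raw = raw33)), raw33, tolerance = 1e-12)
})

test_that("the cohort beat matrix has 33 columns and per-subject bookkeeping", {
  sc <- local_small_cohort()
  bm <- sc$beats
  expect_equal(ncol(bm$values), 33)
  expect_setequal(unique(bm$subject_id), names(sc$end_reason))
  expect_true(all(bm$label %in% 0:3))
  expect_equal(length(bm$label), nrow(bm$values))
  # beats are labeled and none survive past each subject's protocol end
  for (s in unique(bm$subject_id)) {
    expect_lte(max(bm$onset_s[bm$subject_id == s]),
               bm$marks[[s]]$protocol_end_s)
  }
  # a recording whose beats all fall in artifacts is excluded with a warning
  flat <- make_rec(rep(100, 2000))
  expect_warning(expect_warning(
    build_beat_matrix(list(sc$cohort[[1]]$recording, flat)),
    "flat"), "excluded")
})
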