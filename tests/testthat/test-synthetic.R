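notch_prominence <- function(w) {
  n <- length(w)
  mid <- w[round(0.25 * n):round(0.55 * n)]
  i_max <- which.max(diff(sign(diff(mid))) == -2)
  peaks <- which(diff(sign(diff(mid))) == -2) + 1
  troughs <- which(diff(sign(diff(mid))) == 2) + 1
  if (length(peaks) == 0 || length(troughs) == 0) return(0)
  max(mid[peaks]) - min(mid[troughs])
}

test_that("beat template honors its amplitude contract and sample count", {
  cfg <- synth_config()
  w <- beat_template(120, 80, 0.8, severity = 0, cfg, fs = 200)
  expect_length(w, 160)
  expect_gte(min(w), 79.5); expect_lte(min(w), 80.5)
  expect_gte(max(w), 119.5); expect_lte(max(w), 120.5)
  # deterministic
  expect_identical(w, beat_template(120, 80, 0.8, severity = 0, cfg, fs = 200))
  expect_error(beat_template(80, 80, 0.8, 0, cfg), "exceed")
})

test_that("dicrotic notch prominence shrinks strictly with severity", {
  cfg <- synth_config()
  w0 <- beat_template(120, 80, 0.8, severity = 0, cfg, fs = 500)
  w1 <- beat_template(120, 80, 0.8, severity = 1, cfg, fs = 500)
  expect_gt(notch_prominence(w0), notch_prominence(w1))
  expect_gt(notch_prominence(w0), 0)
})

test_that("presyncope recordings end when the stop criteria first fire", {
  cfg <- synth_config(n_subjects = 1, presyncope_fraction = 1, seed = 9)
  sub <- generate_subject(cfg, 1, presyncope = TRUE, seed = 901)
  expect_equal(sub$recording$marks$end_reason, "presyncope")
  tt <- sub$truth
  lb <- tt$beat_onset_s >= cfg$baseline_duration_s
  trig <- detect_presyncope(tt$beat_onset_s[lb], tt$sap_mmHg[lb],
                            tt$dap_mmHg[lb], tt$hr_bpm[lb])
  # generator and detector agree to within one beat
  expect_lte(abs(trig - tt$presyncope_time_s), max(60 / tt$hr_bpm))
  expect_equal(sub$recording$marks$protocol_end_s, tt$presyncope_time_s)
})

test_that("tolerated subjects run to the protocol limit with plateaued severity", {
  cfg <- synth_config(n_subjects = 1, presyncope_fraction = 0,
                      baseline_duration_s = 120, max_lbnp_duration_s = 600,
                      plateau_ramp_s = 200, seed = 10)
  sub <- generate_subject(cfg, 1, presyncope = FALSE, seed = 902)
  expect_equal(sub$recording$marks$end_reason, "tolerated")
  expect_equal(length(sub$recording$pressure) / cfg$fs, 120 + 600, tolerance = 0.01)
  expect_lte(max(sub$truth$severity), cfg$severity_plateau + 1e-9)
})

test_that("severity is zero at baseline and nondecreasing during LBNP", {
  cfg <- synth_config(n_subjects = 2, presyncope_fraction = 1,
                      baseline_duration_s = 90, max_lbnp_duration_s = 400, seed = 3)
  for (sub in generate_cohort(cfg)) {
    tt <- sub$truth
    expect_true(all(tt$severity[tt$beat_onset_s < 90] == 0))
    sev_lbnp <- tt$severity[tt$beat_onset_s >= 90]
    expect_true(all(diff(sev_lbnp) >= -1e-12))
  }
})

test_that("cohorts are reproducible, seed-sensitive and split per the fraction", {
  cfg <- synth_config(n_subjects = 5, presyncope_fraction = 0.8,
                      baseline_duration_s = 65, max_lbnp_duration_s = 150,
                      collapse_time_frac = c(0.3, 0.6), seed = 77)
  coh1 <- generate_cohort(cfg)
  coh2 <- generate_cohort(cfg)
  reasons <- vapply(coh1, function(s) s$recording$marks$end_reason, character(1))
  expect_equal(sum(reasons == "presyncope"), 4)
  expect_identical(lapply(coh1, function(s) s$recording$pressure),
                   lapply(coh2, function(s) s$recording$pressure))
  cfg2 <- synth_config(n_subjects = 5, presyncope_fraction = 0.8,
                       baseline_duration_s = 65, max_lbnp_duration_s = 150,
                       collapse_time_frac = c(0.3, 0.6), seed = 78)
  coh3 <- generate_cohort(cfg2)
  expect_false(identical(coh1[[1]]$recording$pressure,
                         coh3[[1]]$recording$pressure))
})

test_that("pulse pressure of final-stage beats is reduced relative to baseline", {
  sc <- local_small_cohort()
  for (sub in sc$cohort) {
    if (sub$truth$end_reason != "presyncope") next
    tt <- sub$truth
    pp <- tt$sap_mmHg - tt$dap_mmHg
    expect_lt(mean(pp[tt$class == 3]), mean(pp[tt$class == 0]))
  }
})

test_that("calibration artifacts are rendered and listed as half-open intervals", {
  cfg <- synth_config(n_subjects = 1, presyncope_fraction = 0,
                      baseline_duration_s = 100, max_lbnp_duration_s = 120,
                      noise_sd_mmHg = 0, seed = 4)
  sub <- generate_subject(cfg, 1, presyncope = FALSE, seed = 905)
  arts <- sub$recording$artifact_intervals
  expect_gt(length(arts), 0)
  iv <- arts[[1]]
  seg <- sub$recording$pressure[(floor(iv[1] * 200) + 2):(floor(iv[2] * 200) - 1)]
  expect_lt(diff(range(seg)), 1e-9)  # flat line
  cfg2 <- synth_config(n_subjects = 1, presyncope_fraction = 0,
                       baseline_duration_s = 100, max_lbnp_duration_s = 120,
                       list_artifacts = FALSE, seed = 4)
  sub2 <- generate_subject(cfg2, 1, presyncope = FALSE, seed = 905)
  expect_length(sub2$recording$artifact_intervals, 0)
})
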