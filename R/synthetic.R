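#' Configuration of the synthetic hemodynamic cohort generator
#'
#' Defines a cohort of simulated lower-body negative pressure (LBNP) runs:
#' a supine baseline at latent hypovolemia severity 0, then an LBNP phase in
#' which severity ramps as a power law of normalized time. Beat morphology
#' drifts with severity (pulse pressure shrinks, the dicrotic notch
#' attenuates, heart rate rises). Presyncope subjects end in a terminal
#' vasodepressor collapse terminated by the protocol's own stop criteria;
#' tolerated subjects plateau at a sub-critical severity and run to the
#' protocol limit. Periodic cuff-calibration artifacts are rendered as short
#' flat-line segments.
#'
#' @param n_subjects Number of subjects in the cohort.
#' @param presyncope_fraction Fraction of subjects ending in presyncope;
#'   exactly `round(n_subjects * presyncope_fraction)` subjects do.
#' @param fs Sampling rate (Hz).
#' @param baseline_duration_s Supine baseline duration (s).
#' @param max_lbnp_duration_s Protocol tolerance limit for the LBNP phase (s).
#' @param hr_baseline_bpm,sap_baseline_mmHg,dap_baseline_mmHg Named
#'   `c(mean=, sd=)` pairs for between-subject baseline draws.
#' @param severity_shape Exponent of the severity ramp in normalized time
#'   (> 1 makes late-stage change faster).
#' @param onset_step_severity Severity reached immediately at LBNP onset:
#'   a single-step negative-pressure protocol pools blood within seconds, so
#'   the waveform responds as soon as the box pressure is established, before
#'   progressive decompensation sets in.
#' @param pulse_pressure_drop_frac Fractional pulse-pressure reduction at
#'   severity 1.
#' @param notch_attenuation_frac Fractional reduction of the dicrotic
#'   secondary-wave amplitude at severity 1.
#' @param hr_rise_bpm Heart-rate increase at severity 1 (bpm).
#' @param dap_drop_frac Fractional diastolic-pressure reduction at severity 1.
#' @param noise_sd_mmHg SD of additive Gaussian sample noise (mmHg).
#' @param physiocal_period_s,physiocal_duration_s Period and duration of the
#'   calibration artifacts (s).
#' @param list_artifacts If `FALSE`, artifacts are rendered but not recorded
#'   in `artifact_intervals` (to exercise downstream robustness).
#' @param severity_plateau Plateau severity of tolerated subjects.
#' @param plateau_ramp_s Time for a tolerated subject to reach the plateau (s).
#' @param collapse_time_frac Range (fractions of `max_lbnp_duration_s`) from
#'   which each presyncope subject's collapse-onset time is drawn.
#' @param collapse_sap_rate,collapse_dap_rate Terminal pressure decline rates
#'   (mmHg/min).
#' @param collapse_hr_rate Terminal heart-rate decline rate (bpm/min).
#' @param hr_jitter_frac SD of the i.i.d. beat-to-beat period jitter, as a
#'   fraction of the period.
#' @param seed Master seed; per-subject streams are derived from it.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_subjects = 15,
                         presyncope_fraction = 0.8,
                         fs = 200,
                         baseline_duration_s = 300,
                         max_lbnp_duration_s = 1800,
                         hr_baseline_bpm = c(mean = 65, sd = 5),
                         sap_baseline_mmHg = c(mean = 120, sd = 2),
                         dap_baseline_mmHg = c(mean = 70, sd = 1.5),
                         severity_shape = 2,
                         onset_step_severity = 0.15,
                         pulse_pressure_drop_frac = 0.45,
                         notch_attenuation_frac = 0.7,
                         hr_rise_bpm = 25,
                         dap_drop_frac = 0.10,
                         noise_sd_mmHg = 1.5,
                         physiocal_period_s = 70,
                         physiocal_duration_s = 2,
                         list_artifacts = TRUE,
                         severity_plateau = 0.5,
                         plateau_ramp_s = 600,
                         collapse_time_frac = c(0.40, 0.85),
                         collapse_sap_rate = 40,
                         collapse_dap_rate = 20,
                         collapse_hr_rate = 20,
                         hr_jitter_frac = 0.02,
                         seed = 1L) {
  cfg <- list(n_subjects = n_subjects, presyncope_fraction = presyncope_fraction,
              fs = fs, baseline_duration_s = baseline_duration_s,
              max_lbnp_duration_s = max_lbnp_duration_s,
              hr_baseline_bpm = hr_baseline_bpm,
              sap_baseline_mmHg = sap_baseline_mmHg,
              dap_baseline_mmHg = dap_baseline_mmHg,
              severity_shape = severity_shape,
              onset_step_severity = onset_step_severity,
              pulse_pressure_drop_frac = pulse_pressure_drop_frac,
              notch_attenuation_frac = notch_attenuation_frac,
              hr_rise_bpm = hr_rise_bpm, dap_drop_frac = dap_drop_frac,
              noise_sd_mmHg = noise_sd_mmHg,
              physiocal_period_s = physiocal_period_s,
              physiocal_duration_s = physiocal_duration_s,
              list_artifacts = isTRUE(list_artifacts),
              severity_plateau = severity_plateau,
              plateau_ramp_s = plateau_ramp_s,
              collapse_time_frac = collapse_time_frac,
              collapse_sap_rate = collapse_sap_rate,
              collapse_dap_rate = collapse_dap_rate,
              collapse_hr_rate = collapse_hr_rate,
              hr_jitter_frac = hr_jitter_frac,
              seed = seed)
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  stop_if_not_number(cfg$n_subjects, "n_subjects", lower = 1)
  stop_if_not_number(cfg$presyncope_fraction, "presyncope_fraction", 0, 1)
  stop_if_not_number(cfg$fs, "fs", lower = 1e-9)
  stop_if_not_number(cfg$baseline_duration_s, "baseline_duration_s", lower = 1e-9)
  stop_if_not_number(cfg$max_lbnp_duration_s, "max_lbnp_duration_s", lower = 1e-9)
  for (f in c("pulse_pressure_drop_frac", "notch_attenuation_frac",
              "dap_drop_frac", "severity_plateau", "hr_jitter_frac",
              "onset_step_severity")) {
    stop_if_not_number(cfg[[f]], f, 0, 1)
  }
  stop_if_not_number(cfg$severity_shape, "severity_shape", lower = 1e-9)
  stop_if_not_number(cfg$noise_sd_mmHg, "noise_sd_mmHg", lower = 0)
  stop_if_not_number(cfg$hr_rise_bpm, "hr_rise_bpm", lower = 0)
  hr_top <- cfg$hr_baseline_bpm[["mean"]] + 3 * cfg$hr_baseline_bpm[["sd"]] +
    cfg$hr_rise_bpm
  if (hr_top >= 220) stop("baseline HR plus rise must stay below 220 bpm",
                          call. = FALSE)
  if (length(cfg$collapse_time_frac) != 2L ||
      cfg$collapse_time_frac[1] <= 0 || cfg$collapse_time_frac[2] > 1 ||
      diff(cfg$collapse_time_frac) < 0) {
    stop("collapse_time_frac must be an increasing pair in (0, 1]", call. = FALSE)
  }
  invisible(cfg)
}

#' One synthetic arterial pressure beat
#'
#' Builds a single beat sampled at `fs` from three additive components: a
#' primary systolic wave, a dicrotic secondary wave whose relative amplitude
#' is scaled by `1 - severity * notch_attenuation_frac`, and an exponential
#' diastolic run-off. The waveform is affinely anchored so its minimum equals
#' `dap` and its maximum equals `sap`. Deterministic (no randomness).
#'
#' @param sap,dap Systolic and diastolic pressure targets (mmHg), `sap > dap`.
#' @param period_s Beat duration (s).
#' @param severity Latent hypovolemia severity in `[0, 1]`.
#' @param cfg A [synth_config()] (supplies `fs` and the notch attenuation).
#' @param fs Sampling rate; defaults to `cfg$fs`.
#' @return Numeric vector of `round(period_s * fs)` pressure samples.
#' @export
beat_template <- function(sap, dap, period_s, severity, cfg = synth_config(),
                          fs = cfg$fs) {
  if (sap <= dap) stop("`sap` must exceed `dap`", call. = FALSE)
  stop_if_not_number(severity, "severity", 0, 1)
  n <- max(8L, as.integer(round(period_s * fs)))
  tau <- (seq_len(n) - 1) / n
  # primary systolic wave and dicrotic secondary wave
  g1 <- exp(-(tau - 0.13)^2 / (2 * 0.045^2))
  a2 <- 0.25 * (1 - severity * cfg$notch_attenuation_frac)
  g2 <- a2 * exp(-(tau - 0.40)^2 / (2 * 0.06^2))
  s <- g1 + g2
  # exponential diastolic run-off from tau = 0.55 to the next foot
  td <- 0.55
  s_td <- exp(-(td - 0.13)^2 / (2 * 0.045^2)) + a2 * exp(-(td - 0.40)^2 / (2 * 0.06^2))
  tail_idx <- tau >= td
  s[tail_idx] <- s_td * exp(-(tau[tail_idx] - td) / 0.30)
  dap + (sap - dap) * (s - min(s)) / (max(s) - min(s))
}

# Per-beat hemodynamic state at time t for one simulated subject.
subject_state <- function(t, phase, subj, cfg) {
  B <- cfg$baseline_duration_s
  s0 <- cfg$onset_step_severity
  if (t < B) {
    sev <- 0
    dt_collapse <- 0
  } else if (subj$presyncope) {
    ramp <- min(((t - B) / subj$collapse_time_s)^cfg$severity_shape, 1)
    sev <- s0 + (1 - s0) * ramp
    dt_collapse <- max(0, t - B - subj$collapse_time_s)
  } else {
    f <- min((t - B) / cfg$plateau_ramp_s, 1)
    sev <- s0 + max(cfg$severity_plateau - s0, 0) * f^cfg$severity_shape
    dt_collapse <- 0
  }
  dap <- subj$dap0 * (1 - cfg$dap_drop_frac * sev) -
    cfg$collapse_dap_rate / 60 * dt_collapse
  pp <- subj$pp0 * (1 - cfg$pulse_pressure_drop_frac * sev)
  sap <- dap + pp - cfg$collapse_sap_rate / 60 * dt_collapse +
    cfg$collapse_dap_rate / 60 * dt_collapse
  # keep the beat physiologically valid during terminal collapse
  sap <- max(sap, 45)
  if (sap - dap < 15) dap <- sap - 15
  hr <- subj$hr0 + cfg$hr_rise_bpm * sev - cfg$collapse_hr_rate / 60 * dt_collapse
  hr <- max(hr, 35)
  list(sap = sap, dap = dap, hr = hr, severity = sev)
}

#' Generate one synthetic subject
#'
#' Simulates the per-beat hemodynamic series (SAP, DAP, HR, latent severity),
#' stops a presyncope run at the first beat where [detect_presyncope()] fires
#' on that series (so generator and detector agree by construction), renders
#' the continuous pressure signal from [beat_template()], adds sample noise,
#' and stamps periodic flat-line calibration artifacts.
#'
#' @param cfg A [synth_config()].
#' @param subject_index Index of the subject within the cohort (names the
#'   subject and, with `seed`, fixes its random stream).
#' @param presyncope Logical: does this subject end in presyncope?
#' @param seed Seed for this subject's stream (derived from the cohort seed by
#'   [generate_cohort()]).
#' @return A list with elements `recording` (a [pressure_recording()]) and
#'   `truth` (per-beat times, SAP/DAP/HR, latent severity, true class labels,
#'   end reason and presyncope time).
#' @export
generate_subject <- function(cfg, subject_index = 1L, presyncope = TRUE,
                             seed = cfg$seed) {
  validate_synth_config(cfg)
  with_seed(seed, {
    # baseline draws; reject implausible or criteria-violating combinations
    repeat {
      hr0 <- rnorm(1, cfg$hr_baseline_bpm[["mean"]], cfg$hr_baseline_bpm[["sd"]])
      sap0 <- rnorm(1, cfg$sap_baseline_mmHg[["mean"]], cfg$sap_baseline_mmHg[["sd"]])
      dap0 <- rnorm(1, cfg$dap_baseline_mmHg[["mean"]], cfg$dap_baseline_mmHg[["sd"]])
      if (hr0 < 40 || sap0 - dap0 < 25) next
      if (!presyncope) {
        # a tolerated subject must never trip the SAP-floor stop criterion
        sev <- max(cfg$severity_plateau, cfg$onset_step_severity)
        sap_plateau <- dap0 * (1 - cfg$dap_drop_frac * sev) +
          (sap0 - dap0) * (1 - cfg$pulse_pressure_drop_frac * sev)
        if (sap_plateau < 90) next
      }
      break
    }
    subj <- list(hr0 = hr0, sap0 = sap0, dap0 = dap0, pp0 = sap0 - dap0,
                 presyncope = presyncope,
                 collapse_time_s = runif(1, cfg$collapse_time_frac[1],
                                         cfg$collapse_time_frac[2]) *
                   cfg$max_lbnp_duration_s)
    B <- cfg$baseline_duration_s
    end_cap <- B + cfg$max_lbnp_duration_s
    criteria <- presyncope_criteria()

    t <- 0
    bt <- bs <- bd <- bh <- bsev <- bper <- numeric(0)
    presyncope_time <- NA_real_
    lbnp_first <- NA_integer_  # index of the first LBNP beat
    i <- 0L
    repeat {
      st <- subject_state(t, NULL, subj, cfg)
      period <- 60 / st$hr * (1 + rnorm(1, 0, cfg$hr_jitter_frac))
      period <- min(max(period, 0.3), 2.0)
      # quantize to the sample grid so rendered samples align with beat times
      period <- round(period * cfg$fs) / cfg$fs
      i <- i + 1L
      bt <- c(bt, t); bs <- c(bs, st$sap); bd <- c(bd, st$dap)
      bh <- c(bh, st$hr); bsev <- c(bsev, st$severity); bper <- c(bper, period)
      if (presyncope && t >= B) {
        if (is.na(lbnp_first)) lbnp_first <- i
        # first-trigger scan: earlier beats were checked on earlier
        # iterations, so evaluating the stop criteria on the current beat
        # reproduces detect_presyncope() on the LBNP beat series exactly
        if (criterion_fires(bt[lbnp_first:i], bs[lbnp_first:i],
                            bd[lbnp_first:i], bh[lbnp_first:i], criteria)) {
          presyncope_time <- t
          break
        }
      }
      t <- t + period
      if (t >= end_cap) break
    }

    protocol_end <- if (presyncope && !is.na(presyncope_time)) {
      presyncope_time
    } else {
      end_cap
    }
    end_reason <- if (presyncope && !is.na(presyncope_time)) "presyncope" else "tolerated"

    # render the continuous signal beat by beat
    waves <- vector("list", length(bt))
    for (i in seq_along(bt)) {
      waves[[i]] <- beat_template(bs[i], bd[i], bper[i], bsev[i], cfg)
    }
    pressure <- unlist(waves, use.names = FALSE)
    n_max <- as.integer(round((protocol_end + bper[length(bper)]) * cfg$fs))
    if (end_reason == "tolerated") n_max <- as.integer(round(end_cap * cfg$fs))
    pressure <- pressure[seq_len(min(length(pressure), n_max))]
    if (cfg$noise_sd_mmHg > 0) {
      pressure <- pressure + rnorm(length(pressure), 0, cfg$noise_sd_mmHg)
    }

    # periodic flat-line calibration artifacts at the running diastolic level
    t_end <- length(pressure) / cfg$fs
    art <- list()
    w0 <- cfg$physiocal_period_s
    while (w0 + cfg$physiocal_duration_s <= t_end) {
      idx <- seq.int(floor(w0 * cfg$fs) + 1, ceiling((w0 + cfg$physiocal_duration_s) * cfg$fs))
      idx <- idx[idx <= length(pressure)]
      beat_i <- findInterval(w0, bt)
      pressure[idx] <- bd[max(beat_i, 1L)]
      art[[length(art) + 1L]] <- c(w0, w0 + cfg$physiocal_duration_s)
      w0 <- w0 + cfg$physiocal_period_s
    }

    marks <- protocol_marks(0, B, protocol_end, end_reason,
                            tolerance_duration_s = if (end_reason == "tolerated")
                              cfg$max_lbnp_duration_s else NULL)
    rec <- pressure_recording(subject_id = sprintf("S%02d", subject_index),
                              pressure = pressure, fs = cfg$fs, t0 = 0,
                              marks = marks,
                              artifact_intervals = if (cfg$list_artifacts) art else list())
    keep <- bt <= protocol_end
    truth <- list(subject_id = rec$subject_id,
                  end_reason = end_reason,
                  presyncope_time_s = if (end_reason == "presyncope") presyncope_time else NULL,
                  beat_onset_s = bt[keep],
                  sap_mmHg = bs[keep], dap_mmHg = bd[keep], hr_bpm = bh[keep],
                  severity = bsev[keep],
                  class = assign_classes(bt[keep], marks))
    list(recording = rec, truth = truth)
  })
}

#' Generate a reproducible synthetic cohort
#'
#' Exactly `round(n_subjects * presyncope_fraction)` subjects end in
#' presyncope (the first ones by index); the rest tolerate the full LBNP
#' phase. Per-subject random streams are derived from `cfg$seed`, so cohorts
#' are bit-reproducible and subjects independent.
#'
#' @param cfg A [synth_config()].
#' @return List of per-subject `list(recording, truth)` pairs.
#' @export
generate_cohort <- function(cfg = synth_config()) {
  validate_synth_config(cfg)
  n <- as.integer(cfg$n_subjects)
  n_pre <- as.integer(round(n * cfg$presyncope_fraction))
  seeds <- derive_seeds(cfg$seed, n, stream = 11L)
  lapply(seq_len(n), function(i) {
    generate_subject(cfg, subject_index = i, presyncope = i <= n_pre,
                     seed = seeds[i])
  })
}
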