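#' Segment a continuous pressure recording into beats
#'
#' Foot-to-foot beat detection: the first difference of the signal is
#' low-pass filtered (default 10 Hz cutoff, 2nd-order Butterworth applied
#' forward-backward), candidate upstrokes are the local maxima of the
#' filtered derivative above an adaptive threshold with a refractory period,
#' and each beat's foot is the local pressure minimum preceding its steepest
#' upstroke. Beats with duration outside the physiologic band or pulse
#' pressure below `min_pp_mmHg` are discarded.
#'
#' @param rec A [pressure_recording()].
#' @param min_duration_s,max_duration_s Physiologic validity band for the
#'   beat duration (s).
#' @param min_pp_mmHg Minimum pulse pressure (mmHg).
#' @param deriv_cutoff_hz Low-pass cutoff for the derivative (Hz).
#' @param refractory_s Minimum spacing between successive upstrokes (s).
#' @return A list of beats, each a list with `subject_id`, `onset_s`,
#'   `duration_s`, `raw` (foot-to-foot samples, mmHg), `sap_mmHg`,
#'   `dap_mmHg`, `map_mmHg`, `hr_bpm`. A flat recording (total range below
#'   1 mmHg) yields an empty list with a warning.
#' @export
detect_beats <- function(rec, min_duration_s = 0.25, max_duration_s = 2.5,
                         min_pp_mmHg = 10, deriv_cutoff_hz = 10,
                         refractory_s = 0.25) {
  stopifnot(inherits(rec, "pressure_recording"))
  p <- rec$pressure
  fs <- rec$fs
  if (length(p) < 2 * fs) stop("recording must span at least 2 s", call. = FALSE)
  if (diff(range(p)) < 1) {
    warning("flat signal (range < 1 mmHg): no beats detected")
    return(list())
  }
  d <- c(0, diff(p)) * fs
  wc <- min(deriv_cutoff_hz / (fs / 2), 0.99)
  bf <- signal::butter(2, wc, type = "low")
  ds <- signal::filtfilt(bf, d)
  # 0.35 of the 99th derivative percentile separates primary upstrokes from
  # dicrotic secondary waves (about 4-5x weaker) across the physiologic range
  thr <- 0.35 * stats::quantile(ds, 0.99, names = FALSE)
  if (thr <= 0) {
    warning("no positive upstrokes found: no beats detected")
    return(list())
  }
  above <- ds > thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  peaks <- vapply(runs, function(k) {
    i0 <- starts[k]; i1 <- ends[k]
    i0 - 1L + which.max(ds[i0:i1])
  }, integer(1))
  # refractory: greedy left-to-right
  refr <- as.integer(round(refractory_s * fs))
  keep <- integer(0)
  last <- -Inf
  for (pk in peaks) {
    if (pk - last >= refr) {
      keep <- c(keep, pk)
      last <- pk
    }
  }
  if (length(keep) < 2L) return(list())
  # foot: last minimum of the pressure within the search window preceding
  # the steepest upstroke
  win <- as.integer(round(refractory_s * fs))
  feet <- vapply(keep, function(pk) {
    lo <- max(1L, pk - win)
    seg <- p[lo:pk]
    lo - 1L + max(which(seg == min(seg)))
  }, integer(1))
  feet <- unique(feet)
  beats <- vector("list", length(feet) - 1L)
  nb <- 0L
  for (i in seq_len(length(feet) - 1L)) {
    i0 <- feet[i]; i1 <- feet[i + 1L]
    dur <- (i1 - i0) / fs
    if (dur < min_duration_s || dur > max_duration_s) next
    raw <- p[i0:(i1 - 1L)]
    sap <- max(raw); dap <- min(raw)
    if (sap - dap < min_pp_mmHg) next
    if (length(raw) < 4L) next
    nb <- nb + 1L
    beats[[nb]] <- list(subject_id = rec$subject_id,
                        onset_s = rec$t0 + (i0 - 1L) / fs,
                        duration_s = dur,
                        raw = raw,
                        sap_mmHg = sap, dap_mmHg = dap,
                        map_mmHg = mean(raw), hr_bpm = 60 / dur)
  }
  beats[seq_len(nb)]
}

#' Remove beats overlapping calibration-artifact intervals
#'
#' A beat spanning `[onset, onset + duration)` is removed when it overlaps
#' any half-open artifact interval `[start, end)`; beats that merely touch an
#' interval boundary are kept. Order is preserved.
#'
#' @param beats List of beats from [detect_beats()].
#' @param intervals List of half-open `c(start, end)` intervals (s).
#' @return The filtered beat list.
#' @export
remove_calibration_beats <- function(beats, intervals) {
  if (length(intervals) == 0L || length(beats) == 0L) return(beats)
  keep <- vapply(beats, function(b) {
    a0 <- b$onset_s
    a1 <- b$onset_s + b$duration_s
    for (iv in intervals) {
      if (a0 < iv[2] && iv[1] < a1) return(FALSE)
    }
    TRUE
  }, logical(1))
  beats[keep]
}

#' Resample one beat to a fixed-length 33-sample shape vector
#'
#' Monotone cubic Hermite interpolation (Fritsch–Carlson tangents, via
#' `stats::splinefun(method = "monoH.FC")`) of the raw foot-to-foot samples,
#' evaluated at `n_samples` uniformly spaced points spanning the beat
#' (first point = foot sample, last point = final raw sample). Pressure
#' amplitude is not rescaled: values stay in mmHg. On monotone segments the
#' interpolant is range-preserving (no overshoot); at extrema of noisy data
#' any overshoot is bounded by the local sample-to-sample noise.
#'
#' @param beat One beat from [detect_beats()] (needs at least 4 raw samples).
#' @param n_samples Output length (default 33).
#' @return Numeric vector of length `n_samples`.
#' @export
resample_beat <- function(beat, n_samples = 33L) {
  raw <- if (is.list(beat)) beat$raw else beat
  if (length(raw) < 4L) stop("beat must contain at least 4 raw samples",
                             call. = FALSE)
  x <- seq(0, 1, length.out = length(raw))
  f <- stats::splinefun(x, raw, method = "monoH.FC")
  f(seq(0, 1, length.out = n_samples))
}

#' Build the labeled beat matrix for a set of recordings
#'
#' Runs detection, calibration-beat removal and fixed-length resampling per
#' recording, attaches ordinal class labels from each recording's protocol
#' marks ([assign_classes()]; beats after protocol end are dropped), and
#' concatenates across subjects. Recordings yielding no usable beats are
#' excluded with a warning.
#'
#' @param recordings A list of [pressure_recording()] objects (or a cohort
#'   from [generate_cohort()], whose `recording` elements are used).
#' @param n_samples Samples per normalized beat (default 33).
#' @param ... Passed to [detect_beats()].
#' @return An object of class `beat_matrix`: list with `values`
#'   (`n_beats x n_samples` matrix, mmHg), `label`, `subject_id`, `onset_s`,
#'   `duration_s`, `sap_mmHg`, `dap_mmHg`, `hr_bpm`, and `marks` (named list
#'   of per-subject protocol marks).
#' @export
build_beat_matrix <- function(recordings, n_samples = 33L, ...) {
  if (length(recordings) == 0L) stop("need at least one recording", call. = FALSE)
  recs <- lapply(recordings, function(r) {
    if (inherits(r, "pressure_recording")) r else r$recording
  })
  rows <- list(); lab <- integer(0); sid <- character(0)
  ons <- dur <- sap <- dap <- hr <- numeric(0)
  marks <- list()
  for (rec in recs) {
    beats <- detect_beats(rec, ...)
    beats <- remove_calibration_beats(beats, rec$artifact_intervals)
    if (length(beats) > 0L) {
      cls <- assign_classes(vapply(beats, `[[`, numeric(1), "onset_s"), rec$marks)
      beats <- beats[!is.na(cls)]
      cls <- cls[!is.na(cls)]
    } else {
      cls <- integer(0)
    }
    if (length(beats) == 0L) {
      warning(sprintf("subject %s yielded no usable beats and is excluded",
                      rec$subject_id))
      next
    }
    rows[[length(rows) + 1L]] <-
      t(vapply(beats, resample_beat, numeric(n_samples), n_samples = n_samples))
    lab <- c(lab, cls)
    sid <- c(sid, vapply(beats, `[[`, character(1), "subject_id"))
    ons <- c(ons, vapply(beats, `[[`, numeric(1), "onset_s"))
    dur <- c(dur, vapply(beats, `[[`, numeric(1), "duration_s"))
    sap <- c(sap, vapply(beats, `[[`, numeric(1), "sap_mmHg"))
    dap <- c(dap, vapply(beats, `[[`, numeric(1), "dap_mmHg"))
    hr <- c(hr, vapply(beats, `[[`, numeric(1), "hr_bpm"))
    marks[[rec$subject_id]] <- rec$marks
  }
  if (length(rows) == 0L) stop("no recording yielded any usable beats", call. = FALSE)
  structure(list(values = do.call(rbind, rows),
                 label = lab, subject_id = sid, onset_s = ons,
                 duration_s = dur, sap_mmHg = sap, dap_mmHg = dap,
                 hr_bpm = hr, marks = marks),
            class = "beat_matrix")
}

#' @export
print.beat_matrix <- function(x, ...) {
  cat(sprintf("<beat_matrix> %d beats x %d samples, %d subject(s)\n",
              nrow(x$values), ncol(x$values), length(unique(x$subject_id))))
  print(table(class = x$label))
  invisible(x)
}

# Subset a beat_matrix by row index, keeping bookkeeping aligned.
subset_beats <- function(bm, idx) {
  structure(list(values = bm$values[idx, , drop = FALSE],
                 label = bm$label[idx], subject_id = bm$subject_id[idx],
                 onset_s = bm$onset_s[idx], duration_s = bm$duration_s[idx],
                 sap_mmHg = bm$sap_mmHg[idx], dap_mmHg = bm$dap_mmHg[idx],
                 hr_bpm = bm$hr_bpm[idx],
                 marks = bm$marks[intersect(names(bm$marks),
                                            unique(bm$subject_id[idx]))]),
            class = "beat_matrix")
}
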