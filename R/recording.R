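#' Protocol event marks for one recording
#'
#' Times (seconds, relative to the recording clock) of the protocol phases of
#' a lower-body negative pressure (LBNP) run: start of supine baseline, LBNP
#' onset, and protocol end. `end_reason` records whether the run was
#' terminated by presyncope criteria or tolerated to the protocol limit.
#'
#' @param baseline_start_s Start of the supine baseline phase (s).
#' @param lbnp_onset_s Onset of negative pressure (s); must exceed
#'   `baseline_start_s`.
#' @param protocol_end_s End of the protocol (s); must exceed `lbnp_onset_s`.
#' @param end_reason `"presyncope"` or `"tolerated"`.
#' @param tolerance_duration_s Optional: the configured tolerance limit. When
#'   given and `end_reason = "tolerated"`, the LBNP segment must span at least
#'   this duration.
#' @return An object of class `protocol_marks`.
#' @export
protocol_marks <- function(baseline_start_s, lbnp_onset_s, protocol_end_s,
                           end_reason = c("presyncope", "tolerated"),
                           tolerance_duration_s = NULL) {
  end_reason <- match.arg(end_reason)
  stop_if_not_number(baseline_start_s, "baseline_start_s")
  stop_if_not_number(lbnp_onset_s, "lbnp_onset_s")
  stop_if_not_number(protocol_end_s, "protocol_end_s")
  if (lbnp_onset_s <= baseline_start_s) {
    stop("`lbnp_onset_s` must be greater than `baseline_start_s`", call. = FALSE)
  }
  if (protocol_end_s <= lbnp_onset_s) {
    stop("`protocol_end_s` must be greater than `lbnp_onset_s`", call. = FALSE)
  }
  if (!is.null(tolerance_duration_s) && end_reason == "tolerated" &&
      (protocol_end_s - lbnp_onset_s) < tolerance_duration_s - 1e-9) {
    stop("tolerated runs must span at least the tolerance duration", call. = FALSE)
  }
  structure(list(baseline_start_s = baseline_start_s,
                 lbnp_onset_s = lbnp_onset_s,
                 protocol_end_s = protocol_end_s,
                 end_reason = end_reason),
            class = "protocol_marks")
}

#' Continuous arterial pressure recording for one subject
#'
#' Container for a uniformly sampled finger arterial pressure tracing with its
#' protocol marks and any calibration-artifact intervals (e.g. the finger-cuff
#' device's periodic self-calibration, which corrupts the waveform).
#' Intervals are half-open `[start, end)` in seconds.
#'
#' @param subject_id Subject identifier (character scalar).
#' @param pressure Numeric vector of pressure samples (mmHg).
#' @param fs Sampling rate in Hz (default 200).
#' @param t0 Recording start time in seconds (default 0).
#' @param marks A [protocol_marks()] object.
#' @param artifact_intervals List of length-2 numeric vectors `c(start, end)`,
#'   half-open, each contained in the recorded time span.
#' @return An object of class `pressure_recording`.
#' @export
pressure_recording <- function(subject_id, pressure, fs = 200, t0 = 0, marks,
                               artifact_intervals = list()) {
  stopifnot(is.character(subject_id), length(subject_id) == 1L)
  stop_if_not_number(fs, "fs", lower = 1e-9)
  stop_if_not_number(t0, "t0")
  if (!is.numeric(pressure) || length(pressure) < 1L) {
    stop("`pressure` must contain at least one sample", call. = FALSE)
  }
  if (!inherits(marks, "protocol_marks")) {
    stop("`marks` must be a protocol_marks object", call. = FALSE)
  }
  t_end <- t0 + length(pressure) / fs
  for (iv in artifact_intervals) {
    if (length(iv) != 2L || iv[1] >= iv[2]) {
      stop("artifact intervals must be increasing length-2 vectors", call. = FALSE)
    }
    if (iv[1] < t0 - 1e-9 || iv[2] > t_end + 1e-9) {
      stop("artifact interval outside the recorded time span", call. = FALSE)
    }
  }
  structure(list(subject_id = subject_id,
                 fs = fs,
                 pressure = as.numeric(pressure),
                 t0 = t0,
                 marks = marks,
                 artifact_intervals = artifact_intervals),
            class = "pressure_recording")
}

#' @export
print.pressure_recording <- function(x, ...) {
  dur <- length(x$pressure) / x$fs
  cat(sprintf("<pressure_recording> subject %s: %.1f s at %g Hz (%d samples)\n",
              x$subject_id, dur, x$fs, length(x$pressure)))
  cat(sprintf("  baseline %.1f s | LBNP onset %.1f s | end %.1f s (%s)\n",
              x$marks$baseline_start_s, x$marks$lbnp_onset_s,
              x$marks$protocol_end_s, x$marks$end_reason))
  cat(sprintf("  %d artifact interval(s)\n", length(x$artifact_intervals)))
  invisible(x)
}
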