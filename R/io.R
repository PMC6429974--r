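# On-disk dialect: signal = two-column CSV (time_s, pressure_mmHg) with a
# header; marks = a YAML document holding subject id, sampling rate, protocol
# marks and optional artifact intervals. Times are seconds; intervals are
# half-open [start, end).

#' Write a pressure recording to a signal CSV and a marks YAML file
#'
#' The signal file holds `time_s, pressure_mmHg` rows; the marks file holds
#' the subject id, sampling rate, protocol marks and (when present) artifact
#' intervals. The pair round-trips through [read_recording()] with pressures
#' preserved to well below 1e-9 mmHg.
#'
#' @param rec A [pressure_recording()] object.
#' @param signal_path,marks_path Output file paths.
#' @return Invisibly, `rec`.
#' @export
write_recording <- function(rec, signal_path, marks_path) {
  stopifnot(inherits(rec, "pressure_recording"))
  n <- length(rec$pressure)
  tab <- data.table::data.table(
    time_s = rec$t0 + (seq_len(n) - 1) / rec$fs,
    pressure_mmHg = rec$pressure
  )
  data.table::fwrite(tab, signal_path)
  doc <- list(subject_id = rec$subject_id,
              fs = rec$fs,
              t0 = rec$t0,
              marks = unclass(rec$marks))
  if (length(rec$artifact_intervals) > 0) {
    doc$artifact_intervals <- lapply(rec$artifact_intervals, as.numeric)
  }
  yaml::write_yaml(doc, marks_path, precision = 15L)
  invisible(rec)
}

#' Read a pressure recording from a signal CSV and a marks YAML file
#'
#' The signal file must have strictly increasing, uniformly spaced time (the
#' sampling rate is inferred as the reciprocal of the spacing; deviations from
#' uniformity beyond one part in 1e6 are rejected). If the marks document
#' declares a sampling rate it must agree with the inferred one.
#'
#' @param signal_path Path to the two-column signal CSV.
#' @param marks_path Path to the marks YAML document.
#' @return A [pressure_recording()] object.
#' @export
read_recording <- function(signal_path, marks_path) {
  tab <- data.table::fread(signal_path)
  if (ncol(tab) < 2L || !all(c("time_s", "pressure_mmHg") %in% names(tab))) {
    stop("signal file must have columns time_s and pressure_mmHg", call. = FALSE)
  }
  tt <- tab$time_s
  if (length(tt) < 1L) stop("signal file is empty", call. = FALSE)
  if (length(tt) >= 2L) {
    dt <- diff(tt)
    if (any(dt <= 0)) stop("time column must be strictly increasing", call. = FALSE)
    dt0 <- stats::median(dt)
    if (max(abs(dt - dt0)) > 1e-6 * dt0) {
      stop("non-uniform sampling beyond 1 part in 1e6", call. = FALSE)
    }
    fs <- 1 / dt0
  } else {
    fs <- NA_real_
  }
  doc <- yaml::read_yaml(marks_path)
  need <- c("baseline_start_s", "lbnp_onset_s", "protocol_end_s", "end_reason")
  if (is.null(doc$marks) || !all(need %in% names(doc$marks))) {
    stop("marks document is missing required protocol mark fields", call. = FALSE)
  }
  if (!is.null(doc$fs)) {
    if (is.na(fs)) {
      fs <- doc$fs
    } else if (abs(doc$fs - fs) > 1e-6 * doc$fs) {
      stop(sprintf("declared fs (%g Hz) disagrees with inferred fs (%g Hz)",
                   doc$fs, fs), call. = FALSE)
    }
  }
  if (is.na(fs)) stop("cannot infer fs from a single sample without a declared fs",
                      call. = FALSE)
  marks <- protocol_marks(doc$marks$baseline_start_s, doc$marks$lbnp_onset_s,
                          doc$marks$protocol_end_s, doc$marks$end_reason)
  arts <- lapply(doc$artifact_intervals %||% list(), as.numeric)
  pressure_recording(subject_id = doc$subject_id %||% "unknown",
                     pressure = tab$pressure_mmHg,
                     fs = fs,
                     t0 = doc$t0 %||% tt[1],
                     marks = marks,
                     artifact_intervals = arts)
}

#' Write a synthetic cohort to per-subject signal and marks files
#'
#' @param cohort A list as returned by [generate_cohort()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, a data frame with one row per subject: subject id, end
#'   reason and (for presyncope subjects) the presyncope time; also written to
#'   `ground_truth.csv` in `dir`.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  info <- lapply(cohort, function(subj) {
    id <- subj$recording$subject_id
    write_recording(subj$recording,
                    file.path(dir, paste0(id, "_signal.csv")),
                    file.path(dir, paste0(id, "_marks.yaml")))
    data.frame(subject_id = id,
               end_reason = subj$recording$marks$end_reason,
               presyncope_time_s = subj$truth$presyncope_time_s %||% NA_real_)
  })
  info <- do.call(rbind, info)
  data.table::fwrite(info, file.path(dir, "ground_truth.csv"))
  invisible(info)
}
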