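#' Presyncope stop criteria
#'
#' Thresholds of the protocol's hemodynamic stop criteria: an absolute
#' systolic floor, and trailing-window decline rates for systolic pressure,
#' diastolic pressure and heart rate. Decline is measured as the maximum of
#' the series within the trailing window minus the current value, so a
#' "25 mmHg/min" criterion means a 25 mmHg total decline over the 60-s window.
#'
#' @param sap_floor_mmHg Absolute systolic floor (mmHg).
#' @param sap_drop_rate SAP decline threshold (mmHg per window).
#' @param dap_drop_rate DAP decline threshold (mmHg per window).
#' @param hr_drop_rate HR decline threshold (bpm per window).
#' @param window_s Trailing window length (s).
#' @return An object of class `presyncope_criteria`.
#' @export
presyncope_criteria <- function(sap_floor_mmHg = 80, sap_drop_rate = 25,
                                dap_drop_rate = 15, hr_drop_rate = 15,
                                window_s = 60) {
  for (f in c("sap_floor_mmHg", "sap_drop_rate", "dap_drop_rate",
              "hr_drop_rate", "window_s")) {
    stop_if_not_number(get(f), f, lower = 1e-9)
  }
  structure(list(sap_floor_mmHg = sap_floor_mmHg, sap_drop_rate = sap_drop_rate,
                 dap_drop_rate = dap_drop_rate, hr_drop_rate = hr_drop_rate,
                 window_s = window_s),
            class = "presyncope_criteria")
}

# Do the stop criteria hold at the final beat of the given series?
# Windows shorter than `window_s` of history evaluate only the SAP floor.
criterion_fires <- function(times, sap, dap, hr, criteria) {
  i <- length(times)
  if (sap[i] < criteria$sap_floor_mmHg) return(TRUE)
  if (times[i] - times[1] < criteria$window_s) return(FALSE)
  win <- which(times > times[i] - criteria$window_s)
  if (max(sap[win]) - sap[i] >= criteria$sap_drop_rate) return(TRUE)
  if (max(dap[win]) - dap[i] >= criteria$dap_drop_rate) return(TRUE)
  if (max(hr[win]) - hr[i] >= criteria$hr_drop_rate) return(TRUE)
  FALSE
}

#' First time the presyncope criteria fire on a beat-wise series
#'
#' Scans aligned per-beat SAP/DAP/HR series and returns the earliest beat
#' time at which ANY criterion holds: (a) SAP below the floor; (b) SAP
#' decline over the trailing window at least `sap_drop_rate`; (c) likewise
#' for DAP; (d) likewise for HR. Beats with less than one full window of
#' history evaluate only criterion (a). The criteria are disjunctive, the
#' usual convention for safety stop rules.
#'
#' @param times_s Beat times (s), increasing.
#' @param sap_series,dap_series,hr_series Aligned per-beat series.
#' @param criteria A [presyncope_criteria()] object.
#' @return The first trigger time (s), or `NA_real_` if no criterion ever
#'   fires.
#' @export
detect_presyncope <- function(times_s, sap_series, dap_series, hr_series,
                              criteria = presyncope_criteria()) {
  n <- length(times_s)
  if (n == 0L) stop("empty series", call. = FALSE)
  stopifnot(length(sap_series) == n, length(dap_series) == n,
            length(hr_series) == n)
  for (i in seq_len(n)) {
    if (criterion_fires(times_s[seq_len(i)], sap_series[seq_len(i)],
                        dap_series[seq_len(i)], hr_series[seq_len(i)],
                        criteria)) {
      return(times_s[i])
    }
  }
  NA_real_
}

#' Assign ordinal hypovolemia classes from protocol marks
#'
#' Beats during supine baseline (onset before LBNP onset) get class 0.
#' LBNP beats are classed by the elapsed fraction
#' `f = (onset - lbnp_onset) / (protocol_end - lbnp_onset)` into right-closed
#' tertiles: `f` in `[0, 1/3]` is class 1, `(1/3, 2/3]` class 2, and
#' `(2/3, 1]` class 3 (so `f = 0` gets class 1 and `f = 1` class 3). Beats
#' after the protocol end get `NA` and should be dropped by the caller.
#'
#' @param onset_s Beat onset times (s).
#' @param marks A [protocol_marks()] object.
#' @return Integer vector of classes in `{0, 1, 2, 3}`, `NA` after protocol
#'   end.
#' @export
assign_classes <- function(onset_s, marks) {
  if (!inherits(marks, "protocol_marks")) {
    stop("`marks` must be a protocol_marks object", call. = FALSE)
  }
  L <- marks$protocol_end_s - marks$lbnp_onset_s
  if (L <= 0) stop("protocol end must be after LBNP onset", call. = FALSE)
  f <- (onset_s - marks$lbnp_onset_s) / L
  cls <- ifelse(onset_s < marks$lbnp_onset_s, 0L,
         ifelse(f <= 1 / 3, 1L,
         ifelse(f <= 2 / 3, 2L,
         ifelse(f <= 1, 3L, NA_integer_))))
  as.integer(cls)
}
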