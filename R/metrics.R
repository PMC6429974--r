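#' Trailing moving average
#'
#' Trailing-window mean: position `i` averages the most recent
#' `min(i, window)` values, so the first `window - 1` positions average over
#' the available history only and the output has the input's length.
#'
#' @param x Numeric trace.
#' @param window Window length in beats (>= 1).
#' @return Numeric vector, same length as `x`.
#' @export
moving_average <- function(x, window = 20L) {
  if (length(x) == 0L) stop("empty trace", call. = FALSE)
  stop_if_not_number(window, "window", lower = 1)
  window <- as.integer(window)
  if (window == 1L) return(as.numeric(x))
  cs <- cumsum(as.numeric(x))
  lagged <- c(rep(0, window), head(cs, -window))[seq_along(x)]
  (cs - lagged) / pmin(seq_along(x), window)
}

#' Confusion matrix over the four ordinal classes
#'
#' Rows are true classes 0..3, columns predicted classes 0..3. Continuous
#' predictions should be discretized first with the package tie rule (exact
#' halves round toward the lower class).
#'
#' @param true,predicted Integer vectors with values in `{0, 1, 2, 3}`.
#' @return A 4x4 integer matrix of counts.
#' @export
confusion_matrix <- function(true, predicted) {
  stopifnot(length(true) == length(predicted))
  if (any(!true %in% 0:3) || any(!predicted %in% 0:3)) {
    stop("labels must lie in {0, 1, 2, 3}", call. = FALSE)
  }
  tab <- table(factor(true, levels = 0:3), factor(predicted, levels = 0:3))
  m <- matrix(as.integer(tab), 4L, 4L,
              dimnames = list(true = 0:3, predicted = 0:3))
  m
}

#' Cohen's kappa from a confusion matrix
#'
#' Chance-corrected agreement: `kappa = (p_o - p_e) / (1 - p_e)` with
#' observed agreement `p_o = trace/N` and expected agreement
#' `p_e = sum_c row_c * col_c / N^2`. A degenerate table with `p_e = 1`
#' (all mass in one cell) returns 0 by convention.
#'
#' @param confusion A square count matrix.
#' @return Kappa in `[-1, 1]`.
#' @export
cohen_kappa <- function(confusion) {
  stopifnot(is.matrix(confusion), nrow(confusion) == ncol(confusion))
  N <- sum(confusion)
  if (N <= 0) stop("empty confusion matrix", call. = FALSE)
  po <- sum(diag(confusion)) / N
  pe <- sum(rowSums(confusion) * colSums(confusion)) / N^2
  if (1 - pe < 1e-12) return(0)
  (po - pe) / (1 - pe)
}

#' Per-class accuracy and mean squared error of a severity trace
#'
#' For each true class `c`: accuracy is the percentage of class-`c` beats
#' whose rounded trace (halves toward the lower class) equals `c`; MSE is the
#' mean of `(trace - c)^2` over class-`c` beats, computed on the continuous
#' trace. Classes absent from the input get `NA` and are excluded from
#' cohort medians downstream.
#'
#' @param label True classes in `{0, 1, 2, 3}`.
#' @param trace Continuous averaged severity trace, aligned with `label`.
#' @return A list: `per_class` (data frame with class, n, accuracy, mse),
#'   `overall_accuracy` (%), `overall_mse`.
#' @export
per_class_metrics <- function(label, trace) {
  stopifnot(length(label) == length(trace))
  if (any(!label %in% 0:3)) stop("labels must lie in {0, 1, 2, 3}", call. = FALSE)
  rounded <- round_half_down(trace)
  per <- lapply(0:3, function(cc) {
    sel <- label == cc
    if (!any(sel)) {
      data.frame(class = cc, n = 0L, accuracy = NA_real_, mse = NA_real_)
    } else {
      data.frame(class = cc, n = sum(sel),
                 accuracy = 100 * mean(rounded[sel] == cc),
                 mse = mean((trace[sel] - cc)^2))
    }
  })
  list(per_class = do.call(rbind, per),
       overall_accuracy = 100 * mean(rounded == label),
       overall_mse = mean((trace - label)^2))
}

#' Median [IQR] cohort table and pooled kappa
#'
#' Aggregates per-subject metrics into the cohort report: median and IQR
#' (25th–75th percentile, linear interpolation of order statistics) across
#' subjects of the per-class accuracies and MSEs and of the overall metrics,
#' plus a single pooled kappa computed on the summed confusion matrix (not
#' the mean of per-subject kappas).
#'
#' @param metrics_list List of [per_class_metrics()] results, one per subject.
#' @param confusions Optional list of per-subject confusion matrices; when
#'   given, the pooled kappa of their sum is reported.
#' @return A list: `table` (data frame with metric, class, median, q25, q75,
#'   iqr, n_subjects) and `pooled_kappa` (or `NA` without `confusions`).
#' @export
aggregate_cohort <- function(metrics_list, confusions = NULL) {
  stopifnot(length(metrics_list) >= 1L)
  rows <- list()
  grab <- function(metric, cls, vals) {
    vals <- vals[!is.na(vals)]
    if (length(vals) == 0L) {
      data.frame(metric = metric, class = cls, median = NA_real_,
                 q25 = NA_real_, q75 = NA_real_, iqr = NA_real_, n_subjects = 0L)
    } else {
      q <- quantile6(vals, c(0.25, 0.5, 0.75))
      data.frame(metric = metric, class = cls, median = q[2], q25 = q[1],
                 q75 = q[3], iqr = q[3] - q[1], n_subjects = length(vals))
    }
  }
  for (cc in 0:3) {
    acc <- vapply(metrics_list, function(m) m$per_class$accuracy[m$per_class$class == cc],
                  numeric(1))
    mse <- vapply(metrics_list, function(m) m$per_class$mse[m$per_class$class == cc],
                  numeric(1))
    rows[[length(rows) + 1L]] <- grab("accuracy", as.character(cc), acc)
    rows[[length(rows) + 1L]] <- grab("mse", as.character(cc), mse)
  }
  rows[[length(rows) + 1L]] <-
    grab("accuracy", "overall",
         vapply(metrics_list, `[[`, numeric(1), "overall_accuracy"))
  rows[[length(rows) + 1L]] <-
    grab("mse", "overall", vapply(metrics_list, `[[`, numeric(1), "overall_mse"))
  pooled_kappa <- NA_real_
  if (!is.null(confusions) && length(confusions) > 0L) {
    pooled_kappa <- cohen_kappa(Reduce(`+`, confusions))
  }
  list(table = do.call(rbind, rows), pooled_kappa = pooled_kappa)
}

#' Classify a held-out severity trace as increasing or stagnating
#'
#' Operationalizes the cohort phenotypes: an "increase" trace keeps rising
#' into the terminal part of the LBNP phase, a "stagnation" trace levels off
#' early (no further progression toward the critical stage). The call
#' compares the mean trace over the final `tail_fraction` of the LBNP
#' segment with the mean over the mid-LBNP reference window (40–60% of the
#' segment): `"increase"` iff the tail exceeds the reference by at least
#' `delta` classes.
#'
#' @param trace Continuous averaged severity trace.
#' @param onset_s Beat onset times aligned with `trace`.
#' @param marks The subject's [protocol_marks()].
#' @param delta Required rise in classes (default 0.5).
#' @param tail_fraction Fraction of the LBNP segment forming the terminal
#'   window (default 0.10).
#' @return `"increase"` or `"stagnation"`.
#' @export
severity_trend <- function(trace, onset_s, marks, delta = 0.5,
                           tail_fraction = 0.10) {
  stopifnot(length(trace) == length(onset_s))
  if (!any(onset_s < marks$lbnp_onset_s)) {
    stop("trace has no baseline beats", call. = FALSE)
  }
  L <- marks$protocol_end_s - marks$lbnp_onset_s
  tail_sel <- onset_s >= marks$protocol_end_s - tail_fraction * L &
    onset_s <= marks$protocol_end_s
  mid_sel <- onset_s >= marks$lbnp_onset_s + 0.40 * L &
    onset_s <= marks$lbnp_onset_s + 0.60 * L
  if (!any(tail_sel) || !any(mid_sel)) {
    stop("trace does not cover the LBNP segment", call. = FALSE)
  }
  if (mean(trace[tail_sel]) - mean(trace[mid_sel]) >= delta) "increase"
  else "stagnation"
}
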