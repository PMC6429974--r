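#' Evaluation protocol configuration
#'
#' Parameters of the leave-one-subject-out bootstrap protocol: per held-out
#' subject, 10 independent random subsamples of 10% of the pooled remaining
#' training beats are drawn, 10 models are trained and applied to the whole
#' held-out recording, each discrete trace is smoothed with a 20-beat
#' trailing moving average, and the 10 smoothed traces are averaged into the
#' final continuous severity trace.
#'
#' @param n_bootstrap Number of subsample models per fold.
#' @param subsample_fraction Fraction of the pooled training beats per draw.
#' @param smooth_window_beats Moving-average window (beats).
#' @param C_grid Penalty grid for [c_grid_sweep()].
#' @param C Default penalty for single evaluations.
#' @param k_components Number of principal components.
#' @param pca_scope `"fold"` (default; basis refit on each fold's training
#'   pool, no held-out leakage) or `"global"` (single basis over all training
#'   subjects).
#' @param with_replacement Draw subsamples with replacement (classical
#'   bootstrap) instead of without.
#' @param trend_delta,trend_tail_fraction Passed to [severity_trend()].
#' @param max_redraws Maximum redraws of a subsample containing fewer than
#'   two classes.
#' @param seed Protocol seed; all fold and draw streams derive from it.
#' @return An object of class `eval_config`.
#' @export
eval_config <- function(n_bootstrap = 10L, subsample_fraction = 0.10,
                        smooth_window_beats = 20L,
                        C_grid = c(0.001, 0.01, 0.1, 1, 10, 100),
                        C = 0.01, k_components = 5L,
                        pca_scope = c("fold", "global"),
                        with_replacement = FALSE,
                        trend_delta = 0.5, trend_tail_fraction = 0.10,
                        max_redraws = 100L, seed = 1L) {
  pca_scope <- match.arg(pca_scope)
  stop_if_not_number(n_bootstrap, "n_bootstrap", lower = 1)
  stop_if_not_number(subsample_fraction, "subsample_fraction", 1e-12, 1)
  stop_if_not_number(smooth_window_beats, "smooth_window_beats", lower = 1)
  if (length(C_grid) < 1L || any(C_grid <= 0)) {
    stop("`C_grid` must contain positive values", call. = FALSE)
  }
  stop_if_not_number(C, "C", lower = 1e-12)
  stop_if_not_number(k_components, "k_components", lower = 1)
  structure(list(n_bootstrap = as.integer(n_bootstrap),
                 subsample_fraction = subsample_fraction,
                 smooth_window_beats = as.integer(smooth_window_beats),
                 C_grid = C_grid, C = C,
                 k_components = as.integer(k_components),
                 pca_scope = pca_scope,
                 with_replacement = isTRUE(with_replacement),
                 trend_delta = trend_delta,
                 trend_tail_fraction = trend_tail_fraction,
                 max_redraws = as.integer(max_redraws),
                 seed = as.integer(seed)),
            class = "eval_config")
}

# Draw one subsample of row indices with at least two classes present.
draw_subsample <- function(labels, m, with_replacement, max_redraws) {
  n <- length(labels)
  redraws <- 0L
  repeat {
    idx <- sample.int(n, m, replace = with_replacement)
    if (length(unique(labels[idx])) >= 2L) {
      return(list(idx = idx, redraws = redraws))
    }
    redraws <- redraws + 1L
    if (redraws > max_redraws) {
      stop("exceeded maximum redraws of a single-class subsample", call. = FALSE)
    }
  }
}

#' Leave-one-subject-out bootstrap evaluation
#'
#' The full evaluation protocol. Tolerated subjects are never part of any
#' training pool (they serve as a false-positive check) but every subject is
#' evaluated: each presyncope subject against models trained on the
#' remaining presyncope subjects, each tolerated subject against models
#' trained on all presyncope subjects. Per fold, the PCA basis is fitted on
#' the fold's training pool (`pca_scope = "fold"`; an assertion guards
#' against held-out leakage) or once globally, and
#' `n_bootstrap` SVMs are trained on independent `subsample_fraction`
#' subsamples (ceiling of the fraction times the pool size, drawn without
#' replacement within a draw). Deterministic given `cfg$seed`; the draws do
#' not depend on `C` or `k`, so sweeps over either are controlled
#' comparisons.
#'
#' @param beats A labeled `beat_matrix` for the whole cohort.
#' @param end_reason Named character vector (`"presyncope"`/`"tolerated"`)
#'   per subject id.
#' @param cfg An [eval_config()].
#' @param C,k Penalty and component count (default from `cfg`).
#' @return An object of class `loso_eval`: per-subject records (times, true
#'   labels, raw `n x n_bootstrap` predictions, averaged trace, metrics,
#'   trend, confusion), the pooled confusion and kappa over presyncope
#'   subjects, and the median [IQR] cohort table.
#' @export
loso_bootstrap_evaluate <- function(beats, end_reason, cfg = eval_config(),
                                    C = cfg$C, k = cfg$k_components) {
  stopifnot(inherits(beats, "beat_matrix"), inherits(cfg, "eval_config"))
  subjects <- sort(unique(beats$subject_id))
  if (is.null(names(end_reason)) || !all(subjects %in% names(end_reason))) {
    stop("`end_reason` must be named for every subject in `beats`", call. = FALSE)
  }
  train_ids <- subjects[end_reason[subjects] == "presyncope"]
  if (length(train_ids) < 3L) {
    stop("need at least 3 presyncope subjects for the protocol", call. = FALSE)
  }
  global_basis <- NULL
  if (cfg$pca_scope == "global") {
    global_basis <- fit_pca(subset_beats(beats, beats$subject_id %in% train_ids))
  }
  fold_seeds <- derive_seeds(cfg$seed, length(subjects), stream = 23L)
  records <- vector("list", length(subjects))
  names(records) <- subjects
  total_redraws <- 0L
  for (si in seq_along(subjects)) {
    s <- subjects[si]
    pool_ids <- setdiff(train_ids, s)
    pool <- subset_beats(beats, beats$subject_id %in% pool_ids)
    held <- subset_beats(beats, beats$subject_id == s)
    basis <- if (cfg$pca_scope == "fold") fit_pca(pool) else global_basis
    if (cfg$pca_scope == "fold" && s %in% basis$fitted_on) {
      stop("internal leakage: held-out subject present in the PCA fit", call. = FALSE)
    }
    n_pool <- nrow(pool$values)
    m <- as.integer(ceiling(cfg$subsample_fraction * n_pool))
    held_feats <- project_beats(basis, held, k = k)
    raw <- matrix(NA_integer_, nrow(held$values), cfg$n_bootstrap)
    smoothed <- matrix(NA_real_, nrow(held$values), cfg$n_bootstrap)
    with_seed(fold_seeds[si], {
      for (b in seq_len(cfg$n_bootstrap)) {
        draw <- draw_subsample(pool$label, m, cfg$with_replacement, cfg$max_redraws)
        total_redraws <- total_redraws + draw$redraws
        if (any(pool$subject_id[draw$idx] == s)) {
          stop("internal leakage: held-out subject in a training subsample",
               call. = FALSE)
        }
        train_feats <- project_beats(basis, subset_beats(pool, draw$idx), k = k)
        model <- train_svm(train_feats, C = C, tolerance = 1e-4)
        raw[, b] <- predict_classes(model, held_feats)
        smoothed[, b] <- moving_average(raw[, b], cfg$smooth_window_beats)
      }
    })
    avg <- rowMeans(smoothed)
    met <- per_class_metrics(held$label, avg)
    conf <- confusion_matrix(held$label, pmin(pmax(round_half_down(avg), 0L), 3L))
    trend <- severity_trend(avg, held$onset_s, beats$marks[[s]],
                            delta = cfg$trend_delta,
                            tail_fraction = cfg$trend_tail_fraction)
    records[[si]] <- list(subject_id = s,
                          end_reason = unname(end_reason[s]),
                          onset_s = held$onset_s, label = held$label,
                          raw = raw, averaged = avg,
                          metrics = met, confusion = conf, trend = trend,
                          train_subjects = pool_ids,
                          pca_fitted_on = basis$fitted_on)
  }
  pre <- records[vapply(records, function(r) r$end_reason == "presyncope", logical(1))]
  agg <- aggregate_cohort(lapply(pre, `[[`, "metrics"),
                          lapply(pre, `[[`, "confusion"))
  structure(list(subjects = records,
                 pooled_confusion = Reduce(`+`, lapply(pre, `[[`, "confusion")),
                 pooled_kappa = agg$pooled_kappa,
                 table = agg$table,
                 C = C, k = as.integer(k), cfg = cfg,
                 n_redraws = total_redraws),
            class = "loso_eval")
}

#' @export
print.loso_eval <- function(x, ...) {
  trends <- vapply(x$subjects, `[[`, character(1), "trend")
  reasons <- vapply(x$subjects, `[[`, character(1), "end_reason")
  cat(sprintf("<loso_eval> C = %g, k = %d: %d subjects (%d presyncope)\n",
              x$C, x$k, length(x$subjects), sum(reasons == "presyncope")))
  cat(sprintf("  pooled kappa = %.3f\n", x$pooled_kappa))
  cat(sprintf("  severity trend: increase %d/%d presyncope, stagnation %d/%d tolerated\n",
              sum(trends == "increase" & reasons == "presyncope"),
              sum(reasons == "presyncope"),
              sum(trends == "stagnation" & reasons == "tolerated"),
              sum(reasons == "tolerated")))
  invisible(x)
}

#' @export
summary.loso_eval <- function(object, ...) {
  print(object)
  cat("\nMedian [IQR] across presyncope subjects:\n")
  print(object$table, row.names = FALSE, digits = 4)
  invisible(object)
}

#' Plot the severity trace of one evaluated subject
#'
#' Shows the true class staircase, the individual bootstrap-model smoothed
#' traces and their average for one held-out subject.
#'
#' @param x A `loso_eval` object.
#' @param subject Subject id (default: first).
#' @param ... Unused.
#' @export
plot.loso_eval <- function(x, subject = names(x$subjects)[1], ...) {
  r <- x$subjects[[subject]]
  sm <- apply(r$raw, 2L, moving_average, window = x$cfg$smooth_window_beats)
  matplot(r$onset_s, sm, type = "l", lty = 1, col = "grey70",
          xlab = "time (s)", ylab = "class", ylim = c(0, 3),
          main = sprintf("subject %s (%s)", subject, r$end_reason))
  lines(r$onset_s, r$label, type = "s", lwd = 2)
  lines(r$onset_s, r$averaged, lwd = 2, col = "red3")
  legend("topleft", bty = "n", lwd = c(2, 1, 2),
         col = c("black", "grey70", "red3"),
         legend = c("true class", "bootstrap models", "averaged trace"))
  invisible(x)
}

#' Evaluate the protocol over the penalty grid
#'
#' Runs [loso_bootstrap_evaluate()] for every `C` in `cfg$C_grid` with the
#' same seed, so the subsample draws are identical across `C` and the sweep
#' is a controlled comparison.
#'
#' @param beats,end_reason,cfg As in [loso_bootstrap_evaluate()].
#' @param k Component count.
#' @return A list with `runs` (one `loso_eval` per C) and `summary` (data
#'   frame with C, pooled kappa, overall accuracy/MSE medians).
#' @export
c_grid_sweep <- function(beats, end_reason, cfg = eval_config(),
                         k = cfg$k_components) {
  runs <- lapply(cfg$C_grid, function(C) {
    loso_bootstrap_evaluate(beats, end_reason, cfg, C = C, k = k)
  })
  names(runs) <- as.character(cfg$C_grid)
  list(runs = runs, summary = sweep_summary(runs, "C", cfg$C_grid))
}

#' Stepwise component-addition curve
#'
#' Reruns the full evaluation at fixed `C` for each requested component
#' count, reporting pooled kappa and the overall accuracy and MSE medians
#' per k — the stepwise feature-addition analysis used to pick the number of
#' components.
#'
#' @param beats,end_reason,cfg As in [loso_bootstrap_evaluate()].
#' @param k_values Increasing vector of component counts (all >= 1).
#' @param C Penalty (default `cfg$C`).
#' @return A list with `runs` (one `loso_eval` per k) and `summary` (data
#'   frame with k, pooled kappa, overall accuracy/MSE medians).
#' @export
component_addition_curve <- function(beats, end_reason, cfg = eval_config(),
                                     k_values = c(1, 2, 3, 5, 10), C = cfg$C) {
  if (any(k_values < 1) || is.unsorted(k_values, strictly = TRUE)) {
    stop("`k_values` must be strictly increasing and >= 1", call. = FALSE)
  }
  runs <- lapply(k_values, function(k) {
    loso_bootstrap_evaluate(beats, end_reason, cfg, C = C, k = k)
  })
  names(runs) <- as.character(k_values)
  list(runs = runs, summary = sweep_summary(runs, "k", k_values))
}

sweep_summary <- function(runs, par_name, par_values) {
  out <- data.frame(par = par_values,
                    pooled_kappa = vapply(runs, `[[`, numeric(1), "pooled_kappa"),
                    overall_accuracy_median = vapply(runs, function(r) {
                      r$table$median[r$table$metric == "accuracy" &
                                       r$table$class == "overall"]
                    }, numeric(1)),
                    overall_mse_median = vapply(runs, function(r) {
                      r$table$median[r$table$metric == "mse" &
                                       r$table$class == "overall"]
                    }, numeric(1)))
  names(out)[1] <- par_name
  rownames(out) <- NULL
  out
}
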