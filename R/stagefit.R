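#' Fit the hypovolemia staging model
#'
#' The central model of the package: a principal-component parametrization of
#' fixed-length beat shape vectors followed by a one-vs-one soft-margin
#' linear SVM over the ordinal classes 0 (baseline normovolemia) to 3
#' (final LBNP stage). Returns a single fitted object with the usual
#' modelling methods (`print`, `summary`, `coef`, `predict`).
#'
#' @param beats A `beat_matrix` from [build_beat_matrix()] with labels
#'   attached.
#' @param C Soft-margin penalty of the SVM.
#' @param k Number of principal components fed to the SVM.
#' @param basis Optional pre-fitted [fit_pca()] basis (e.g. a training-fold
#'   basis); fitted on `beats` when `NULL`.
#' @param tolerance SVM solver tolerance.
#' @return An object of class `stagefit` with elements `basis`, `svm`, `C`,
#'   `k`, `n_beats`, `classes_present`, `call`.
#' @export
#' @examples
#' cfg <- synth_config(n_subjects = 2, presyncope_fraction = 1,
#'                     baseline_duration_s = 60, max_lbnp_duration_s = 240,
#'                     physiocal_period_s = 1e6, seed = 7)
#' bm <- build_beat_matrix(generate_cohort(cfg))
#' fit <- stagefit(bm, C = 0.01, k = 3)
#' fit
#' table(predict(fit, bm))
stagefit <- function(beats, C = 0.01, k = 5L, basis = NULL, tolerance = 1e-6) {
  stopifnot(inherits(beats, "beat_matrix"))
  if (is.null(basis)) basis <- fit_pca(beats)
  feats <- project_beats(basis, beats, k = k)
  svm <- train_svm(feats, C = C, tolerance = tolerance)
  structure(list(basis = basis, svm = svm, C = C, k = as.integer(k),
                 n_beats = nrow(beats$values),
                 classes_present = svm$classes_present,
                 call = match.call()),
            class = "stagefit")
}

#' @export
print.stagefit <- function(x, ...) {
  cat("Hypovolemia staging model (PCA + one-vs-one linear SVM)\n")
  cat(sprintf("  %d training beats, k = %d components, C = %g\n",
              x$n_beats, x$k, x$C))
  ev <- x$basis$explained_variance
  cat(sprintf("  variance captured by k components: %.1f%%\n",
              100 * sum(ev[seq_len(x$k)]) / sum(ev)))
  cat(sprintf("  classes present: %s\n", paste(x$classes_present, collapse = ", ")))
  invisible(x)
}

#' @export
summary.stagefit <- function(object, ...) {
  ev <- object$basis$explained_variance
  out <- list(fit = object,
              variance_fractions = ev / sum(ev),
              pair_margins = vapply(object$svm$pairs,
                                    function(p) 2 / sqrt(sum(p$w^2)), numeric(1)))
  class(out) <- "summary.stagefit"
  out
}

#' @export
print.summary.stagefit <- function(x, ...) {
  print(x$fit)
  cat("  explained variance fractions (first 8):\n  ")
  cat(sprintf("%.4f", head(x$variance_fractions, 8)), sep = " ")
  cat("\n  pairwise geometric margins 2/||w||:\n")
  for (i in seq_along(x$fit$svm$pairs)) {
    p <- x$fit$svm$pairs[[i]]
    cat(sprintf("    %d vs %d: %.3g\n", p$lo, p$hi, x$pair_margins[i]))
  }
  invisible(x)
}

#' @export
coef.stagefit <- function(object, ...) {
  out <- lapply(object$svm$pairs, function(p) c(p$w, bias = p$b))
  names(out) <- vapply(object$svm$pairs,
                       function(p) sprintf("%dvs%d", p$lo, p$hi), character(1))
  out
}

#' Predict ordinal classes for new beats
#'
#' Projects `newdata` onto the model's training-fold PCA basis and applies
#' the one-vs-one vote. With `smooth_window > 1` the discrete class trace is
#' additionally smoothed with a trailing moving average and returned as a
#' continuous severity trace in `[0, 3]`.
#'
#' @param object A [stagefit()] model.
#' @param newdata A `beat_matrix` (or numeric 33-column matrix).
#' @param smooth_window `NULL` or 1 for raw discrete classes; otherwise the
#'   moving-average window in beats.
#' @param ... Unused.
#' @return Integer classes, or a numeric trace when smoothing is requested.
#' @export
predict.stagefit <- function(object, newdata, smooth_window = NULL, ...) {
  feats <- project_beats(object$basis, newdata, k = object$k)
  cls <- predict_classes(object$svm, feats)
  if (is.null(smooth_window) || smooth_window <= 1L) return(cls)
  moving_average(cls, window = smooth_window)
}
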