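#' Train the one-vs-one soft-margin linear SVM stager
#'
#' Fits one binary soft-margin linear SVM (hinge loss, penalty `C`) per
#' unordered pair of classes present in the training labels, using libsvm
#' (via \pkg{e1071}) as the quadratic-program solver. Each separator is
#' reduced to an explicit weight vector and bias, oriented so that positive
#' decision values favor the lower (less severe) class of the pair.
#' Deterministic for a fixed input order and solver tolerance.
#'
#' @param features A `feature_matrix` from [project_beats()], or a numeric
#'   score matrix (then `labels` must be given).
#' @param C Soft-margin penalty (> 0); larger values penalize training
#'   misclassification harder and shrink the margin.
#' @param labels Integer class labels in `{0, 1, 2, 3}` (taken from
#'   `features$label` when absent).
#' @param tolerance Solver termination tolerance.
#' @return An object of class `staging_svm`: `C`, `k` (feature count),
#'   `classes_present`, and `pairs`, a list with one `(lo, hi, w, b)` entry
#'   per class pair.
#' @export
train_svm <- function(features, C = 0.01, labels = NULL, tolerance = 1e-6) {
  stop_if_not_number(C, "C", lower = 1e-12)
  x <- if (inherits(features, "feature_matrix")) features$scores else features
  if (is.null(labels)) labels <- features$label
  stopifnot(is.matrix(x), length(labels) == nrow(x))
  if (any(!is.finite(x))) stop("non-finite feature values", call. = FALSE)
  if (any(!labels %in% 0:3)) stop("labels must lie in {0, 1, 2, 3}", call. = FALSE)
  classes <- sort(unique(labels))
  if (length(classes) < 2L) {
    stop("training data must contain at least 2 classes", call. = FALSE)
  }
  pair_idx <- utils::combn(classes, 2L)
  pairs <- vector("list", ncol(pair_idx))
  for (p in seq_len(ncol(pair_idx))) {
    lo <- pair_idx[1, p]; hi <- pair_idx[2, p]
    sel <- labels %in% c(lo, hi)
    xs <- x[sel, , drop = FALSE]
    y <- factor(ifelse(labels[sel] == lo, "lo", "hi"), levels = c("lo", "hi"))
    fit <- e1071::svm(x = xs, y = y, scale = FALSE, kernel = "linear",
                      cost = C, tolerance = tolerance)
    w <- drop(t(fit$coefs) %*% fit$SV)
    b <- -fit$rho
    # orient the separator so positive decisions favor the lower class
    f <- drop(xs %*% w) + b
    if (mean(f[y == "lo"]) < mean(f[y == "hi"])) {
      w <- -w; b <- -b
    }
    pairs[[p]] <- list(lo = lo, hi = hi, w = w, b = b)
  }
  structure(list(C = C, k = ncol(x), classes_present = classes, pairs = pairs),
            class = "staging_svm")
}

#' @export
print.staging_svm <- function(x, ...) {
  cat(sprintf("<staging_svm> C = %g, %d features, classes {%s}, %d pairwise separators\n",
              x$C, x$k, paste(x$classes_present, collapse = ","), length(x$pairs)))
  invisible(x)
}

# Pairwise decision values: one column per class pair, positive toward the
# pair's lower class.
pair_decision_values <- function(model, scores) {
  vapply(model$pairs, function(p) drop(scores %*% p$w) + p$b,
         numeric(nrow(scores)))
}

#' Predict ordinal classes by one-vs-one majority vote
#'
#' Each pairwise separator casts one vote (its lower class on nonnegative
#' decision values, its upper class otherwise); the class with the most votes
#' wins, and vote ties break toward the lower (less severe) class.
#'
#' @param model A [train_svm()] model.
#' @param features A `feature_matrix` or numeric score matrix with `model$k`
#'   columns.
#' @return Integer vector of predicted classes in `{0, 1, 2, 3}`.
#' @export
predict_classes <- function(model, features) {
  stopifnot(inherits(model, "staging_svm"))
  x <- if (inherits(features, "feature_matrix")) features$scores else features
  if (ncol(x) != model$k) {
    stop(sprintf("feature count %d does not match model k = %d", ncol(x), model$k),
         call. = FALSE)
  }
  votes <- matrix(0L, nrow(x), 4L)
  dec <- pair_decision_values(model, x)
  if (nrow(x) == 1L) dec <- matrix(dec, nrow = 1L)
  for (p in seq_along(model$pairs)) {
    pr <- model$pairs[[p]]
    lo_wins <- dec[, p] >= 0
    votes[lo_wins, pr$lo + 1L] <- votes[lo_wins, pr$lo + 1L] + 1L
    votes[!lo_wins, pr$hi + 1L] <- votes[!lo_wins, pr$hi + 1L] + 1L
  }
  max.col(votes, ties.method = "first") - 1L
}
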