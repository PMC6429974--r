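#' Principal-component parametrization of the beat matrix
#'
#' Centers the `n x 33` beat matrix by its column means and takes the
#' right-singular vectors of the centered matrix as orthonormal shape
#' components, ordered by decreasing explained variance. The PCA is on the
#' covariance (not correlation) of the raw mmHg values: all 33 features share
#' units and the pressure level is informative. Component signs follow a
#' deterministic convention: the largest-magnitude loading of each component
#' is positive.
#'
#' @param x A `beat_matrix` or a plain numeric matrix (beats in rows).
#' @param fitted_on Identifier of the training subset (defaults to the sorted
#'   subject ids when `x` is a `beat_matrix`); carried along so downstream
#'   code can assert that held-out data were never part of the fit.
#' @return An object of class `pca_basis`: `mean` (length-33), `components`
#'   (33 x m orthonormal), `explained_variance` (nonincreasing),
#'   `fitted_on`.
#' @export
fit_pca <- function(x, fitted_on = NULL) {
  if (inherits(x, "beat_matrix")) {
    if (is.null(fitted_on)) fitted_on <- sort(unique(x$subject_id))
    x <- x$values
  }
  stopifnot(is.matrix(x), is.numeric(x))
  n <- nrow(x)
  if (n < 2L) stop("need at least 2 beats to fit a PCA", call. = FALSE)
  mu <- colMeans(x)
  xc <- sweep(x, 2L, mu)
  if (max(abs(xc)) == 0) {
    stop("all beats are identical: zero variance in every direction",
         call. = FALSE)
  }
  sv <- svd(xc)
  v <- sv$v
  for (j in seq_len(ncol(v))) {
    i <- which.max(abs(v[, j]))
    if (v[i, j] < 0) v[, j] <- -v[, j]
  }
  structure(list(mean = mu,
                 components = v,
                 explained_variance = sv$d^2 / (n - 1),
                 fitted_on = fitted_on %||% "unlabeled"),
            class = "pca_basis")
}

#' @export
print.pca_basis <- function(x, ...) {
  ev <- x$explained_variance
  cat(sprintf("<pca_basis> %d components; leading variance fractions: %s\n",
              ncol(x$components),
              paste(sprintf("%.3f", head(ev / sum(ev), 5)), collapse = " ")))
  invisible(x)
}

#' Project beats onto the first k principal components
#'
#' Scores are `(values - mean) %*% components[, 1:k]`. Labels, subject ids
#' and onset times are carried through when the input is a `beat_matrix`.
#'
#' @param basis A [fit_pca()] basis.
#' @param x A `beat_matrix` or numeric matrix with matching column count.
#' @param k Number of components to keep (`1 <= k <= m`).
#' @return An object of class `feature_matrix`: `scores` (`n x k`), plus
#'   `label`, `subject_id`, `onset_s`, `marks` when available, and the
#'   basis's `fitted_on` tag.
#' @export
project_beats <- function(basis, x, k = 5L) {
  stopifnot(inherits(basis, "pca_basis"))
  m <- ncol(basis$components)
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k > m) {
    stop(sprintf("`k` must be in [1, %d]", m), call. = FALSE)
  }
  k <- as.integer(k)
  bm <- if (inherits(x, "beat_matrix")) x else NULL
  vals <- if (is.null(bm)) x else bm$values
  stopifnot(is.matrix(vals), ncol(vals) == length(basis$mean))
  scores <- sweep(vals, 2L, basis$mean) %*% basis$components[, seq_len(k), drop = FALSE]
  structure(list(scores = scores,
                 label = bm$label, subject_id = bm$subject_id,
                 onset_s = bm$onset_s, marks = bm$marks,
                 k = k, fitted_on = basis$fitted_on),
            class = "feature_matrix")
}
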