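# Independent oracles used by the tests. These deliberately avoid the code
# paths they check.

# Brute-force soft-margin linear SVM by active-set enumeration of the dual:
#   max sum(a) - 1/2 a' Q a,  0 <= a <= C,  sum(a*y) = 0,  Q = yy' .* XX'.
# Every point is assigned to {zero, upper-bound, free}; the KKT system is
# solved for each assignment and candidates are kept only when all KKT
# conditions verify. Exponential in n: use for n <= 8 only.
qp_svm_oracle <- function(X, y, C, tol = 1e-8) {
  n <- nrow(X)
  stopifnot(n <= 8, all(y %in% c(-1, 1)))
  K <- X %*% t(X)
  best <- NULL
  status <- expand.grid(rep(list(0:2), n))  # 0 zero, 1 upper, 2 free
  for (r in seq_len(nrow(status))) {
    st <- as.integer(status[r, ])
    Fs <- which(st == 2L); Us <- which(st == 1L)
    alpha <- numeric(n); alpha[Us] <- C
    if (length(Fs) > 0) {
      # unknowns: alpha_F and b;  y_i * f(x_i) = 1  for i in F; sum(a*y) = 0
      A <- matrix(0, length(Fs) + 1, length(Fs) + 1)
      rhs <- numeric(length(Fs) + 1)
      for (ii in seq_along(Fs)) {
        i <- Fs[ii]
        A[ii, seq_along(Fs)] <- y[Fs] * K[i, Fs]
        A[ii, length(Fs) + 1] <- 1
        rhs[ii] <- y[i] - sum(C * y[Us] * K[i, Us])
      }
      A[length(Fs) + 1, seq_along(Fs)] <- y[Fs]
      rhs[length(Fs) + 1] <- -sum(C * y[Us])
      sol <- tryCatch(solve(A, rhs), error = function(e) NULL)
      if (is.null(sol)) next
      alpha[Fs] <- sol[seq_along(Fs)]
      b <- sol[length(Fs) + 1]
      if (any(alpha[Fs] < -tol) || any(alpha[Fs] > C + tol)) next
    } else {
      if (abs(sum(alpha * y)) > tol) next
      # b undetermined by the dual: pick it to minimize the hinge term
      w0 <- colSums(alpha * y * X)
      f0 <- drop(X %*% w0)
      bs <- y - f0
      obj_b <- vapply(bs, function(bb)
        sum(pmax(0, 1 - y * (f0 + bb))), numeric(1))
      b <- bs[which.min(obj_b)]
    }
    w <- colSums(alpha * y * X)
    f <- drop(X %*% w) + b
    margin <- y * f
    ok <- TRUE
    for (i in seq_len(n)) {
      if (st[i] == 0L && margin[i] < 1 - 1e-6) ok <- FALSE
      if (st[i] == 1L && margin[i] > 1 + 1e-6) ok <- FALSE
      if (st[i] == 2L && abs(margin[i] - 1) > 1e-6) ok <- FALSE
    }
    if (!ok) next
    obj <- 0.5 * sum(w^2) + C * sum(pmax(0, 1 - margin))
    if (is.null(best) || obj < best$objective - 1e-12) {
      best <- list(w = w, b = b, alpha = alpha, objective = obj)
    }
  }
  best
}

# Primal soft-margin objective of a trained pairwise separator.
svm_primal_objective <- function(w, b, X, y, C) {
  0.5 * sum(w^2) + C * sum(pmax(0, 1 - y * (drop(X %*% w) + b)))
}

# Cohen's kappa recomputed from the expanded label pairs of a count matrix.
kappa_pairs_oracle <- function(cm) {
  a <- rep(rep(seq_len(nrow(cm)), ncol(cm)), as.vector(cm))
  b <- rep(rep(seq_len(ncol(cm)), each = nrow(cm)), as.vector(cm))
  po <- mean(a == b)
  pe <- sum(vapply(seq_len(nrow(cm)), function(cc)
    mean(a == cc) * mean(b == cc), numeric(1)))
  if (1 - pe < 1e-12) return(0)
  (po - pe) / (1 - pe)
}

# Small fast cohort for the evaluation-protocol unit tests, built once.
local_small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synth_config(n_subjects = 5, presyncope_fraction = 0.8,
                          baseline_duration_s = 120, max_lbnp_duration_s = 480,
                          plateau_ramp_s = 200, seed = 301)
      coh <- generate_cohort(cfg)
      bm <- build_beat_matrix(coh)
      er <- vapply(coh, function(s) s$recording$marks$end_reason, character(1))
      names(er) <- vapply(coh, function(s) s$recording$subject_id, character(1))
      cache <<- list(cfg = cfg, cohort = coh, beats = bm, end_reason = er)
    }
    cache
  }
})
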